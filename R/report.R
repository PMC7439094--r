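#' Pipeline configuration
#'
#' Collects the tunable parameters of the end-to-end analysis. Paths may be
#' `NULL` when the pipeline starts from a simulated study.
#'
#' @param abundance_path,design_path,gmt_path Optional input file paths; when
#'   `abundance_path` is `NULL` the pipeline simulates a study from
#'   `synthetic` instead.
#' @param synthetic A [synthetic_config()] used when no abundance file is
#'   given.
#' @param baseline_strain Reference strain for the OLS adjustment.
#' @param scaling OPLS-DA scaling mode (`"uv"`, `"pareto"`, `"center"`).
#' @param k_ortho Number of orthogonal components.
#' @param n_folds Cross-validation folds.
#' @param n_perm Label permutations for pQ2.
#' @param vip_min rmsVIP selection threshold.
#' @param fc_min Symmetric fold-change threshold for the robust subset.
#' @param alpha Significance level.
#' @param log_transform Apply a natural-log transform before the OPLS-DA
#'   scaling.
#' @param seed Master seed for every stochastic stage.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(abundance_path = NULL, design_path = NULL,
                            gmt_path = NULL,
                            synthetic = synthetic_config(),
                            baseline_strain = "CC011", scaling = "uv",
                            k_ortho = 1L, n_folds = 7L, n_perm = 1000L,
                            vip_min = 1.5, fc_min = 1.5, alpha = 0.05,
                            log_transform = FALSE, seed = 1L) {
  if (vip_min <= 0 || fc_min <= 0) stop2("thresholds must be positive")
  if (alpha <= 0 || alpha >= 1) stop2("alpha must lie in (0, 1)")
  if (is.null(seed)) stop2("a seed is mandatory (stochastic stages)")
  structure(list(abundance_path = abundance_path,
                 design_path = design_path, gmt_path = gmt_path,
                 synthetic = synthetic, baseline_strain = baseline_strain,
                 scaling = scaling, k_ortho = k_ortho,
                 n_folds = as.integer(n_folds), n_perm = as.integer(n_perm),
                 vip_min = vip_min, fc_min = fc_min, alpha = alpha,
                 log_transform = log_transform, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop2("[stage ", name, "] ", conditionMessage(e))
  })
}

#' Run the end-to-end analysis
#'
#' Chains the full pipeline: (simulate or load) -> preprocess -> strain
#' adjustment -> diet OPLS-DA with permutation test -> VIP selection and
#' strain-stratified fold-change statistics -> set enrichment. Writes
#' machine-readable outputs under `out_dir` (when given) and returns the
#' result bundle. Fully reproducible from `(config, seed)`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; created if absent.
#' @return List with `summary` (Q2, pQ2, R2Y, counts of selected / robust
#'   metabolites, enrichment hits), `model`, `permutation`, `vip`,
#'   `selection`, `response`, `enrichment`, `adjustment`, `abundance`,
#'   `design`, and (for simulated runs) `truth`.
#' @export
run_report <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed, 4L)
  hash <- config_hash(unclass(config)[setdiff(names(config),
                                              c("abundance_path",
                                                "design_path", "gmt_path"))])

  truth <- NULL
  if (is.null(config$abundance_path)) {
    sim <- stage("simulate", {
      sc <- config$synthetic
      sc$seed <- seeds[1]
      simulate_study(sc)
    })
    abundance <- sim$abundance
    design <- sim$design
    truth <- sim$truth
  } else {
    design <- stage("read", read_design(config$design_path))
    abundance <- stage("read", read_abundance(config$abundance_path,
                                              design = design))
  }

  pp <- stage("preprocess", preprocess_abundance(abundance))
  if (config$log_transform) {
    pp <- abundance_matrix(log(pp$values), run_day = pp$run_day,
                           status = union(pp$status, "corrected"),
                           imputed = pp$imputed)
  }
  adj <- stage("adjust",
               fit_and_correct(pp, design,
                               baseline = config$baseline_strain))
  d_al <- align_design(pp, design)

  perm <- stage("oplsda", permutation_test(
    adj$corrected$values, d_al$diet, k_ortho = config$k_ortho,
    scaling = config$scaling, n_folds = config$n_folds,
    n_perm = config$n_perm, seed = seeds[2]))
  model <- stage("oplsda", fit_oplsda(
    adj$corrected$values, d_al$diet, k_ortho = config$k_ortho,
    scaling = config$scaling, n_folds = config$n_folds, seed = seeds[2]))
  vip <- compute_vip(model, vip_min = config$vip_min)

  response <- stage("stratify", fold_change(pp, design))
  selection <- stage("stratify",
                     robust_change_filter(vip, response,
                                          vip_min = config$vip_min,
                                          fc_min = config$fc_min))

  sets <- if (!is.null(config$gmt_path)) {
    stage("read", read_gmt(config$gmt_path))
  } else if (!is.null(truth)) {
    # positive-control sets built around the simulated truth, scaled to
    # the universe when the study is smaller than the default design
    stage("simulate", {
      p <- ncol(pp$values)
      make_pathway_sets(
        colnames(pp$values),
        set_sizes = c(min(100L, p %/% 2L), rep(min(50L, p %/% 4L), 4L)),
        overlap_with_truth = 0.8,
        truth_ids = truth$diet_responsive_ids, seed = seeds[3])
    })
  } else NULL

  enrichment <- NULL
  if (!is.null(sets) && any(selection$selected)) {
    enrichment <- stage("enrich", ora(
      selection$metabolite[selection$selected], sets,
      universe = colnames(pp$values), alpha = config$alpha))
  }

  summary <- list(
    n_samples = nrow(pp$values), n_metabolites = ncol(pp$values),
    q2 = perm$q2, p_q2 = perm$p_q2, r2y = perm$r2y, p_r2y = perm$p_r2y,
    n_selected = sum(selection$selected),
    n_robust = sum(selection$robust),
    n_enriched = if (is.null(enrichment)) NA_integer_ else
      sum(enrichment$significant),
    seed = config$seed, config_hash = hash)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_abundance(pp, file.path(out_dir, "preprocessed.tsv"),
                    seed = config$seed, hash = hash)
    write_abundance(adj$corrected, file.path(out_dir, "corrected.tsv"),
                    seed = config$seed, hash = hash)
    write_design(design, file.path(out_dir, "design.tsv"),
                 seed = config$seed, hash = hash)
    write_stamped_table(vip, file.path(out_dir, "vip.tsv"),
                        config$seed, hash)
    write_stamped_table(selection, file.path(out_dir, "selection.tsv"),
                        config$seed, hash)
    write_stamped_table(
      data.frame(perm_q2 = perm$perm_q2, perm_r2y = perm$perm_r2y),
      file.path(out_dir, "permutations.tsv"), config$seed, hash)
    if (!is.null(enrichment)) {
      write_stamped_table(as.data.frame(enrichment),
                          file.path(out_dir, "enrichment.tsv"),
                          config$seed, hash)
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }

  list(summary = summary, model = model, permutation = perm, vip = vip,
       selection = selection, response = response, enrichment = enrichment,
       adjustment = adj, abundance = pp, design = design, truth = truth)
}

write_stamped_table <- function(df, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, seed, hash)
  utils::write.table(df, con, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}
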