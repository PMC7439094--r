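#' Configuration for the synthetic strain-by-diet metabolomics study
#'
#' Defines the simulated study: a panel of inbred strains crossed with a
#' vitamin-D-sufficient (VDS) vs -deficient (VDD) diet, untargeted liver
#' metabolite abundances on a multiplicative (log-normal) scale, run-day
#' batch factors, and below-LOD censoring. Defaults emulate a design of
#' 8 Collaborative Cross strains, 72 dams in groups of 3-6 per strain x diet
#' cell, and 654 metabolites of which 78 respond to diet.
#'
#' Effects are additive on the natural-log scale. Each diet-responsive
#' metabolite carries a population log2 fold change whose magnitude is drawn
#' from `diet_log2fc_range` (sign positive with probability `diet_up_frac`).
#' `responder_specs` declare strain-specific responses: for the named strain,
#' the total VDD/VDS fold change of every metabolite in the named responsive
#' subset is pinned to `2^log2fc` (the interaction term absorbs the
#' difference from the population effect). Default responder strains mirror
#' a strongly fatty-acid-responsive strain at 4.5-fold and a
#' glycerophospholipid-responsive strain at 9-fold.
#'
#' @param n_strains Number of strains.
#' @param strains Strain labels.
#' @param n_total Total number of dams across all strain x diet groups.
#' @param group_size_range Admissible per-group sizes (inclusive range).
#' @param group_sizes Optional explicit `n_strains x 2` matrix of group sizes
#'   (columns VDS, VDD) overriding the random draw.
#' @param n_metabolites Number of metabolites.
#' @param n_diet_responsive Number of metabolites with a diet effect.
#' @param frac_strain_affected Fraction of metabolites with strain main
#'   effects.
#' @param strain_effect_sd SD (log scale) of strain shifts for affected
#'   metabolites.
#' @param diet_log2fc_range Range of |log2 fold change| for diet-responsive
#'   metabolites.
#' @param diet_up_frac Probability a diet effect is an increase.
#' @param responder_specs List of `list(strain=, set=, log2fc=)` entries
#'   declaring strain-specific total responses on responsive subsets.
#' @param responsive_set_sizes Named integer vector partitioning the
#'   diet-responsive metabolites into labelled subsets (pathway-like groups);
#'   any remainder is labelled `"other"`.
#' @param n_run_days Number of instrument batches (run days).
#' @param batch_sd SD (log scale) of the per-day batch factor.
#' @param noise_cv Residual coefficient of variation on the natural scale.
#' @param lod_quantile Fraction of each metabolite's lowest raw values
#'   censored to missing (limit-of-detection emulation).
#' @param seed Integer seed; all randomness fans out from it.
#'
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_strains = 8L,
                             strains = c("CC001", "CC004", "CC011", "CC017",
                                         "CC032", "CC041", "CC042", "CC051"),
                             n_total = 72L,
                             group_size_range = c(3L, 6L),
                             group_sizes = NULL,
                             n_metabolites = 654L,
                             n_diet_responsive = 78L,
                             frac_strain_affected = 0.3,
                             strain_effect_sd = 0.5,
                             diet_log2fc_range = c(1, 2),
                             diet_up_frac = 0.75,
                             responder_specs = list(
                               list(strain = "CC017", set = "fatty_acid",
                                    log2fc = log2(4.5)),
                               list(strain = "CC032",
                                    set = "glycerophospholipid",
                                    log2fc = log2(9))),
                             responsive_set_sizes = c(
                               fatty_acid = 13L, glycerophospholipid = 15L,
                               acylglycerol = 6L, uremic_solute = 8L),
                             n_run_days = 4L,
                             batch_sd = 0.1,
                             noise_cv = 0.3,
                             lod_quantile = 0.02,
                             seed = 1L) {
  cfg <- list(n_strains = as.integer(n_strains), strains = strains,
              n_total = as.integer(n_total),
              group_size_range = as.integer(group_size_range),
              group_sizes = group_sizes,
              n_metabolites = as.integer(n_metabolites),
              n_diet_responsive = as.integer(n_diet_responsive),
              frac_strain_affected = frac_strain_affected,
              strain_effect_sd = strain_effect_sd,
              diet_log2fc_range = diet_log2fc_range,
              diet_up_frac = diet_up_frac,
              responder_specs = responder_specs,
              responsive_set_sizes = responsive_set_sizes,
              n_run_days = as.integer(n_run_days),
              batch_sd = batch_sd, noise_cv = noise_cv,
              lod_quantile = lod_quantile, seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (length(cfg$strains) != cfg$n_strains) {
    stop2("length(strains) must equal n_strains")
  }
  if (cfg$n_diet_responsive > cfg$n_metabolites) {
    stop2("n_diet_responsive must not exceed n_metabolites")
  }
  if (cfg$lod_quantile < 0 || cfg$lod_quantile >= 1) {
    stop2("lod_quantile must lie in [0, 1)")
  }
  if (cfg$group_size_range[1] < 2L) {
    stop2("group sizes below 2 are not a valid design")
  }
  if (!is.null(cfg$group_sizes)) {
    gs <- cfg$group_sizes
    if (!is.matrix(gs) || nrow(gs) != cfg$n_strains || ncol(gs) != 2L) {
      stop2("group_sizes must be an n_strains x 2 matrix (VDS, VDD)")
    }
    if (any(gs < 2L)) stop2("group sizes below 2 are not a valid design")
  }
  for (sp in cfg$responder_specs) {
    if (!sp$strain %in% cfg$strains) {
      stop2("responder strain not in strain panel: ", sp$strain)
    }
    if (!sp$set %in% c(names(cfg$responsive_set_sizes), "other")) {
      stop2("responder set has no declared subset: ", sp$set)
    }
  }
  if (cfg$frac_strain_affected < 0 || cfg$frac_strain_affected > 1) {
    stop2("frac_strain_affected must lie in [0, 1]")
  }
  invisible(cfg)
}

# Draw per-group sizes uniformly from the admissible range, then nudge
# random groups up/down until the panel total matches n_total.
draw_group_sizes <- function(n_groups, range, total) {
  lo <- range[1]; hi <- range[2]
  if (total < n_groups * lo || total > n_groups * hi) {
    stop2("n_total ", total, " unreachable with group sizes in [",
          lo, ", ", hi, "]")
  }
  sizes <- sample(seq(lo, hi), n_groups, replace = TRUE)
  while (sum(sizes) > total) {
    i <- sample(which(sizes > lo), 1L)
    sizes[i] <- sizes[i] - 1L
  }
  while (sum(sizes) < total) {
    i <- sample(which(sizes < hi), 1L)
    sizes[i] <- sizes[i] + 1L
  }
  sizes
}

#' Simulate a strain-by-diet metabolomics study
#'
#' Generates raw (pre-normalization) metabolite abundances under a log-normal
#' model: log abundance = metabolite baseline + strain shift + diet effect
#' (modulated by strain-specific interaction for responsive metabolites) +
#' run-day batch factor + Gaussian noise. Values are exponentiated and the
#' lowest `lod_quantile` fraction of each metabolite's values is censored to
#' missing, emulating below-LOD dropout. Run days are assigned round-robin
#' over samples so every batch contains every group.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `abundance` ([abundance_matrix()]),
#'   `design` ([study_design()]) and `truth` (a `SyntheticTruth` list holding
#'   the injected effects: `diet_responsive_ids`, `diet_log2fc`,
#'   `interaction_log` matrix, `strain_effect_map`, `responsive_set`,
#'   `day_factors`, `lod_censored`, `baseline_log`).
#' @examples
#' sim <- simulate_study(synthetic_config(n_metabolites = 20, seed = 7))
#' sim$abundance
#' @export
simulate_study <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  seeds <- derive_seeds(config$seed, 6L)
  n_s <- config$n_strains
  p <- config$n_metabolites
  met_ids <- sprintf("met_%03d", seq_len(p))

  ## --- design -------------------------------------------------------------
  design <- with_seed(seeds[1], {
    gs <- config$group_sizes
    if (is.null(gs)) {
      sizes <- draw_group_sizes(2L * n_s, config$group_size_range,
                                config$n_total)
      gs <- matrix(sizes, nrow = n_s, ncol = 2L)
    }
    rows <- list()
    for (si in seq_len(n_s)) {
      for (di in 1:2) {
        diet <- c("VDS", "VDD")[di]
        k <- gs[si, di]
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_%s_%d", config$strains[si], diet,
                              seq_len(k)),
          strain = config$strains[si], diet = diet,
          stringsAsFactors = FALSE)
      }
    }
    d <- do.call(rbind, rows)
    d$run_day <- factor(sprintf("day%d",
                                ((seq_len(nrow(d)) - 1L) %% config$n_run_days) + 1L))
    study_design(d)
  })
  n <- nrow(design)

  ## --- effect structure ---------------------------------------------------
  baseline_log <- with_seed(seeds[2], stats::rnorm(p))
  names(baseline_log) <- met_ids

  strain_effect_map <- with_seed(seeds[3], {
    map <- matrix(0, n_s, p, dimnames = list(config$strains, met_ids))
    n_aff <- round(config$frac_strain_affected * p)
    if (n_aff > 0 && config$strain_effect_sd > 0) {
      aff <- sample(p, n_aff)
      map[, aff] <- stats::rnorm(n_s * n_aff, sd = config$strain_effect_sd)
      # center within metabolite so strain shifts do not mimic a global shift
      map[, aff] <- sweep(map[, aff, drop = FALSE], 2L,
                          colMeans(map[, aff, drop = FALSE]))
    }
    map
  })

  truth_diet <- with_seed(seeds[4], {
    resp_idx <- sort(sample(p, config$n_diet_responsive))
    nr <- length(resp_idx)
    l2 <- stats::runif(nr, config$diet_log2fc_range[1],
                       config$diet_log2fc_range[2])
    sgn <- ifelse(stats::runif(nr) < config$diet_up_frac, 1, -1)
    l2 <- l2 * sgn
    # partition responsive metabolites into labelled pathway-like subsets
    set_lab <- rep("other", nr)
    pos <- 1L
    for (nm in names(config$responsive_set_sizes)) {
      k <- min(config$responsive_set_sizes[[nm]], nr - pos + 1L)
      if (k <= 0) break
      set_lab[pos:(pos + k - 1L)] <- nm
      pos <- pos + k
    }
    # strain-specific responder effects override the population fold change
    # for the named strain: interaction = target log effect - population
    inter <- matrix(0, n_s, nr, dimnames = list(config$strains, NULL))
    for (sp in config$responder_specs) {
      j <- which(set_lab == sp$set)
      if (length(j)) {
        target_log <- log(2) * sp$log2fc
        inter[sp$strain, j] <- target_log - log(2) * l2[j]
      }
    }
    list(idx = resp_idx, log2fc = l2, set = set_lab, inter = inter)
  })

  ## --- assemble log abundances -------------------------------------------
  day_factors <- with_seed(seeds[5], {
    df <- stats::rnorm(config$n_run_days, sd = config$batch_sd)
    names(df) <- sprintf("day%d", seq_len(config$n_run_days))
    df
  })

  si <- match(design$strain, config$strains)
  vdd <- design$diet == "VDD"
  L <- matrix(rep(baseline_log, each = n), n, p,
              dimnames = list(design$sample_id, met_ids))
  L <- L + strain_effect_map[si, , drop = FALSE]
  diet_log <- numeric(p)
  diet_log[truth_diet$idx] <- log(2) * truth_diet$log2fc
  L[vdd, ] <- L[vdd, ] + rep(diet_log, each = sum(vdd))
  inter_full <- matrix(0, n_s, p)
  inter_full[, truth_diet$idx] <- truth_diet$inter
  L[vdd, ] <- L[vdd, ] + inter_full[si[vdd], , drop = FALSE]
  L <- L + day_factors[as.character(design$run_day)]

  sdlog <- sqrt(log(1 + config$noise_cv^2))
  if (sdlog > 0) {
    L <- L + with_seed(seeds[6], matrix(stats::rnorm(n * p, sd = sdlog), n, p))
  }
  values <- exp(L)

  ## --- LOD censoring: drop the lowest lod_quantile fraction per metabolite
  k_cens <- floor(config$lod_quantile * n)
  lod_censored <- NULL
  if (k_cens > 0) {
    cens_list <- vector("list", p)
    for (j in seq_len(p)) {
      ord <- order(values[, j])[seq_len(k_cens)]
      values[ord, j] <- NA_real_
      cens_list[[j]] <- data.frame(sample_id = design$sample_id[ord],
                                   metabolite = met_ids[j],
                                   stringsAsFactors = FALSE)
    }
    lod_censored <- do.call(rbind, cens_list)
  }

  truth <- list(
    diet_responsive_ids = met_ids[truth_diet$idx],
    diet_log2fc = stats::setNames(truth_diet$log2fc,
                                  met_ids[truth_diet$idx]),
    responsive_set = stats::setNames(truth_diet$set,
                                     met_ids[truth_diet$idx]),
    interaction_log = `colnames<-`(truth_diet$inter,
                                   met_ids[truth_diet$idx]),
    strain_effect_map = strain_effect_map,
    day_factors = day_factors,
    baseline_log = baseline_log,
    lod_censored = lod_censored)
  class(truth) <- "SyntheticTruth"

  list(abundance = abundance_matrix(values, run_day = design$run_day),
       design = design,
       truth = truth)
}

#' Simulate per-sample plasma 25(OH)D concentrations
#'
#' Draws log-normal 25(OH)D values (ng/mL) around per-strain VDS means; VDD
#' samples are drawn around the depleted mean `strain_mean * (1 - depletion)`.
#' With `cv = 0` values are the exact group means. All values are positive.
#'
#' @param design A [study_design()].
#' @param strain_means_vds Named numeric vector of VDS-arm mean 25(OH)D per
#'   strain (ng/mL); must cover every strain in the design.
#' @param depletion_frac Fractional reduction caused by the VDD diet; either
#'   a scalar or a named per-strain vector, each entry in \[0, 1\].
#' @param cv Coefficient of variation of the draw.
#' @param seed Integer seed.
#' @return Numeric vector of 25(OH)D values named by sample id.
#' @examples
#' d <- study_design(data.frame(sample_id = c("a", "b"), strain = "CC011",
#'                              diet = c("VDS", "VDD")))
#' simulate_25ohd(d, c(CC011 = 15.9), 0.34, cv = 0)
#' @export
simulate_25ohd <- function(design, strain_means_vds, depletion_frac,
                           cv = 0.2, seed = NULL) {
  design <- if (inherits(design, "StudyDesign")) design else
    study_design(design)
  strains <- levels(droplevels(design$strain))
  miss <- setdiff(strains, names(strain_means_vds))
  if (length(miss)) stop2("strain_means_vds lacks: ",
                          paste(miss, collapse = ", "))
  if (any(strain_means_vds < 0)) stop2("negative strain mean")
  if (length(depletion_frac) == 1L && is.null(names(depletion_frac))) {
    depletion_frac <- stats::setNames(rep(depletion_frac, length(strains)),
                                      strains)
  }
  if (any(depletion_frac < 0 | depletion_frac > 1)) {
    stop2("depletion_frac must lie in [0, 1]")
  }
  mu <- strain_means_vds[as.character(design$strain)]
  dep <- depletion_frac[as.character(design$strain)]
  target <- ifelse(design$diet == "VDD", mu * (1 - dep), mu)
  out <- with_seed(seed, {
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      # meanlog chosen so the arithmetic mean equals the target
      stats::rlnorm(nrow(design), meanlog = log(target) - sdlog^2 / 2,
                    sdlog = sdlog)
    } else {
      target
    }
  })
  stats::setNames(as.numeric(out), design$sample_id)
}

#' Build synthetic pathway-style metabolite sets
#'
#' Constructs named metabolite sets (a stand-in for curated pathway
#' databases) for enrichment testing. The first set is the designated
#' "responsive" positive control: it contains `floor(overlap_with_truth *
#' length(truth_ids))` truth metabolites, with the remainder filled from the
#' non-truth universe. Remaining sets are drawn uniformly from the universe.
#'
#' @param metabolite_ids Universe of metabolite identifiers.
#' @param set_sizes Integer vector of set sizes; the first entry is the
#'   responsive set.
#' @param overlap_with_truth Fraction of `truth_ids` placed in the responsive
#'   set, in \[0, 1\].
#' @param truth_ids Identifiers of truly responsive metabolites.
#' @param seed Integer seed.
#' @return Named list of character vectors (GMT-style sets); the positive
#'   control is named `"responsive_set"`.
#' @export
make_pathway_sets <- function(metabolite_ids, set_sizes,
                              overlap_with_truth = 0.8,
                              truth_ids = character(), seed = NULL) {
  if (any(set_sizes > length(metabolite_ids))) {
    stop2("set size exceeds number of metabolites")
  }
  if (overlap_with_truth < 0 || overlap_with_truth > 1) {
    stop2("overlap_with_truth must lie in [0, 1]")
  }
  if (length(setdiff(truth_ids, metabolite_ids))) {
    stop2("truth_ids must be a subset of metabolite_ids")
  }
  with_seed(seed, {
    sets <- vector("list", length(set_sizes))
    k_overlap <- floor(overlap_with_truth * length(truth_ids))
    k_overlap <- min(k_overlap, set_sizes[1])
    nontruth <- setdiff(metabolite_ids, truth_ids)
    members <- c(if (k_overlap > 0) sample(truth_ids, k_overlap),
                 sample(nontruth, set_sizes[1] - k_overlap))
    sets[[1]] <- sort(members)
    if (length(set_sizes) > 1L) {
      for (i in 2:length(set_sizes)) {
        sets[[i]] <- sort(sample(metabolite_ids, set_sizes[i]))
      }
    }
    names(sets) <- c("responsive_set",
                     if (length(set_sizes) > 1L)
                       sprintf("random_set_%02d", seq_along(set_sizes)[-1]))
    sets
  })
}
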