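# Strain-stratified and population-level univariate statistics:
# fold changes, percentage reduction, assumption-gated test battery,
# Brown-Mood median test, Tukey-Kramer HSD with compact letter display,
# and the VIP / fold-change robust-selection filter.

#' Fold change of group means (VDD / VDS)
#'
#' Ratio of arithmetic group means per metabolite, either over the whole
#' population or stratified by strain. A non-positive VDS mean makes the
#' ratio undefined; such entries are returned as `NA` and flagged rather
#' than dropped.
#'
#' @param m A fully imputed [abundance_matrix()].
#' @param d A [study_design()].
#' @param by_strain Compute per-strain fold changes instead of the
#'   population value.
#' @return Data frame with columns `metabolite`, (`strain`,) `mean_vds`,
#'   `mean_vdd`, `fold_change`, `undefined`.
#' @export
fold_change <- function(m, d, by_strain = FALSE) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  if (anyNA(m$values)) stop2("matrix must be fully imputed")
  d <- align_design(m, d)
  one_block <- function(rows_vds, rows_vdd, label = NULL) {
    if (!length(rows_vds) || !length(rows_vdd)) {
      stop2("fold change needs samples in both diet arms",
            if (!is.null(label)) paste0(" (strain ", label, ")"))
    }
    mv <- colMeans(m$values[rows_vds, , drop = FALSE])
    md <- colMeans(m$values[rows_vdd, , drop = FALSE])
    fc <- ifelse(mv > 0, md / mv, NA_real_)
    data.frame(metabolite = colnames(m$values),
               mean_vds = mv, mean_vdd = md, fold_change = fc,
               undefined = mv <= 0,
               row.names = NULL, stringsAsFactors = FALSE)
  }
  if (!by_strain) {
    return(one_block(which(d$diet == "VDS"), which(d$diet == "VDD")))
  }
  out <- lapply(levels(droplevels(d$strain)), function(s) {
    rows <- d$strain == s
    b <- one_block(which(rows & d$diet == "VDS"),
                   which(rows & d$diet == "VDD"), label = s)
    cbind(strain = s, b, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-sample percentage change relative to the strain VDS mean
#'
#' For each VDD sample, `100 * (value - VDS_mean) / VDS_mean` with the VDS
#' mean computed within the sample's strain; per-strain summaries are the
#' mean and SEM of the per-sample values. Used for quantities such as the
#' VDD-induced reduction in plasma 25(OH)D.
#'
#' @param values Numeric vector named by sample id (e.g. 25(OH)D in ng/mL).
#' @param d A [study_design()] covering those samples.
#' @return List with `per_sample` (data frame: sample_id, strain,
#'   pct_change) and `per_strain` (data frame: strain, mean_pct, sem_pct, n).
#' @examples
#' d <- study_design(data.frame(sample_id = c("a", "b", "c"),
#'                              strain = "CC011",
#'                              diet = c("VDS", "VDS", "VDD")))
#' pct_reduction_25ohd(c(a = 15, b = 16.8, c = 10.5), d)
#' @export
pct_reduction_25ohd <- function(values, d) {
  d <- if (inherits(d, "StudyDesign")) d else study_design(d)
  if (is.null(names(values))) stop2("`values` must be named by sample id")
  miss <- setdiff(d$sample_id, names(values))
  if (length(miss)) stop2("values missing for sample(s): ",
                          paste(miss, collapse = ", "))
  v <- values[d$sample_id]
  per_sample <- NULL
  per_strain <- NULL
  for (s in levels(droplevels(d$strain))) {
    vds <- v[d$strain == s & d$diet == "VDS"]
    vdd <- v[d$strain == s & d$diet == "VDD"]
    if (!length(vds)) stop2("strain ", s, " has no VDS samples")
    if (!length(vdd)) stop2("strain ", s, " has no VDD samples")
    vds_mean <- mean(vds)
    pct <- 100 * (vdd - vds_mean) / vds_mean
    per_sample <- rbind(per_sample, data.frame(
      sample_id = names(pct), strain = s, pct_change = unname(pct),
      stringsAsFactors = FALSE))
    per_strain <- rbind(per_strain, data.frame(
      strain = s, mean_pct = mean(pct),
      sem_pct = stats::sd(pct) / sqrt(length(pct)), n = length(pct),
      stringsAsFactors = FALSE))
  }
  list(per_sample = per_sample, per_strain = per_strain)
}

#' Assumption-gated univariate group comparison
#'
#' Implements the classical gated workflow: per-group Shapiro-Wilk tests of
#' normality at `alpha`; if any group fails, a rank test (Wilcoxon for 2
#' groups, Kruskal-Wallis for more). If normality holds, Bartlett's test of
#' equal variances decides between the pooled test (t / ANOVA) and the
#' unequal-variance Welch form (Welch t / Welch ANOVA). Groups too small or
#' degenerate for the parametric gates fall back to the rank test with a
#' warning; data with no variance at all return p = 1.
#'
#' @param groups List of numeric vectors (one per group), each of length
#'   >= 2.
#' @param alpha Gate significance level for Shapiro-Wilk and Bartlett.
#' @return List with `test` (name of the test used), `branch`
#'   (`"parametric"`, `"welch"`, `"nonparametric"` or `"degenerate"`), and
#'   `p`.
#' @export
gated_test <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop2("`groups` must be a list of at least two numeric vectors")
  }
  groups <- lapply(groups, as.numeric)
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop2("every group needs at least 2 observations")
  }
  k <- length(groups)
  all_values <- unlist(groups)
  if (stats::sd(all_values) == 0) {
    warn2("all observations identical; no evidence of group differences")
    return(list(test = "degenerate", branch = "degenerate", p = 1))
  }
  g <- factor(rep(seq_len(k), vapply(groups, length, 1L)))

  shapiro_ok <- function(x) {
    if (length(x) < 3L || stats::sd(x) == 0) return(NA)
    stats::shapiro.test(x)$p.value > alpha
  }
  normal <- vapply(groups, shapiro_ok, NA)
  if (anyNA(normal)) {
    warn2("group too small or constant for normality testing; ",
          "using the nonparametric branch")
    normal <- FALSE
  }
  if (!all(normal)) {
    if (k == 2L) {
      p <- stats::wilcox.test(groups[[1]], groups[[2]], exact = FALSE)$p.value
      return(list(test = "wilcoxon", branch = "nonparametric", p = p))
    }
    p <- stats::kruskal.test(all_values, g)$p.value
    return(list(test = "kruskal-wallis", branch = "nonparametric", p = p))
  }
  equal_var <- stats::bartlett.test(all_values, g)$p.value > alpha
  if (equal_var) {
    if (k == 2L) {
      p <- stats::t.test(groups[[1]], groups[[2]], var.equal = TRUE)$p.value
      return(list(test = "t", branch = "parametric", p = p))
    }
    p <- summary(stats::aov(all_values ~ g))[[1]][["Pr(>F)"]][1]
    return(list(test = "anova", branch = "parametric", p = p))
  }
  if (k == 2L) {
    p <- stats::t.test(groups[[1]], groups[[2]], var.equal = FALSE)$p.value
    return(list(test = "welch-t", branch = "welch", p = p))
  }
  p <- stats::oneway.test(all_values ~ g, var.equal = FALSE)$p.value
  list(test = "welch-anova", branch = "welch", p = p)
}

#' Brown-Mood median test
#'
#' Classifies every observation as above vs at-or-below the grand median and
#' tests independence of that classification from group membership: Fisher's
#' exact test when any expected cell count is below 5, otherwise the
#' chi-square test. All-equal data return p = 1.
#'
#' @param groups List of >= 2 numeric vectors.
#' @return List with `p`, `method`, and the `table` tested.
#' @export
median_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop2("`groups` must be a list of at least two numeric vectors")
  }
  groups <- lapply(groups, as.numeric)
  all_values <- unlist(groups)
  if (length(unique(all_values)) == 1L) {
    return(list(p = 1, method = "degenerate",
                table = NULL))
  }
  grand <- stats::median(all_values)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  above <- factor(all_values > grand, levels = c(FALSE, TRUE),
                  labels = c("le", "gt"))
  tab <- table(g, above)
  if (sum(tab[, "gt"]) == 0L) {
    # grand median equals the maximum: classification is uninformative
    return(list(p = 1, method = "degenerate", table = tab))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    p <- stats::fisher.test(tab)$p.value
    method <- "fisher"
  } else {
    p <- stats::chisq.test(tab, correct = FALSE)$p.value
    method <- "chi-square"
  }
  list(p = p, method = method, table = tab)
}

#' Tukey-Kramer HSD with compact letter display
#'
#' All pairwise comparisons of group means by the studentized-range (Tukey
#' HSD) test with Kramer's unequal-n correction, via `stats::TukeyHSD` on a
#' one-way `aov` fit. Groups are then labelled with letters by the
#' insert-and-absorb algorithm so that two groups share a letter exactly
#' when they are not significantly different at `alpha`.
#'
#' @param groups Named list of >= 3 numeric vectors, each of length >= 2.
#' @param alpha Significance level for the letter display.
#' @return List with `pairwise` (data frame: group1, group2, diff, p) and
#'   `letters` (named character vector, one entry per group).
#' @examples
#' g <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10, 10))
#' tukey_kramer(g)$letters
#' @export
tukey_kramer <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 3L) {
    stop2("Tukey-Kramer needs >= 3 groups; use gated_test() for two groups")
  }
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop2("every group needs at least 2 observations")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  fit <- stats::aov(y ~ g)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  pairwise <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                         diff = tk[, "diff"], p = tk[, "p adj"],
                         row.names = NULL, stringsAsFactors = FALSE)
  letters_out <- cld_insert_absorb(names(groups), pairwise, alpha)
  list(pairwise = pairwise, letters = letters_out)
}

# Compact letter display by insert-and-absorb: start from one letter set
# containing all groups; for each significantly different pair, split any
# set containing both; absorb sets nested in others; label sets a, b, c...
cld_insert_absorb <- function(group_names, pairwise, alpha) {
  sets <- list(group_names)
  sig <- pairwise[pairwise$p < alpha, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    a <- sig$group1[i]; b <- sig$group2[i]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb: drop sets contained in another set
    keep <- rep(TRUE, length(new_sets))
    for (u in seq_along(new_sets)) {
      for (v in seq_along(new_sets)) {
        if (u != v && keep[u] &&
            all(new_sets[[u]] %in% new_sets[[v]]) &&
            (length(new_sets[[u]]) < length(new_sets[[v]]) || u > v)) {
          keep[u] <- FALSE
        }
      }
    }
    sets <- new_sets[keep]
  }
  # order sets by the position of their first group for stable labels
  first_pos <- vapply(sets, function(s) min(match(s, group_names)), 1)
  sets <- sets[order(first_pos)]
  out <- stats::setNames(rep("", length(group_names)), group_names)
  for (i in seq_along(sets)) {
    for (gname in sets[[i]]) {
      out[gname] <- paste0(out[gname], letters[i])
    }
  }
  out
}

#' Combined VIP / fold-change robust selection
#'
#' Selects metabolites whose rmsVIP meets `vip_min`, and within those flags
#' the "robust" subset whose fold change meets `fc_min` symmetrically
#' (ratio or its reciprocal, so 1.5-fold decreases count like 1.5-fold
#' increases).
#'
#' @param vip_table Output of [compute_vip()].
#' @param response_table Population-level output of [fold_change()] (same
#'   metabolites).
#' @param vip_min rmsVIP threshold (inclusive).
#' @param fc_min Symmetric fold-change threshold (inclusive).
#' @return Data frame with columns `metabolite`, `rms_vip`, `fold_change`,
#'   `selected`, `robust`.
#' @export
robust_change_filter <- function(vip_table, response_table, vip_min = 1.5,
                                 fc_min = 1.5) {
  if (!setequal(vip_table$metabolite, response_table$metabolite)) {
    stop2("vip_table and response_table cover different metabolites")
  }
  rt <- response_table[match(vip_table$metabolite,
                             response_table$metabolite), , drop = FALSE]
  fc <- rt$fold_change
  sym_fc <- pmax(fc, 1 / fc)
  selected <- vip_table$rms_vip >= vip_min
  robust <- selected & !is.na(sym_fc) & sym_fc >= fc_min
  data.frame(metabolite = vip_table$metabolite,
             rms_vip = vip_table$rms_vip, fold_change = fc,
             selected = selected, robust = robust,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Strain-stratified response table
#'
#' Builds the per-metabolite summary used for reporting: population and
#' per-strain VDD/VDS fold changes, the gated diet test on population
#' values, a gated test of strain effect on the per-sample VDD response
#' (each VDD sample expressed relative to its strain's VDS mean), and
#' Tukey-Kramer letters over strains for that response. Raw p-values are
#' reported (significance read at `alpha`, as in the classical workflow);
#' Benjamini-Hochberg adjusted columns are added as a labelled extension.
#'
#' @param m A fully imputed [abundance_matrix()].
#' @param d A [study_design()].
#' @param alpha Significance level for letters.
#' @param metabolites Optional subset of metabolite ids to summarize.
#' @return List with `per_metabolite` (data frame: metabolite, fold_change,
#'   diet_test, diet_p, diet_q_bh, strain_effect_test, strain_effect_p,
#'   strain_effect_q_bh) , `per_strain` (long data frame of strain fold
#'   changes with Tukey letters).
#' @export
strain_response_table <- function(m, d, alpha = 0.05, metabolites = NULL) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  if (anyNA(m$values)) stop2("matrix must be fully imputed")
  d <- align_design(m, d)
  mets <- metabolites %||% colnames(m$values)
  bad <- setdiff(mets, colnames(m$values))
  if (length(bad)) stop2("unknown metabolite(s): ",
                         paste(utils::head(bad, 5), collapse = ", "))

  pop_fc <- fold_change(m, d)
  strain_fc <- fold_change(m, d, by_strain = TRUE)
  strains <- levels(droplevels(d$strain))
  vdd_idx <- d$diet == "VDD"

  per_met <- vector("list", length(mets))
  per_strain <- vector("list", length(mets))
  for (i in seq_along(mets)) {
    met <- mets[i]
    x <- m$values[, met]
    diet_res <- suppressWarnings(
      gated_test(list(VDS = x[d$diet == "VDS"], VDD = x[vdd_idx]), alpha))
    # per-sample VDD response relative to the strain's VDS mean
    resp_groups <- lapply(strains, function(s) {
      vds_mean <- mean(x[d$strain == s & d$diet == "VDS"])
      x[d$strain == s & vdd_idx] / vds_mean
    })
    names(resp_groups) <- strains
    ok_sizes <- all(vapply(resp_groups, length, 1L) >= 2L)
    strain_res <- if (length(strains) >= 2L && ok_sizes) {
      suppressWarnings(gated_test(resp_groups, alpha))
    } else list(test = NA_character_, p = NA_real_)
    letters_s <- if (length(strains) >= 3L && ok_sizes) {
      tryCatch(tukey_kramer(resp_groups, alpha)$letters,
               error = function(e) stats::setNames(rep(NA_character_,
                                                       length(strains)),
                                                   strains))
    } else stats::setNames(rep(NA_character_, length(strains)), strains)

    per_met[[i]] <- data.frame(
      metabolite = met,
      fold_change = pop_fc$fold_change[pop_fc$metabolite == met],
      diet_test = diet_res$test, diet_p = diet_res$p,
      strain_effect_test = strain_res$test, strain_effect_p = strain_res$p,
      stringsAsFactors = FALSE)
    sfc <- strain_fc[strain_fc$metabolite == met, , drop = FALSE]
    sfc$tukey_letter <- letters_s[sfc$strain]
    per_strain[[i]] <- sfc
  }
  per_met <- do.call(rbind, per_met)
  # BH-adjusted columns: an extension beyond the raw-alpha workflow
  per_met$diet_q_bh <- stats::p.adjust(per_met$diet_p, method = "BH")
  per_met$strain_effect_q_bh <- stats::p.adjust(per_met$strain_effect_p,
                                                method = "BH")
  list(per_metabolite = per_met, per_strain = do.call(rbind, per_strain))
}
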