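#' Per-metabolite OLS strain adjustment
#'
#' Fits, independently for each metabolite, the additive ordinary least
#' squares model `metabolite ~ diet + strain` with treatment (reference
#' level) coding — reference strain = `baseline`, reference diet = VDS — and
#' subtracts each sample's fitted strain coefficient from its value. Samples
#' of the baseline strain are left untouched. The diet term is deliberately
#' kept in the data (and strain-by-diet interactions remain in the
#' residuals), so a subsequent diet-supervised OPLS-DA sees the diet signal
#' free of strain main effects.
#'
#' @param m A fully imputed [abundance_matrix()] (no missing values).
#' @param d A [study_design()] covering every sample.
#' @param baseline Baseline (reference) strain label, untouched by the
#'   correction.
#' @return An object of class `AdjustmentModel`: list with `baseline`,
#'   `coefficients` (terms x metabolites matrix: intercept, diet contrast,
#'   strain contrasts), `corrected` (an `AbundanceMatrix`), and
#'   `rank_deficient` (logical; TRUE when some coefficients were
#'   inestimable and treated as zero).
#' @examples
#' sim <- simulate_study(synthetic_config(n_metabolites = 12, seed = 3))
#' pp <- preprocess_abundance(sim$abundance)
#' adj <- fit_and_correct(pp, sim$design, baseline = "CC011")
#' @export
fit_and_correct <- function(m, d, baseline = "CC011") {
  stopifnot(inherits(m, "AbundanceMatrix"))
  if (anyNA(m$values)) stop2("matrix must be fully imputed before adjustment")
  d <- align_design(m, d)
  if (!baseline %in% levels(d$strain)) {
    stop2("unknown baseline strain: ", baseline)
  }
  if (nlevels(droplevels(d$strain)) < 2L) {
    # single-strain input: every sample is baseline, nothing to subtract
    cm <- abundance_matrix(m$values, run_day = m$run_day,
                           status = union(m$status, "corrected"),
                           imputed = m$imputed)
    return(structure(list(baseline = baseline,
                          coefficients = matrix(nrow = 0, ncol = ncol(m$values)),
                          corrected = cm, rank_deficient = FALSE),
                     class = "AdjustmentModel"))
  }
  strain <- stats::relevel(droplevels(d$strain), ref = baseline)
  diet <- d$diet  # reference VDS by construction
  if (nlevels(droplevels(diet)) < 2L) stop2("both diets must be present")

  X <- stats::model.matrix(~ diet + strain)
  qrX <- qr(X)
  rank_deficient <- qrX$rank < ncol(X)
  if (rank_deficient) {
    warn2("rank-deficient design (confounded strain/diet); ",
          "inestimable coefficients treated as zero")
  }
  B <- qr.coef(qrX, m$values)          # terms x metabolites
  B[is.na(B)] <- 0
  strain_rows <- grep("^strain", rownames(B))
  corrected <- m$values -
    X[, strain_rows, drop = FALSE] %*% B[strain_rows, , drop = FALSE]
  # baseline-strain samples have all strain dummies 0: bit-identical input
  cm <- abundance_matrix(corrected, run_day = m$run_day,
                         status = union(m$status, "corrected"),
                         imputed = m$imputed)
  structure(list(baseline = baseline, coefficients = B, corrected = cm,
                 rank_deficient = rank_deficient),
            class = "AdjustmentModel")
}

#' @export
print.AdjustmentModel <- function(x, ...) {
  cat(sprintf("AdjustmentModel: baseline strain %s, %d metabolites, %d terms\n",
              x$baseline, ncol(x$coefficients), nrow(x$coefficients)))
  invisible(x)
}
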