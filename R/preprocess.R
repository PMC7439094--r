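#' Run-day median normalization
#'
#' Removes inter-day instrument drift by dividing each metabolite's values
#' within each run day by that metabolite's within-day median, i.e. shifting
#' every (metabolite, day) block's median to 1 and correcting each value
#' proportionately. Missing entries stay missing. Exactly invariant to
#' per-day multiplicative batch factors.
#'
#' @param m An [abundance_matrix()] with `run_day` set.
#' @return The normalized `AbundanceMatrix` (status gains `"normalized"`).
#' @examples
#' m <- abundance_matrix(matrix(c(2, 4, 6), 3, 1), run_day = rep("d1", 3))
#' normalize_run_day(m)$values
#' @export
normalize_run_day <- function(m) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  if (is.null(m$run_day)) stop2("run-day labels required for normalization")
  v <- m$values
  for (day in levels(m$run_day)) {
    rows <- which(m$run_day == day)
    block <- v[rows, , drop = FALSE]
    med <- apply(block, 2L, stats::median, na.rm = TRUE)
    bad <- which(is.na(med))
    if (length(bad)) {
      stop2("metabolite(s) entirely missing on ", day, ": ",
            paste(colnames(v)[utils::head(bad, 5L)], collapse = ", "))
    }
    zero <- which(med == 0)
    if (length(zero)) {
      stop2("within-day median is zero for metabolite(s) on ", day, ": ",
            paste(colnames(v)[utils::head(zero, 5L)], collapse = ", "))
    }
    v[rows, ] <- sweep(block, 2L, med, "/")
  }
  abundance_matrix(v, run_day = m$run_day,
                   status = union(m$status, "normalized"),
                   imputed = m$imputed)
}

#' Rescale each metabolite to unit median
#'
#' Divides each metabolite by its overall median over observed values, so
#' every metabolite has median 1 and widely ranging compounds become directly
#' comparable (equal weighting in downstream multivariate models).
#'
#' @param m An [abundance_matrix()].
#' @return The rescaled `AbundanceMatrix` (status gains `"rescaled"`).
#' @export
rescale_to_unit_median <- function(m) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  v <- m$values
  med <- apply(v, 2L, stats::median, na.rm = TRUE)
  if (anyNA(med)) {
    stop2("metabolite(s) with no observed values: ",
          paste(colnames(v)[utils::head(which(is.na(med)), 5L)],
                collapse = ", "))
  }
  if (any(med == 0)) {
    stop2("metabolite(s) with zero median: ",
          paste(colnames(v)[utils::head(which(med == 0), 5L)],
                collapse = ", "))
  }
  v <- sweep(v, 2L, med, "/")
  abundance_matrix(v, run_day = m$run_day,
                   status = union(m$status, "rescaled"),
                   imputed = m$imputed)
}

#' Impute missing values with the per-metabolite observed minimum
#'
#' Replaces each missing (below-LOD) entry of a metabolite with the minimum
#' observed value of that metabolite, the convention for left-censored
#' untargeted metabolomics data. No missing values remain afterwards and
#' imputed cells are flagged in the `imputed` mask.
#'
#' @param m An [abundance_matrix()].
#' @return The imputed `AbundanceMatrix` (status gains `"imputed"`).
#' @export
impute_minimum <- function(m) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  v <- m$values
  obs_min <- suppressWarnings(apply(v, 2L, min, na.rm = TRUE))
  if (any(!is.finite(obs_min))) {
    stop2("metabolite(s) with no observed values: ",
          paste(colnames(v)[utils::head(which(!is.finite(obs_min)), 5L)],
                collapse = ", "))
  }
  imputed <- is.na(v)
  for (j in which(colSums(imputed) > 0L)) {
    v[imputed[, j], j] <- obs_min[j]
  }
  abundance_matrix(v, run_day = m$run_day,
                   status = union(m$status, "imputed"),
                   imputed = imputed)
}

#' Full preprocessing pipeline
#'
#' Applies, in order, [normalize_run_day()], [rescale_to_unit_median()] and
#' [impute_minimum()]. After the first two steps every metabolite has unit
#' median over observed values; after the third no missingness remains.
#'
#' @param m An [abundance_matrix()] with `run_day` set.
#' @return The preprocessed `AbundanceMatrix`.
#' @export
preprocess_abundance <- function(m) {
  impute_minimum(rescale_to_unit_median(normalize_run_day(m)))
}
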