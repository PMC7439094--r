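#' Construct an abundance matrix
#'
#' The central data container of the pipeline: a samples x metabolites matrix
#' of non-negative abundances with `NA` marking values below the limit of
#' detection, an optional per-sample run-day (instrument batch) label, and a
#' provenance status recording which preprocessing stages have been applied.
#'
#' @param values Numeric matrix, samples in rows, metabolites in columns.
#'   Row and column names are the sample and metabolite identifiers.
#'   Values must be non-negative where present; `NA` encodes missingness.
#' @param run_day Optional vector (length = number of samples) of run-day
#'   labels; coerced to factor. Required by [normalize_run_day()].
#' @param status Character vector of provenance flags, a subset of
#'   `c("raw", "normalized", "rescaled", "imputed")`.
#' @param imputed Optional logical matrix marking cells filled in by
#'   [impute_minimum()].
#'
#' @return An object of class `AbundanceMatrix`: a list with elements
#'   `values`, `run_day`, `status`, `imputed`.
#' @examples
#' m <- abundance_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("s1", "s2"), c("m1", "m2", "m3"))))
#' @export
abundance_matrix <- function(values, run_day = NULL, status = "raw",
                             imputed = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop2("`values` must be a numeric matrix (samples x metabolites)")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("sample_", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("met_", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) stop2("duplicated sample ids")
  if (anyDuplicated(colnames(values))) stop2("duplicated metabolite ids")
  # strain-corrected residual matrices may legitimately go negative
  if (!"corrected" %in% status && any(values < 0, na.rm = TRUE)) {
    stop2("abundances must be non-negative where present")
  }
  if (!is.null(run_day)) {
    if (length(run_day) != nrow(values)) {
      stop2("`run_day` must have one entry per sample")
    }
    run_day <- as.factor(run_day)
    if (anyNA(run_day)) stop2("`run_day` must be defined for every sample")
  }
  bad <- setdiff(status,
                 c("raw", "normalized", "rescaled", "imputed", "corrected"))
  if (length(bad)) stop2("unknown status flag: ", paste(bad, collapse = ", "))
  structure(list(values = values, run_day = run_day, status = status,
                 imputed = imputed),
            class = "AbundanceMatrix")
}

#' @export
print.AbundanceMatrix <- function(x, ...) {
  cat(sprintf("AbundanceMatrix: %d samples x %d metabolites [%s]\n",
              nrow(x$values), ncol(x$values),
              paste(x$status, collapse = ",")))
  nmiss <- sum(is.na(x$values))
  cat(sprintf("  missing cells: %d (%.2f%%)\n", nmiss,
              100 * nmiss / length(x$values)))
  if (!is.null(x$run_day)) {
    cat("  run days:", paste(levels(x$run_day), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.AbundanceMatrix <- function(x) dim(x$values)

#' Construct and validate a study design table
#'
#' Per-sample experimental metadata: genetic strain, diet arm, and optionally
#' plasma 25(OH)D (ng/mL) and litter size. The diet factor must have exactly
#' the two arms `VDS` (vitamin D sufficient) and `VDD` (vitamin D deficient),
#' with `VDS` as the reference level.
#'
#' @param df Data frame with columns `sample_id`, `strain`, `diet`, and
#'   optionally `run_day`, `vitd_25ohd`, `litter_size`.
#' @return A validated data frame of class `StudyDesign`.
#' @export
study_design <- function(df) {
  need <- c("sample_id", "strain", "diet")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop2("design lacks column(s): ",
                          paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop2("duplicated sample ids in design")
  df$strain <- as.factor(as.character(df$strain))
  bad_diet <- setdiff(unique(as.character(df$diet)), c("VDS", "VDD"))
  if (length(bad_diet)) {
    stop2("unknown diet label(s): ", paste(bad_diet, collapse = ", "),
          " (expected VDS/VDD)")
  }
  df$diet <- factor(as.character(df$diet), levels = c("VDS", "VDD"))
  if (nlevels(droplevels(df$strain)) < 1L) stop2("no strains in design")
  class(df) <- c("StudyDesign", "data.frame")
  df
}

# Check that every abundance sample has a design row (and vice versa when
# strict); returns the design reordered to match the matrix rows.
align_design <- function(m, d) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  d <- if (inherits(d, "StudyDesign")) d else study_design(d)
  ids <- rownames(m$values)
  missing_rows <- setdiff(ids, d$sample_id)
  if (length(missing_rows)) {
    stop2("design lacks sample(s): ", paste(missing_rows, collapse = ", "))
  }
  d[match(ids, d$sample_id), , drop = FALSE]
}
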