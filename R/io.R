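# TSV / GMT readers and writers.  The on-disk dialect: tab-separated files
# with an optional block of leading "#" comment lines (used to stamp seed
# and configuration hash), missing abundances written as empty cells.

write_header <- function(con, seed = NULL, hash = NULL) {
  if (!is.null(seed)) writeLines(sprintf("# seed=%s", seed), con)
  if (!is.null(hash)) writeLines(sprintf("# config_hash=%s", hash), con)
}

#' Write / read an abundance matrix as TSV
#'
#' Rows are samples, columns metabolites; the first column is `sample_id`;
#' missing values are written as empty cells. Leading `#` lines carry the
#' seed and configuration hash and are skipped on read.
#'
#' @param m An [abundance_matrix()].
#' @param path Output file path.
#' @param seed,hash Optional provenance stamps written as comments.
#' @return `write_abundance` returns `path` invisibly.
#' @export
write_abundance <- function(m, path, seed = NULL, hash = NULL) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, seed, hash)
  df <- data.frame(sample_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance
#' @param design Optional [study_design()] providing `run_day` labels for
#'   the samples being read.
#' @return `read_abundance` returns an `AbundanceMatrix`.
#' @export
read_abundance <- function(path, design = NULL) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          na.strings = "", stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id") {
    stop2("abundance file must start with a sample_id column")
  }
  if (anyDuplicated(df$sample_id)) stop2("duplicated sample ids in ", path)
  v <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- df$sample_id
  run_day <- NULL
  if (!is.null(design)) {
    design <- if (inherits(design, "StudyDesign")) design else
      study_design(design)
    if (!"run_day" %in% names(design)) {
      stop2("design has no run_day column")
    }
    miss <- setdiff(rownames(v), design$sample_id)
    if (length(miss)) stop2("design lacks sample(s): ",
                            paste(miss, collapse = ", "))
    run_day <- design$run_day[match(rownames(v), design$sample_id)]
  }
  # negative entries can only come from a strain-corrected residual matrix
  status <- if (any(v < 0, na.rm = TRUE)) c("raw", "corrected") else "raw"
  abundance_matrix(v, run_day = run_day, status = status)
}

#' Write / read a study design table as TSV
#'
#' @param d A [study_design()].
#' @param path File path.
#' @param seed,hash Optional provenance stamps.
#' @return `write_design` returns `path` invisibly; `read_design` returns a
#'   `StudyDesign`.
#' @export
write_design <- function(d, path, seed = NULL, hash = NULL) {
  d <- if (inherits(d, "StudyDesign")) d else study_design(d)
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, seed, hash)
  utils::write.table(as.data.frame(d), con, sep = "\t", quote = FALSE,
                     na = "", row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", na.strings = "",
                          stringsAsFactors = FALSE)
  study_design(df)
}

#' Read / write GMT metabolite-set files
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a set are dropped with a warning (set sizes count unique members).
#'
#' @param path File path.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) stop2("malformed GMT line: ",
                                   substr(ln, 1, 60))
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warn2("duplicate member(s) in set '", fields[1],
            "' deduplicated")
      members <- unique(members)
    }
    sets[[fields[1]]] <- members
  }
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets))) stop2("sets must be named")
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
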