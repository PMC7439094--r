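#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH adjustment with monotonicity enforcement (delegates to
#' `stats::p.adjust` after validating the input).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and names as `p`.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stop2("p-values must be numeric")
  if (any(!is.na(p) & (p < 0 | p > 1))) stop2("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Over-representation analysis of a metabolite selection
#'
#' One-sided hypergeometric test, per metabolite set, of whether the
#' selected metabolites overlap the set more than expected by chance given
#' the analysis universe. Sets are intersected with the universe before
#' testing; sets with fewer than `min_set_size` members after intersection
#' are skipped (reported with `NA` p) so untestable sets do not dilute the
#' FDR. BH q-values are computed across the tested sets.
#'
#' @param selected Character vector of selected metabolite ids (must be a
#'   subset of `universe`).
#' @param sets Named list of character vectors (GMT-style metabolite sets).
#' @param universe Character vector: all metabolites eligible for selection
#'   (typically everything present after preprocessing).
#' @param min_set_size Minimum post-intersection set size to test.
#' @param alpha FDR significance threshold for the `significant` flag.
#' @return Data frame of class `enrichment_result` with one row per set:
#'   `set`, `universe_size`, `set_size`, `n_selected`, `overlap`, `p`, `q`,
#'   `significant`, `tested`.
#' @examples
#' ora(c("m1", "m2"), list(s = c("m1", "m2", "m3")), paste0("m", 1:10))
#' @export
ora <- function(selected, sets, universe, min_set_size = 2L, alpha = 0.05) {
  if (!length(universe)) stop2("empty universe")
  if (!length(selected)) stop2("empty selection")
  universe <- unique(universe)
  selected <- unique(selected)
  extra <- setdiff(selected, universe)
  if (length(extra)) {
    stop2("selected metabolite(s) outside the universe: ",
          paste(utils::head(extra, 5), collapse = ", "))
  }
  if (is.null(names(sets))) names(sets) <- paste0("set_", seq_along(sets))
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), universe)
    K <- length(members)
    k <- length(intersect(members, selected))
    tested <- K >= min_set_size
    p <- if (tested) {
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    } else NA_real_
    data.frame(set = nm, universe_size = N, set_size = K, n_selected = n,
               overlap = k, p = p, tested = tested,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(!out$tested)) {
    message(sum(!out$tested), " set(s) below minimum size after universe ",
            "intersection were skipped")
  }
  out$q <- NA_real_
  out$q[out$tested] <- bh_fdr(out$p[out$tested])
  out$significant <- !is.na(out$q) & out$q < alpha
  class(out) <- c("enrichment_result", "data.frame")
  out
}
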