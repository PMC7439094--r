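# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded package functions do not perturb the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive k reproducible sub-seeds (< 2^31) from one master seed, so that
# independent simulation components consume independent substreams.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# Polynomial rolling hash (mod 2^31 - 1) of a character scalar, reported as
# 8 hex digits.  Used to stamp output files with a configuration fingerprint;
# collision resistance beyond audit purposes is not required.
poly_hash32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  m <- 2^31 - 1
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% m
  sprintf("%08x", h)
}

# Hash an R object (config lists etc.) via its canonical JSON serialization.
config_hash <- function(x) {
  poly_hash32(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                            force = TRUE)))
}

stop2 <- function(...) stop(..., call. = FALSE)
warn2 <- function(...) warning(..., call. = FALSE)
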