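# OPLS-DA: orthogonal-signal-corrected NIPALS PLS with one predictive
# component, cross-validated Q2, and label-permutation significance.
#
# The model removes k_ortho components of X-variation orthogonal to the
# class vector before fitting a single predictive PLS component, so the
# predictive score concentrates the between-class separation and the
# orthogonal scores capture structured within-class (nuisance) variation.

# ---- low-level numerical core ---------------------------------------------

# Encode a 2-level class vector as +1/-1 (second factor level = +1).
encode_class <- function(y) {
  f <- droplevels(as.factor(y))
  if (nlevels(f) != 2L) stop2("exactly two classes required, got ",
                              nlevels(f))
  ifelse(f == levels(f)[2L], 1, -1)
}

scale_columns <- function(X, center, scale_mode) {
  sds <- switch(scale_mode,
    uv     = apply(X, 2L, stats::sd),
    pareto = sqrt(apply(X, 2L, stats::sd)),
    center = rep(1, ncol(X)),
    stop2("unknown scaling mode: ", scale_mode))
  sds[!is.finite(sds) | sds == 0] <- 1  # constant columns pass through
  list(center = center, scale = sds)
}

apply_scaling <- function(X, sc) {
  sweep(sweep(X, 2L, sc$center), 2L, sc$scale, "/")
}

# Core NIPALS fit on a pre-scaled X and centered y.  Returns weights,
# loadings and scores for k_ortho orthogonal components plus one predictive
# component.  Written lean: it runs hundreds of thousands of times inside
# cross-validation and permutation loops.
opls_core <- function(X, yc, k_ortho) {
  p <- ncol(X)
  ssx_tot <- sum(X * X)
  W_o <- P_o <- matrix(0, p, k_ortho)
  T_o <- matrix(0, nrow(X), k_ortho)
  ssx_o <- numeric(k_ortho)
  Xd <- X
  for (a in seq_len(k_ortho)) {
    w <- crossprod(Xd, yc)
    nw <- sqrt(sum(w * w))
    if (nw < 1e-12) stop2("k_ortho too large: X carries no further ",
                          "y-correlated variation (rank exhausted)")
    w <- w / nw
    t_p <- Xd %*% w
    p_l <- crossprod(Xd, t_p) / sum(t_p * t_p)
    w_o <- p_l - c(crossprod(w, p_l)) * w
    nwo <- sqrt(sum(w_o * w_o))
    if (nwo < 1e-12) {
      stop2("k_ortho = ", k_ortho, " exceeds the orthogonal rank of X")
    }
    w_o <- w_o / nwo
    t_o <- Xd %*% w_o
    p_o <- crossprod(Xd, t_o) / sum(t_o * t_o)
    Xd <- Xd - tcrossprod(t_o, p_o)
    W_o[, a] <- w_o; P_o[, a] <- p_o; T_o[, a] <- t_o
    ssx_o[a] <- sum(t_o * t_o) * sum(p_o * p_o)
  }
  w <- crossprod(Xd, yc)
  nw <- sqrt(sum(w * w))
  if (nw < 1e-12) stop2("no y-correlated variation left for the ",
                        "predictive component")
  w <- w / nw
  t_p <- Xd %*% w
  sst <- sum(t_p * t_p)
  p_l <- crossprod(Xd, t_p) / sst
  q <- sum(t_p * yc) / sst
  list(w = c(w), t = c(t_p), p = c(p_l), q = q,
       W_o = W_o, P_o = P_o, T_o = T_o,
       ssx_pred = sst * sum(p_l * p_l), ssx_o = ssx_o, ssx_tot = ssx_tot)
}

# Predict (in centered-y units) for new pre-scaled rows.
opls_predict_core <- function(core, Xnew) {
  k_ortho <- ncol(core$W_o)
  for (a in seq_len(k_ortho)) {
    t_o <- Xnew %*% core$W_o[, a]
    Xnew <- Xnew - tcrossprod(t_o, core$P_o[, a])
  }
  c(Xnew %*% core$w) * core$q
}

# Stratified fold assignment: within each class, shuffled members are dealt
# round-robin to folds, so every training fold retains both classes.
assign_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# Cross-validated PRESS given a fixed fold assignment.  Scaling is
# re-estimated on each training fold; test rows are passed through the
# training fold's orthogonal filter before prediction.
cv_press <- function(X, u, fold, k_ortho, scale_mode) {
  press <- 0
  for (f in sort(unique(fold))) {
    te <- fold == f
    Xtr <- X[!te, , drop = FALSE]
    sc <- scale_columns(Xtr, colMeans(Xtr), scale_mode)
    Xtr_s <- apply_scaling(Xtr, sc)
    utr <- u[!te]
    core <- opls_core(Xtr_s, utr - mean(utr), k_ortho)
    pred <- opls_predict_core(core, apply_scaling(X[te, , drop = FALSE], sc)) +
      mean(utr)
    press <- press + sum((u[te] - pred)^2)
  }
  press
}

# ---- user-facing fitting --------------------------------------------------

#' Fit an OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis for a
#' binary class: after centering and scaling, `k_ortho` NIPALS components of
#' X-variation orthogonal to the class vector are removed, then one
#' predictive PLS component is fitted. Reports R2Y (training class-variance
#' explained), per-component R2X, and a K-fold cross-validated Q2 in which
#' each held-out fold is filtered through the training fold's orthogonal
#' components before prediction.
#'
#' @param X Numeric matrix (samples x variables), no missing values.
#' @param y Binary class labels (factor, character or logical); the second
#'   factor level is encoded +1.
#' @param k_ortho Number of orthogonal components (0 = plain one-component
#'   PLS1-DA), or `"auto"` to add components while cross-validated Q2
#'   improves by more than 0.01.
#' @param scaling `"uv"` (unit variance, default), `"pareto"`, or
#'   `"center"`.
#' @param n_folds Number of cross-validation folds (stratified by class).
#' @param seed Integer seed governing the fold assignment.
#' @return An object of class `opls_model` with elements `weights`,
#'   `scores`, `loadings`, `y_loading`, orthogonal counterparts
#'   (`ortho_weights`, `ortho_scores`, `ortho_loadings`), `centers`,
#'   `scales`, `r2y`, `q2`, `r2x` (per component), `k_ortho`, `n_folds`,
#'   `scaling`, `seed`, `y_levels`, `fitted`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40 * 12), 40)
#' y <- rep(c("a", "b"), each = 20)
#' X[y == "b", 1:3] <- X[y == "b", 1:3] + 2
#' fit <- fit_oplsda(X, y, k_ortho = 1, seed = 5)
#' fit$q2
#' @export
fit_oplsda <- function(X, y, k_ortho = 1L, scaling = "uv", n_folds = 7L,
                       seed = NULL) {
  X <- as.matrix(X)
  if (anyNA(X)) stop2("X must not contain missing values")
  u <- encode_class(y)
  if (min(table(u)) < 2L) stop2("each class needs at least 2 samples")
  if (length(u) < n_folds) stop2("fewer samples than folds")

  if (identical(k_ortho, "auto")) {
    return(autoselect_k_ortho(X, y, scaling, n_folds, seed))
  }
  k_ortho <- as.integer(k_ortho)

  sc <- scale_columns(X, colMeans(X), scaling)
  Xs <- apply_scaling(X, sc)
  yc <- u - mean(u)
  core <- opls_core(Xs, yc, k_ortho)

  r2y <- 1 - sum((yc - core$t * core$q)^2) / sum(yc^2)
  fold <- with_seed(seed, assign_folds(u, n_folds))
  press <- cv_press(X, u, fold, k_ortho, scaling)
  q2 <- 1 - press / sum(yc^2)

  f <- droplevels(as.factor(y))
  structure(list(
    weights = core$w, scores = core$t, loadings = core$p,
    y_loading = core$q,
    ortho_weights = core$W_o, ortho_scores = core$T_o,
    ortho_loadings = core$P_o,
    centers = sc$center, scales = sc$scale, scaling = scaling,
    r2y = r2y, q2 = q2,
    r2x = c(pred = core$ssx_pred / core$ssx_tot,
            ortho = if (k_ortho > 0) core$ssx_o / core$ssx_tot else NULL),
    ssx_o = core$ssx_o, ssx_tot = core$ssx_tot,
    k_ortho = k_ortho, n_folds = as.integer(n_folds), seed = seed,
    y_levels = levels(f), y = u, fold = fold,
    fitted = core$t * core$q + mean(u),
    variable_ids = colnames(X) %||% paste0("x", seq_len(ncol(X)))),
    class = "opls_model")
}

autoselect_k_ortho <- function(X, y, scaling, n_folds, seed, max_k = 10L) {
  best <- fit_oplsda(X, y, k_ortho = 0L, scaling = scaling,
                     n_folds = n_folds, seed = seed)
  for (k in seq_len(max_k)) {
    cand <- tryCatch(
      fit_oplsda(X, y, k_ortho = k, scaling = scaling, n_folds = n_folds,
                 seed = seed),
      error = function(e) NULL)
    if (is.null(cand) || cand$q2 - best$q2 <= 0.01) break
    best <- cand
  }
  best
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "OPLS-DA model: %d samples, %d variables, %d orthogonal component(s)\n",
    length(x$scores), length(x$weights), x$k_ortho))
  cat(sprintf("  R2Y = %.3f   Q2 = %.3f (%d-fold CV)   scaling = %s\n",
              x$r2y, x$q2, x$n_folds, x$scaling))
  invisible(x)
}

#' Predict class scores from a fitted OPLS-DA model
#'
#' @param object A fitted `opls_model`.
#' @param newdata Matrix of new samples (same variables as training).
#' @param ... Unused.
#' @return Numeric predictions on the centered +1/-1 encoding scale.
#' @export
predict.opls_model <- function(object, newdata, ...) {
  Xs <- apply_scaling(as.matrix(newdata),
                      list(center = object$centers, scale = object$scales))
  k_ortho <- object$k_ortho
  for (a in seq_len(k_ortho)) {
    t_o <- Xs %*% object$ortho_weights[, a]
    Xs <- Xs - tcrossprod(t_o, object$ortho_loadings[, a])
  }
  c(Xs %*% object$weights) * object$y_loading + mean(object$y)
}

# ---- VIP ------------------------------------------------------------------

#' Variable importance to projection (VIP) scores
#'
#' Computes, per variable, the predictive VIP (for the single predictive
#' component this reduces to `sqrt(p) * |w_j|` with normalized weights), the
#' orthogonal VIP (squared orthogonal weights averaged with per-component
#' explained X-variance weights), and their root mean square
#' `rmsVIP = sqrt((VIP_pred^2 + VIP_ortho^2) / 2)`, the combined importance
#' measure used for feature selection. Both VIP columns have mean square 1
#' across variables by construction.
#'
#' @param model A fitted `opls_model`.
#' @param vip_min Selection threshold applied to rmsVIP (inclusive).
#' @return Data frame with columns `metabolite`, `vip_pred`, `vip_ortho`,
#'   `rms_vip`, `selected`. When `k_ortho = 0` the orthogonal VIP is `NA`
#'   and `rms_vip` equals `vip_pred`.
#' @export
compute_vip <- function(model, vip_min = 1.5) {
  if (!inherits(model, "opls_model")) stop2("`model` must be a fitted opls_model")
  p <- length(model$weights)
  vip_pred <- sqrt(p) * abs(model$weights)
  if (model$k_ortho > 0) {
    wts <- model$ssx_o / sum(model$ssx_o)
    vip_ortho <- sqrt(p * c(model$ortho_weights^2 %*% wts))
    rms_vip <- sqrt((vip_pred^2 + vip_ortho^2) / 2)
  } else {
    vip_ortho <- rep(NA_real_, p)
    rms_vip <- vip_pred
  }
  data.frame(metabolite = model$variable_ids,
             vip_pred = vip_pred, vip_ortho = vip_ortho, rms_vip = rms_vip,
             selected = rms_vip >= vip_min,
             stringsAsFactors = FALSE)
}

# ---- permutation test -----------------------------------------------------

#' Label-permutation significance of an OPLS-DA model
#'
#' Refits the full model — including cross-validation — under `n_perm`
#' uniform permutations of the class labels and reports
#' `pQ2 = (1 + #\{Q2_perm >= Q2_obs\}) / (1 + n_perm)` (add-one counting, so
#' p-values are never zero), and the analogous `pR2Y`. The cross-validation
#' partition is drawn once from the seed and reused across permutations so
#' that only the label assignment varies.
#'
#' @param X,y,k_ortho,scaling,n_folds As in [fit_oplsda()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed governing folds and permutations.
#' @return An object of class `permutation_result`: list with `q2`, `r2y`
#'   (observed), `perm_q2`, `perm_r2y` (length `n_perm`), `p_q2`, `p_r2y`,
#'   `n_perm`, `seed`, and the observed `model`.
#' @export
permutation_test <- function(X, y, k_ortho = 1L, scaling = "uv",
                             n_folds = 7L, n_perm = 1000L, seed = NULL) {
  if (n_perm < 1L) stop2("n_perm must be at least 1")
  X <- as.matrix(X)
  u <- encode_class(y)
  k_ortho <- as.integer(k_ortho)

  with_seed(seed, {
    fold <- assign_folds(u, n_folds)
    sc <- scale_columns(X, colMeans(X), scaling)
    Xs <- apply_scaling(X, sc)
    # pre-scale each training/test fold once: X never changes under
    # permutation, only the labels do
    fold_data <- lapply(sort(unique(fold)), function(f) {
      te <- fold == f
      Xtr <- X[!te, , drop = FALSE]
      sctr <- scale_columns(Xtr, colMeans(Xtr), scaling)
      list(te = which(te), tr = which(!te),
           Xtr_s = apply_scaling(Xtr, sctr),
           Xte_s = apply_scaling(X[te, , drop = FALSE], sctr))
    })
    tss <- function(u) sum((u - mean(u))^2)
    eval_labels <- function(u) {
      yc <- u - mean(u)
      core <- opls_core(Xs, yc, k_ortho)
      r2y <- 1 - sum((yc - core$t * core$q)^2) / sum(yc^2)
      press <- 0
      for (fd in fold_data) {
        utr <- u[fd$tr]
        core_f <- opls_core(fd$Xtr_s, utr - mean(utr), k_ortho)
        pred <- opls_predict_core(core_f, fd$Xte_s) + mean(utr)
        press <- press + sum((u[fd$te] - pred)^2)
      }
      c(r2y = r2y, q2 = 1 - press / tss(u))
    }
    obs <- eval_labels(u)
    perm <- vapply(seq_len(n_perm), function(i) eval_labels(sample(u)),
                   numeric(2))
    p_q2 <- (1 + sum(perm["q2", ] >= obs["q2"])) / (1 + n_perm)
    p_r2y <- (1 + sum(perm["r2y", ] >= obs["r2y"])) / (1 + n_perm)
    structure(list(q2 = unname(obs["q2"]), r2y = unname(obs["r2y"]),
                   perm_q2 = unname(perm["q2", ]),
                   perm_r2y = unname(perm["r2y", ]),
                   p_q2 = p_q2, p_r2y = p_r2y,
                   n_perm = as.integer(n_perm), seed = seed),
              class = "permutation_result")
  })
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (%d permutations):\n", x$n_perm))
  cat(sprintf("  Q2 = %.3f  (pQ2 = %.4g)\n", x$q2, x$p_q2))
  cat(sprintf("  R2Y = %.3f (pR2Y = %.4g)\n", x$r2y, x$p_r2y))
  invisible(x)
}

# ---- PCA and one-vs-rest strain signatures --------------------------------

#' Principal components analysis of an abundance matrix
#'
#' Thin wrapper around the singular value decomposition of the centered
#' (optionally unit-variance scaled) matrix, returning scores, loadings and
#' the proportion of variance explained.
#'
#' @param X Numeric matrix (samples x variables), no missing values.
#' @param n_components Number of components to return.
#' @param scale. Scale columns to unit variance before decomposition.
#' @return List with `scores`, `loadings`, `explained_variance` (proportions,
#'   non-increasing), `sdev`.
#' @export
run_pca <- function(X, n_components = 2L, scale. = FALSE) {
  X <- as.matrix(X)
  if (anyNA(X)) stop2("X must not contain missing values")
  pr <- stats::prcomp(X, center = TRUE, scale. = scale.)
  rank_x <- sum(pr$sdev > max(pr$sdev) * 1e-12)
  if (n_components > rank_x) {
    stop2("n_components (", n_components, ") exceeds the rank of X (",
          rank_x, ")")
  }
  keep <- seq_len(n_components)
  list(scores = pr$x[, keep, drop = FALSE],
       loadings = pr$rotation[, keep, drop = FALSE],
       explained_variance = (pr$sdev^2 / sum(pr$sdev^2))[keep],
       sdev = pr$sdev[keep])
}

#' One-strain-vs-rest OPLS-DA signature within a diet stratum
#'
#' Restricts the data to one diet arm, supervises an OPLS-DA model with
#' "target strain vs all other strains", and reports the metabolites with
#' predictive VIP at or above the threshold as the strain's metabolomic
#' signature within that stratum.
#'
#' @param m A fully imputed [abundance_matrix()].
#' @param d A [study_design()].
#' @param strain Target strain label.
#' @param diet_stratum `"VDS"` or `"VDD"`.
#' @param vip_min Signature threshold on the predictive VIP (inclusive).
#' @param k_ortho,scaling,n_folds,seed As in [fit_oplsda()].
#' @return List with `model` (`opls_model`), `vip` (VIP table; selection on
#'   `vip_pred`), and `signature` (character vector of selected metabolites).
#' @export
strain_signature <- function(m, d, strain, diet_stratum = c("VDS", "VDD"),
                             vip_min = 1.5, k_ortho = 1L, scaling = "uv",
                             n_folds = 7L, seed = NULL) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  diet_stratum <- match.arg(diet_stratum)
  d <- align_design(m, d)
  keep <- d$diet == diet_stratum
  ds <- d[keep, , drop = FALSE]
  if (!strain %in% as.character(ds$strain)) {
    stop2("strain ", strain, " absent from the ", diet_stratum, " stratum")
  }
  if (all(as.character(ds$strain) == strain)) {
    stop2("stratum contains only strain ", strain,
          "; one-vs-rest model needs at least one other strain")
  }
  X <- m$values[keep, , drop = FALSE]
  if (anyNA(X)) stop2("matrix must be fully imputed")
  y <- factor(ifelse(as.character(ds$strain) == strain, strain, "rest"),
              levels = c("rest", strain))
  model <- fit_oplsda(X, y, k_ortho = k_ortho, scaling = scaling,
                      n_folds = n_folds, seed = seed)
  vip <- compute_vip(model, vip_min = vip_min)
  # strain signatures select on the predictive VIP alone
  vip$selected <- vip$vip_pred >= vip_min
  list(model = model, vip = vip,
       signature = vip$metabolite[vip$selected])
}
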