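#' Partial least squares regression (NIPALS, single response)
#'
#' Latent-component regression of a desirability response on UV-scaled
#' descriptors with a centered response: suited to descriptor matrices that
#' are wide and collinear. For each component, the weight vector is the
#' (normalized) covariance direction `X'y`, scores `t = Xw`, followed by
#' deflation of X and y. Regression coefficients are back-transformed to
#' the original descriptor scale.
#'
#' @param x compound x descriptor numeric matrix (no constant columns).
#' @param y response vector; rows with missing y are dropped.
#' @param n_components number of latent components (>= 1).
#' @return A `pls_model`: `n_components`, `weights`, `loadings`,
#'   `y_loadings`, `scores`, `coefficients`/`intercept` (original scale),
#'   `coefficients_scaled`, `r2`, scaling metadata, `n`.
#' @export
pls_fit <- function(x, y, n_components = 2L) {
  stopifnot(is.matrix(x))
  ok <- !is.na(y)
  x <- x[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y); p <- ncol(x)
  if (n_components < 1L || n_components > min(n - 1L, p))
    stop("n_components must be in [1, min(rows - 1, cols)]")
  if (stats::sd(y) == 0) stop("response has zero variance")
  xs <- uv_scale(x)
  ctr <- attr(xs, "center"); scl <- attr(xs, "scale")
  yc <- y - mean(y)

  W <- P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- numeric(n_components)
  Xd <- xs; yd <- yc
  for (a in seq_len(n_components)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { n_components <- a - 1L; break }
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    pvec <- crossprod(Xd, t) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - t %*% t(pvec)
    yd <- yd - qa * t
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- t; q[a] <- qa
  }
  if (n_components < 1L) stop("response uncorrelated with all descriptors")
  W <- W[, seq_len(n_components), drop = FALSE]
  P <- P[, seq_len(n_components), drop = FALSE]
  Tm <- Tm[, seq_len(n_components), drop = FALSE]
  q <- q[seq_len(n_components)]

  b_scaled <- drop(W %*% solve(crossprod(P, W), q))
  b <- b_scaled / scl
  intercept <- mean(y) - sum(b * ctr)
  fitted <- drop(x %*% b) + intercept
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)

  dimnames(W) <- dimnames(P) <- list(colnames(x), paste0("comp", seq_len(n_components)))
  structure(list(
    n_components = n_components,
    weights = W, loadings = P, y_loadings = q, scores = Tm,
    coefficients = stats::setNames(b, colnames(x)),
    coefficients_scaled = stats::setNames(b_scaled, colnames(x)),
    intercept = intercept, r2 = r2,
    center = ctr, scale = scl, n = n), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("PLS model:", x$n_components, "component(s), n =", x$n,
      ", R2 =", round(x$r2, 4), "\n")
  invisible(x)
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  miss <- setdiff(names(object$coefficients), colnames(newdata))
  if (length(miss)) stop("missing descriptor column(s): ",
                         paste(miss, collapse = ", "))
  drop(newdata[, names(object$coefficients), drop = FALSE] %*%
         object$coefficients) + object$intercept
}

#' k-fold cross-validated Q-squared
#'
#' `Q2 = 1 - PRESS / SS_total`, where PRESS accumulates squared prediction
#' errors over `k` folds (each fold predicted by a model refit on the
#' remaining folds) and SS_total is about the full-data mean. Fold
#' assignment is a seeded random balanced partition; the published
#' validation uses seven folds.
#'
#' @param x descriptor matrix.
#' @param y response vector; rows with missing y are dropped.
#' @param fit_fun fitting function `function(x, y) -> model` supporting
#'   `predict(model, x)`; see [pls_spec()] and [mlr_spec()].
#' @param k number of folds (default 7).
#' @param seed integer seed for the fold partition.
#' @return list `(q2, press, press_per_fold, ss_total, folds)`.
#' @export
kfold_q2 <- function(x, y, fit_fun, k = 7L, seed = 1L) {
  ok <- !is.na(y)
  x <- x[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y)
  if (k < 2L || k > n) stop("k must be in [2, rows]")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  folds <- sample(rep(seq_len(k), length.out = n))
  press_f <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    model <- fit_fun(x[tr, , drop = FALSE], y[tr])
    pred <- stats::predict(model, x[!tr, , drop = FALSE])
    press_f[f] <- sum((y[!tr] - pred)^2)
  }
  ss_tot <- sum((y - mean(y))^2)
  list(q2 = 1 - sum(press_f) / ss_tot, press = sum(press_f),
       press_per_fold = press_f, ss_total = ss_tot, folds = folds)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Model-specification helpers for cross-validation
#'
#' Thin closures binding fit parameters, for use with [kfold_q2()].
#'
#' @param n_components PLS components.
#' @return A fitting function `function(x, y) -> model`.
#' @export
pls_spec <- function(n_components = 2L) {
  function(x, y) pls_fit(x, y, n_components = n_components)
}

#' @rdname pls_spec
#' @param ... arguments passed on to [stepwise_mlr_fit()].
#' @export
mlr_spec <- function(...) {
  function(x, y) suppressWarnings(stepwise_mlr_fit(x, y, ...))
}

#' Choose the PLS component count by cross-validated Q-squared
#'
#' Components are added while the seven-fold Q2 improves by at least
#' `min_gain`; the returned count maximizes Q2 over the accepted range.
#'
#' @param x descriptor matrix.
#' @param y response.
#' @param max_components upper bound on components.
#' @param k folds (default 7).
#' @param seed fold seed.
#' @param min_gain minimum Q2 improvement to keep adding (default 0.01).
#' @return list `(n_components, q2, table)`.
#' @export
choose_pls_ncomp <- function(x, y, max_components = 10L, k = 7L, seed = 1L,
                             min_gain = 0.01) {
  ok <- !is.na(y)
  kmax <- min(max_components, sum(ok) - ceiling(sum(ok) / k) - 1L, ncol(x))
  if (kmax < 1L) stop("too few rows to cross-validate a PLS model")
  q2 <- numeric(0)
  for (a in seq_len(kmax)) {
    q2[a] <- kfold_q2(x, y, pls_spec(a), k = k, seed = seed)$q2
    if (a > 1L && q2[a] - q2[a - 1L] < min_gain) break
  }
  best <- which.max(q2)
  list(n_components = best, q2 = q2[best],
       table = data.frame(n_components = seq_along(q2), q2 = q2))
}

#' Predict desirability for new compounds
#'
#' Linear prediction from a fitted `mlr_model` or `pls_model`, optionally
#' clipped to the feasible desirability range [0.1, 0.9].
#'
#' @param model fitted model.
#' @param newdata compound x descriptor matrix containing the model's
#'   descriptors.
#' @param clip clip predictions into [0.1, 0.9] (default `TRUE`).
#' @return Named numeric vector of predicted D-values.
#' @export
predict_desirability <- function(model, newdata, clip = TRUE) {
  pred <- stats::predict(model, newdata)
  if (clip) pred <- pmin(0.9, pmax(0.1, pred))
  stats::setNames(pred, rownames(newdata))
}
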