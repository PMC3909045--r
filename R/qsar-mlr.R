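#' Stepwise multiple linear regression on probability-of-F thresholds
#'
#' Forward-and-backward selection of descriptors for a desirability
#' response. At each forward step, every candidate's partial-F probability
#' given the current model is computed (via residual partial correlations);
#' the best candidate enters if it is significant at `p_enter` *at the step
#' level*, i.e. after a Sidak adjustment for the number of candidates
#' scanned, so a pure-noise scan enters a variable with probability
#' `p_enter` per step regardless of how many descriptors are offered.
#' After each entry, included variables whose partial-F probability exceeds
#' `p_remove` are removed (worst first). Iteration stops at a fixed point.
#' Ties break toward the lowest column index. Candidates numerically
#' collinear with the current model (residual variance below `collinear_tol`)
#' are skipped, so a duplicated column is never co-selected.
#'
#' @param x compound x descriptor numeric matrix.
#' @param y response vector (e.g. an axis D-value); rows with missing y are
#'   dropped.
#' @param p_enter probability-of-F to enter (default 0.05).
#' @param p_remove probability-of-F to remove (default 0.10);
#'   must exceed `p_enter`.
#' @param entry_adjust `"sidak"` (default, step-level type-I control) or
#'   `"none"` (classical per-candidate rule).
#' @param max_steps safety bound on selection iterations.
#' @param collinear_tol residual-variance threshold for the collinearity
#'   guard.
#' @return An `mlr_model`: `selected` (descriptor names), `coefficients`
#'   and `intercept` on the original descriptor scale, `coefficients_scaled`
#'   (per unit of UV-scaled descriptor), `r2`, `trace` (step log),
#'   `center`/`scale` metadata, `n`.
#' @export
stepwise_mlr_fit <- function(x, y, p_enter = 0.05, p_remove = 0.10,
                             entry_adjust = c("sidak", "none"),
                             max_steps = 100L, collinear_tol = 1e-10) {
  entry_adjust <- match.arg(entry_adjust)
  stopifnot(is.matrix(x), p_enter < p_remove)
  ok <- !is.na(y)
  x <- x[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y)
  if (n < 10L) stop("need >= 10 complete-case rows, got ", n)
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))

  sdx <- apply(x, 2L, stats::sd)
  usable <- which(sdx > 0)
  sel <- integer(0)
  trace <- list()
  step <- 0L

  partial_p <- function(candidates, sel) {
    # p-of-F for adding each candidate to the model holding `sel`
    qx <- qr(cbind(1, x[, sel, drop = FALSE]))
    ry <- qr.resid(qx, y)
    rc <- qr.resid(qx, x[, candidates, drop = FALSE])
    rss_c <- colSums(rc^2)
    df2 <- n - length(sel) - 2L
    p <- rep(NA_real_, length(candidates))
    for (i in seq_along(candidates)) {
      if (rss_c[i] < collinear_tol * n) next  # collinear with current model
      r <- sum(ry * rc[, i]) / sqrt(sum(ry^2) * rss_c[i])
      r2 <- min(r^2, 1)
      f <- if (r2 >= 1) Inf else r2 * df2 / (1 - r2)
      p[i] <- stats::pf(f, 1L, df2, lower.tail = FALSE)
    }
    p
  }

  repeat {
    step <- step + 1L
    if (step > max_steps) break
    changed <- FALSE

    cand <- setdiff(usable, sel)
    if (length(cand) > 0L && n - length(sel) - 2L >= 1L) {
      p <- partial_p(cand, sel)
      if (any(!is.na(p))) {
        best <- which.min(p)          # first index on ties
        p_best <- p[best]
        m <- sum(!is.na(p))
        p_step <- if (entry_adjust == "sidak") 1 - (1 - p_best)^m else p_best
        if (!is.na(p_step) && p_step < p_enter) {
          sel <- c(sel, cand[best])
          trace[[length(trace) + 1L]] <- data.frame(
            step = step, action = "enter", variable = colnames(x)[cand[best]],
            p_value = p_best, p_step = p_step, stringsAsFactors = FALSE)
          changed <- TRUE
        }
      }
    }

    # backward passes until all retained variables are significant
    while (length(sel) > 0L) {
      fit <- stats::lm.fit(cbind(1, x[, sel, drop = FALSE]), y)
      df2 <- n - length(sel) - 1L
      if (df2 < 1L) break
      sigma2 <- sum(fit$residuals^2) / df2
      xtx_inv <- chol2inv(fit$qr$qr[seq_len(length(sel) + 1L), , drop = FALSE])
      se <- sqrt(sigma2 * diag(xtx_inv))[-1L]
      tval <- fit$coefficients[-1L] / se
      p_out <- 2 * stats::pt(-abs(tval), df2)
      worst <- which.max(p_out)
      if (p_out[worst] > p_remove) {
        trace[[length(trace) + 1L]] <- data.frame(
          step = step, action = "remove", variable = colnames(x)[sel[worst]],
          p_value = p_out[worst], p_step = p_out[worst], stringsAsFactors = FALSE)
        sel <- sel[-worst]
        changed <- TRUE
      } else break
    }

    if (!changed) break
  }

  if (length(sel) == 0L) {
    warning("no descriptor passed the entry threshold; intercept-only model")
    model <- structure(list(
      selected = character(0),
      coefficients = numeric(0), intercept = mean(y),
      coefficients_scaled = numeric(0),
      r2 = 0, trace = bind_trace(trace),
      center = numeric(0), scale = numeric(0), n = n), class = "mlr_model")
    return(model)
  }

  sel <- sort(sel)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, x[, sel, drop = FALSE]), y)
  coefs <- fit$coefficients[-1L]
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  structure(list(
    selected = colnames(x)[sel],
    coefficients = stats::setNames(coefs, colnames(x)[sel]),
    intercept = unname(fit$coefficients[1L]),
    coefficients_scaled = stats::setNames(coefs * sdx[sel], colnames(x)[sel]),
    r2 = r2,
    trace = bind_trace(trace),
    center = colMeans(x[, sel, drop = FALSE]),
    scale = sdx[sel],
    n = n), class = "mlr_model")
}

bind_trace <- function(trace) {
  if (length(trace) == 0L)
    return(data.frame(step = integer(), action = character(),
                      variable = character(), p_value = numeric(),
                      p_step = numeric()))
  out <- do.call(rbind, trace)
  rownames(out) <- NULL
  out
}

#' @export
print.mlr_model <- function(x, ...) {
  cat("Stepwise MLR model:", length(x$selected), "descriptor(s), n =",
      x$n, ", R2 =", round(x$r2, 4), "\n")
  if (length(x$selected)) {
    print(round(x$coefficients, 4))
  }
  invisible(x)
}

#' @export
predict.mlr_model <- function(object, newdata, ...) {
  if (length(object$selected) == 0L)
    return(rep(object$intercept, nrow(newdata)))
  miss <- setdiff(object$selected, colnames(newdata))
  if (length(miss)) stop("missing descriptor column(s): ",
                         paste(miss, collapse = ", "))
  drop(newdata[, object$selected, drop = FALSE] %*% object$coefficients) +
    object$intercept
}
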