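#' Local weighted regression (tricube kernel) with pointwise standard errors
#'
#' At each evaluation point `x0`, a polynomial of the given degree is fit by
#' weighted least squares over the `ceiling(span * n)` nearest data points,
#' with tricube weights `(1 - (d/d_max)^3)^3` scaled by the window radius.
#' The fit at `x0` is a linear smoother `l(x0)' y`; the residual variance is
#' estimated from the fitted values at the data points with
#' `df = n - tr(L)`, and the pointwise standard error is
#' `sigma * ||l(x0)||`. Exactly linear data are reproduced exactly by
#' `degree = 1`; constant data give zero standard errors.
#'
#' @param distances numeric predictor (e.g. annulus mid-radius in µm).
#' @param values numeric response, same length.
#' @param span fraction of points in each local window, in (0, 1].
#' @param degree local polynomial degree (0, 1 or 2; default 1).
#' @param eval_at evaluation points (default: the data points).
#' @return tibble `x`, `fitted`, `se`; residual sigma and trace in
#'   attributes `sigma` / `trace_hat`.
#' @export
loess_curve <- function(distances, values, span = 0.75, degree = 1,
                        eval_at = NULL) {
  x <- as.numeric(distances); y <- as.numeric(values)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < max(4, degree + 2)) abort("too few points for the local fit")
  if (span <= 0 || span > 1) abort("`span` must be in (0, 1]")
  if (length(unique(x)) == 1) abort("degenerate design: all x equal")
  q <- min(n, ceiling(span * n))
  if (q < degree + 1) abort("window smaller than degree + 1; raise `span`")
  eval_at <- eval_at %||% x

  lvec <- function(x0) {
    d <- abs(x - x0)
    dq <- sort(d, partial = q)[q]
    w <- numeric(n)
    inw <- d <= dq + 1e-12
    if (dq == 0) w[inw] <- 1 else
      w[inw] <- (1 - pmin(d[inw] / dq, 1)^3)^3
    X <- outer(x - x0, 0:degree, `^`)
    XtW <- t(X * w)
    beta_mat <- solve(XtW %*% X + diag(1e-12, degree + 1), XtW)
    beta_mat[1, ]  # row giving the local intercept = fit at x0
  }
  L_eval <- t(vapply(eval_at, lvec, numeric(n)))
  L_data <- t(vapply(x, lvec, numeric(n)))
  fitted_data <- as.numeric(L_data %*% y)
  tr <- sum(diag(L_data))
  df <- max(n - tr, 1)
  sigma <- sqrt(sum((y - fitted_data)^2) / df)
  out <- tibble(x = eval_at,
                fitted = as.numeric(L_eval %*% y),
                se = sigma * sqrt(rowSums(L_eval^2)))
  attr(out, "sigma") <- sigma
  attr(out, "trace_hat") <- tr
  out
}
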