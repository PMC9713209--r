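#' Local regression (LOESS) smoother
#'
#' Local polynomial weighted least squares with tricube weights over the
#' nearest span-fraction of the data, evaluated on a query grid. Degree 1
#' (local linear), span 0.75 by default.
#'
#' @param x,y data points (at least degree + 2 of them).
#' @param span fraction of points in each local window, in (0, 1].
#' @param degree local polynomial degree (0, 1 or 2).
#' @param grid query points; defaults to a 100-point grid over range(x).
#' @return data.frame with \code{x} (the grid) and \code{fitted}.
#' @export
loess_fit <- function(x, y, span = 0.75, degree = 1, grid = NULL) {
  stopifnot(length(x) == length(y), !anyNA(x), !anyNA(y),
            span > 0, span <= 1, degree %in% 0:2,
            length(x) >= degree + 2)
  n <- length(x)
  if (is.null(grid)) grid <- seq(min(x), max(x), length.out = 100)
  q <- max(degree + 1, ceiling(span * n))
  fitted <- vapply(grid, function(x0) {
    d <- abs(x - x0)
    h <- sort(d)[q]
    if (h == 0) {
      # window collapses onto x0 (replicated x); local fit is their mean
      return(mean(y[d == 0]))
    }
    w <- (1 - pmin(d / h, 1)^3)^3
    use <- w > 0
    if (degree >= 1 && length(unique(x[use])) < degree + 1)
      stop("degenerate local design: all x equal in a window", call. = FALSE)
    X <- outer(x[use] - x0, 0:degree, `^`)
    wl <- w[use]
    beta <- solve(crossprod(X * sqrt(wl)), crossprod(X, wl * y[use]))
    beta[1]
  }, numeric(1))
  data.frame(x = grid, fitted = fitted)
}
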