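#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test with fixed margins. The two-sided p-value uses
#' the point-probability method (sum of the probabilities of all tables no
#' more probable than the observed one); a central method (doubling the
#' smaller tail, capped at 1) is available.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param method "point" (default) or "central".
#' @return \code{test_result} with \code{statistic} = odds-ratio estimate
#'   (cross-product ratio), \code{p_value}.
#' @export
fisher_exact <- function(table, method = c("point", "central")) {
  method <- match.arg(method)
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  m <- a + b        # row 1 total
  n2 <- c_ + d      # row 2 total
  k <- a + c_       # column 1 total
  lo <- max(0, k - n2)
  hi <- min(m, k)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  p <- if (method == "point") {
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  } else {
    p_low  <- sum(probs[support <= a])
    p_high <- sum(probs[support >= a])
    min(1, 2 * min(p_low, p_high))
  }
  or <- if (b * c_ > 0) (a * d) / (b * c_) else Inf
  structure(list(name = "Fisher exact", statistic = or, p_value = min(1, p),
                 df = NA_real_, method = method),
            class = "test_result")
}

#' Pearson chi-squared test for a 2 x k table
#'
#' @param table 2 x k matrix of counts (k >= 2); expected counts must all be
#'   positive.
#' @return \code{test_result} with the Pearson statistic, df = k - 1 and
#'   upper-tail chi-squared p-value.
#' @export
chi2_test <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) == 2, ncol(table) >= 2, all(table >= 0))
  rs <- rowSums(table); cs <- colSums(table); N <- sum(table)
  if (any(rs == 0) || any(cs == 0)) stop("zero marginal total", call. = FALSE)
  E <- outer(rs, cs) / N
  stat <- sum((table - E)^2 / E)
  df <- ncol(table) - 1
  structure(list(name = "chi-squared", statistic = stat,
                 p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
                 df = df),
            class = "test_result")
}

# U statistic of x against y using midranks for ties.
mw_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties. The p-value is exact
#' (full enumeration of label assignments) when n_x + n_y <= 12 and there
#' are no ties; otherwise a normal approximation with tie correction and
#' continuity correction is used. Two-sided throughout; the exact branch
#' also reports the one-sided upper tail.
#'
#' @param x,y numeric samples.
#' @return \code{test_result} with \code{statistic} = U (of \code{x}),
#'   \code{p_value} (two-sided), \code{exact}, and \code{p_greater}
#'   (one-sided P(U >= observed), exact branch only).
#' @export
mann_whitney <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx > 0, ny > 0)
  u <- mw_u(x, y)
  mu <- nx * ny / 2
  pooled <- c(x, y)
  ties <- anyDuplicated(pooled) > 0
  if (nx + ny <= 12 && !ties) {
    idx <- utils::combn(nx + ny, nx)
    us <- apply(idx, 2, function(ii) mw_u(pooled[ii], pooled[-ii]))
    p_two <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    p_gr <- mean(us >= u - 1e-9)
    return(structure(list(name = "Mann-Whitney U", statistic = u,
                          p_value = p_two, df = NA_real_, exact = TRUE,
                          p_greater = p_gr),
                     class = "test_result"))
  }
  n <- nx + ny
  tie_counts <- table(pooled)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_counts^3 - tie_counts) / (n * (n - 1)))
  z <- if (sigma2 > 0) (abs(u - mu) - 0.5) / sqrt(sigma2) else 0
  p_two <- min(1, 2 * stats::pnorm(-max(z, 0)))
  structure(list(name = "Mann-Whitney U", statistic = u, p_value = p_two,
                 df = NA_real_, exact = FALSE, p_greater = NA_real_),
            class = "test_result")
}
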