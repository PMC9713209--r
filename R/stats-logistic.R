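#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood fit of a binary outcome on a design matrix (an
#' intercept column is added internally). Standard errors are Wald, from the
#' inverse observed information at the optimum; odds ratios are exp(coef)
#' with symmetric-on-log-scale 95\% intervals. Quasi-separation is flagged
#' when coefficients diverge (fitted probabilities collapsing to 0/1);
#' estimates are still reported, with a warning.
#'
#' @param design numeric matrix or data.frame of covariates (no intercept
#'   column; factors must be pre-coded numerically).
#' @param outcome binary vector (0/1 or logical).
#' @param max_iter maximum IRLS iterations.
#' @param tol convergence tolerance on the log-likelihood change.
#' @return list of class \code{logistic_fit}: \code{coefficients},
#'   \code{se}, \code{or}, \code{ci_low}, \code{ci_high}, \code{z},
#'   \code{p_value}, \code{log_lik}, \code{converged}, \code{separation},
#'   \code{fitted}, \code{n}.
#' @export
logistic_fit <- function(design, outcome, max_iter = 50, tol = 1e-10) {
  y <- as.numeric(as.logical(outcome))
  X <- as.matrix(cbind(`(Intercept)` = 1, design))
  storage.mode(X) <- "double"
  stopifnot(nrow(X) == length(y), !anyNA(X), !anyNA(y))
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient after adding an intercept", call. = FALSE)
  beta <- numeric(ncol(X))
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    # Newton step: beta + (X'WX)^{-1} X'(y - p)
    XtWX <- crossprod(X * sqrt(w))
    step <- tryCatch(solve(XtWX, crossprod(X, y - p)),
                     error = function(e) stop("information matrix is singular",
                                              call. = FALSE))
    beta <- beta + drop(step)
    eta <- drop(X %*% beta)
    ll <- sum(y * eta - log1p(exp(eta)))
    if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  p <- stats::plogis(drop(X %*% beta))
  separation <- max(abs(beta[-1]), 0) > 15 ||
    (all(p[y == 1] > 1 - 1e-6) && all(p[y == 0] < 1e-6))
  if (separation)
    warning("quasi-separation detected: coefficients diverge; estimates unreliable",
            call. = FALSE)
  if (!converged && !separation)
    stop("IRLS failed to converge without evidence of separation", call. = FALSE)
  w <- pmax(p * (1 - p), 1e-10)
  info <- crossprod(X * sqrt(w))
  se <- sqrt(diag(solve(info)))
  z <- beta / se
  names(beta) <- names(se) <- colnames(X)
  structure(list(coefficients = beta, se = se,
                 or = exp(beta), ci_low = exp(beta - 1.959963984540054 * se),
                 ci_high = exp(beta + 1.959963984540054 * se),
                 z = z, p_value = 2 * stats::pnorm(-abs(z)),
                 log_lik = sum(y * log(pmax(p, 1e-300)) +
                                 (1 - y) * log(pmax(1 - p, 1e-300))),
                 converged = converged, separation = separation,
                 fitted = p, n = length(y)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d, logLik = %.3f%s\n", x$n, x$log_lik,
              if (x$separation) " [SEPARATION]" else ""))
  tab <- data.frame(coef = x$coefficients, se = x$se, OR = x$or,
                    ci_low = x$ci_low, ci_high = x$ci_high, p = x$p_value)
  print(round(tab, 4))
  invisible(x)
}

# Tidy one fit into a report row per non-intercept term.
logistic_rows <- function(fit, model_label) {
  k <- names(fit$coefficients)
  keep <- k != "(Intercept)"
  data.frame(model = model_label, term = k[keep],
             or = fit$or[keep], ci_low = fit$ci_low[keep],
             ci_high = fit$ci_high[keep], p_value = fit$p_value[keep],
             separation = fit$separation, n = fit$n,
             stringsAsFactors = FALSE, row.names = NULL)
}
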