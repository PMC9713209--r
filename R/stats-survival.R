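#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator with Greenwood variance. At tied times,
#' events are handled before censorings (censored units remain in the risk
#' set for an event at the same time). Confidence intervals are plain
#' Greenwood on the survival scale clipped to [0, 1] by default; a
#' log(-log) transform is available.
#'
#' @param times non-negative follow-up times.
#' @param events binary event indicators (1 = event, 0 = censored).
#' @param conf_type "plain" (Greenwood, clipped) or "log-log".
#' @return list of class \code{km_curve} with data.frame \code{table}
#'   (\code{time}, \code{n_risk}, \code{n_event}, \code{n_censor},
#'   \code{surv}, \code{se}, \code{lower}, \code{upper}) over distinct
#'   event/censoring times, plus \code{n} and \code{max_time}.
#' @export
km <- function(times, events, conf_type = c("plain", "log-log")) {
  conf_type <- match.arg(conf_type)
  events <- as.integer(as.logical(events))
  stopifnot(length(times) == length(events), all(times >= 0), length(times) > 0)
  tt <- sort(unique(times))
  n <- length(times)
  n_risk <- n_event <- n_censor <- integer(length(tt))
  for (i in seq_along(tt)) {
    n_risk[i]   <- sum(times >= tt[i])
    n_event[i]  <- sum(times == tt[i] & events == 1L)
    n_censor[i] <- sum(times == tt[i] & events == 0L)
  }
  frac <- ifelse(n_risk > 0, 1 - n_event / n_risk, 1)
  surv <- cumprod(frac)
  # Greenwood: var(S) = S^2 * cumsum(d / (n(n-d)))
  gw_term <- ifelse(n_risk > n_event, n_event / (n_risk * (n_risk - n_event)), 0)
  se <- surv * sqrt(cumsum(gw_term))
  if (conf_type == "plain") {
    lower <- pmax(0, surv - 1.959963984540054 * se)
    upper <- pmin(1, surv + 1.959963984540054 * se)
  } else {
    # CI on log(-log S); collapses to the point estimate at S = 0 or 1
    ok <- surv > 0 & surv < 1
    lower <- upper <- surv
    se_ll <- ifelse(ok, se / (surv * abs(log(surv))), NA)
    lower[ok] <- surv[ok]^exp(1.959963984540054 * se_ll[ok])
    upper[ok] <- surv[ok]^exp(-1.959963984540054 * se_ll[ok])
  }
  structure(list(table = data.frame(time = tt, n_risk = n_risk,
                                    n_event = n_event, n_censor = n_censor,
                                    surv = surv, se = se,
                                    lower = lower, upper = upper),
                 n = n, max_time = max(times), conf_type = conf_type),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d distinct times, S(max) = %.3f\n",
              x$n, nrow(x$table), utils::tail(x$table$surv, 1)))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Right-continuous step-function evaluation: S(t) is the estimate at the
#' latest event/censoring time <= t (1 before the first). Evaluation beyond
#' the last follow-up returns the last value with \code{extrapolated = TRUE}.
#'
#' @param curve a \code{\link{km}} result.
#' @param t non-negative time.
#' @return list with \code{estimate}, \code{lower}, \code{upper},
#'   \code{extrapolated}.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), t >= 0)
  tab <- curve$table
  i <- findInterval(t, tab$time)
  if (i == 0) return(list(estimate = 1, lower = 1, upper = 1, extrapolated = FALSE))
  list(estimate = tab$surv[i], lower = tab$lower[i], upper = tab$upper[i],
       extrapolated = t > curve$max_time)
}

#' Two-group log-rank test
#'
#' Observed-minus-expected statistic over the pooled distinct event times,
#' with the hypergeometric variance, referred to chi-squared with 1 df.
#'
#' @param times_a,events_a,times_b,events_b follow-up and event indicators
#'   per group.
#' @return list of class \code{test_result}: \code{statistic},
#'   \code{p_value}, \code{df}, \code{observed}, \code{expected} (group a).
#' @export
logrank <- function(times_a, events_a, times_b, events_b) {
  ea <- as.integer(as.logical(events_a)); eb <- as.integer(as.logical(events_b))
  stopifnot(length(times_a) == length(ea), length(times_b) == length(eb),
            length(times_a) > 0, length(times_b) > 0)
  times <- c(times_a, times_b)
  events <- c(ea, eb)
  grp_a <- c(rep(TRUE, length(times_a)), rep(FALSE, length(times_b)))
  et <- sort(unique(times[events == 1L]))
  if (length(et) == 0) {
    warning("no events in either group; log-rank undefined, returning p = 1",
            call. = FALSE)
    return(structure(list(name = "log-rank", statistic = 0, p_value = 1, df = 1,
                          observed = 0, expected = 0), class = "test_result"))
  }
  O <- E <- V <- 0
  for (t in et) {
    at_risk <- times >= t
    n_t  <- sum(at_risk)
    n1_t <- sum(at_risk & grp_a)
    d_t  <- sum(times == t & events == 1L)
    d1_t <- sum(times == t & events == 1L & grp_a)
    O <- O + d1_t
    E <- E + d_t * n1_t / n_t
    if (n_t > 1)
      V <- V + d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  structure(list(name = "log-rank", statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 df = 1, observed = O, expected = E),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g%s, p = %.4g\n",
              x$name, x$statistic,
              if (!is.null(x$df) && !is.na(x$df)) sprintf(" (df = %g)", x$df) else "",
              x$p_value))
  invisible(x)
}
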