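#' ROC curve with Youden-optimal cutoff
#'
#' Classification rule: predict positive (relapse) iff score >= threshold —
#' higher recipient chimerism means higher risk. Thresholds sweep all
#' distinct observed scores plus +Inf; AUC is the trapezoidal area under the
#' (FPR, TPR) polyline, which equals the pairwise-comparison probability
#' (ties counted 1/2). The Youden cutoff maximizes J = sensitivity +
#' specificity - 1; ties are broken toward the smallest threshold (favors
#' sensitivity, the screening use-case).
#'
#' @param scores numeric vector.
#' @param labels binary vector (0/1 or logical), 1 = positive class.
#' @return list of class \code{roc_result}: \code{thresholds}, \code{tpr},
#'   \code{fpr}, \code{auc}, \code{youden_cutoff}, \code{j_at_cutoff},
#'   \code{sensitivity_at_cutoff}, \code{specificity_at_cutoff}, \code{n_pos},
#'   \code{n_neg}.
#' @export
roc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to build an ROC curve", call. = FALSE)
  thr <- c(sort(unique(scores)), Inf)
  tpr <- vapply(thr, function(t) mean(scores[labels == 1L] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[labels == 0L] >= t), numeric(1))
  # polyline ordered from (0,0) [thr = Inf] to (1,1) [thr = min score]
  ord <- order(fpr, tpr)
  xf <- c(0, fpr[ord], 1)
  yf <- c(0, tpr[ord], 1)
  auc <- sum(diff(xf) * (utils::head(yf, -1) + utils::tail(yf, -1)) / 2)
  j <- tpr - fpr
  finite <- is.finite(thr)
  best <- which(finite & j >= max(j[finite]) - 1e-15)
  best <- best[which.min(thr[best])]
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 youden_cutoff = thr[best], j_at_cutoff = j[best],
                 sensitivity_at_cutoff = tpr[best],
                 specificity_at_cutoff = 1 - fpr[best],
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f | Youden cutoff %.4g (J %.3f, sens %.2f, spec %.2f) | %d pos / %d neg\n",
              x$auc, x$youden_cutoff, x$j_at_cutoff,
              x$sensitivity_at_cutoff, x$specificity_at_cutoff,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Sensitivity and specificity at a fixed cutoff
#'
#' Sensitivity = fraction of positives with score >= cutoff; specificity =
#' fraction of negatives with score < cutoff.
#'
#' @param scores,labels as in \code{\link{roc}}.
#' @param cutoff finite numeric cutoff.
#' @return list with \code{sensitivity} and \code{specificity}.
#' @export
sens_spec_at <- function(scores, labels, cutoff) {
  labels <- as.integer(as.logical(labels))
  stopifnot(is.finite(cutoff))
  if (sum(labels == 1L) == 0 || sum(labels == 0L) == 0)
    stop("both classes must be present", call. = FALSE)
  list(sensitivity = mean(scores[labels == 1L] >= cutoff),
       specificity = mean(scores[labels == 0L] < cutoff))
}
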