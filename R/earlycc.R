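#' Early-window configuration for the complete-chimerism analysis
#'
#' @param window_days length of the early window in days (default 60; the
#'   window is day 0 through \code{window_days} inclusive).
#' @param compartment compartment analyzed (default "blood": early marrow
#'   sampling is infrequent in routine care).
#' @return list of class \code{early_config}.
#' @export
early_config <- function(window_days = 60, compartment = "blood") {
  stopifnot(window_days > 0, compartment %in% COMPARTMENTS)
  structure(list(window_days = window_days, compartment = compartment),
            class = "early_config")
}

#' Per-transplant minimum early chimerism (%min)
#'
#' %min is the lowest chimerism value observed in the configured compartment
#' and lineage during the early window (day 0 to \code{window_days},
#' inclusive). Transplants with no qualifying measurement are omitted and
#' listed in the \code{"dropped"} attribute.
#'
#' @param x a \code{chim_cohort}.
#' @param lineage lineage analyzed (default "CD3").
#' @param config an \code{\link{early_config}}.
#' @return data.frame with \code{transplant_id}, \code{pct_min},
#'   \code{n_samples_used}; attribute \code{"dropped"}.
#' @export
compute_pct_min <- function(x, lineage = "CD3", config = early_config()) {
  stopifnot(inherits(x, "chim_cohort"), lineage %in% LINEAGES,
            inherits(config, "early_config"))
  m <- x$measurements
  m <- m[m$compartment == config$compartment & m$lineage == lineage &
           m$day >= 0 & m$day <= config$window_days, , drop = FALSE]
  if (nrow(m) == 0) {
    out <- data.frame(transplant_id = character(0), pct_min = numeric(0),
                      n_samples_used = integer(0), stringsAsFactors = FALSE)
    attr(out, "dropped") <- x$transplants$transplant_id
    return(out)
  }
  sp <- split(m$percent_recipient, m$transplant_id)
  out <- data.frame(transplant_id = names(sp),
                    pct_min = vapply(sp, min, numeric(1)),
                    n_samples_used = vapply(sp, length, integer(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dropped") <- setdiff(x$transplants$transplant_id, out$transplant_id)
  out
}

#' Exclude transplants relapsing within the early window
#'
#' A relapse inside the early window cannot be predicted by early-window
#' chimerism without look-ahead; such transplants (relapse_day <=
#' \code{window_days}) are removed before the early-CC analysis.
#'
#' @param x a \code{chim_cohort}.
#' @param config an \code{\link{early_config}}.
#' @return a \code{chim_cohort} subset.
#' @export
exclude_early_relapses <- function(x, config = early_config()) {
  tr <- x$transplants
  keep <- is.na(tr$relapse_day) | tr$relapse_day > config$window_days
  tr <- tr[keep, , drop = FALSE]
  cohort(tr, x$measurements[x$measurements$transplant_id %in% tr$transplant_id, ,
                            drop = FALSE])
}

#' Dichotomize transplants into complete vs mixed chimerism
#'
#' Complete chimerism (CC) means at least one early value strictly below the
#' cutoff, i.e. \code{pct_min < cutoff}; otherwise mixed chimerism (MC).
#'
#' @param pct_min output of \code{\link{compute_pct_min}} (or any data.frame
#'   with \code{transplant_id} and \code{pct_min}).
#' @param cutoff percent-recipient cutoff (> 0).
#' @return data.frame with \code{transplant_id}, \code{pct_min},
#'   \code{label} ("CC"/"MC"), \code{cutoff_used}.
#' @export
dichotomize_cc <- function(pct_min, cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff > 0)
  data.frame(transplant_id = pct_min$transplant_id,
             pct_min = pct_min$pct_min,
             label = ifelse(pct_min$pct_min < cutoff, "CC", "MC"),
             cutoff_used = cutoff,
             stringsAsFactors = FALSE)
}

#' Published early-CC cutoff presets (percent recipient)
#'
#' Cutoffs derived on the original clinical cohort by Youden-optimal ROC
#' analysis of early blood %min per lineage and age subset, usable when the
#' cutoff is to be fixed rather than re-derived.
#'
#' @return named nested list: \code{preset[[age_group]][[lineage]]}.
#' @export
cc_cutoff_presets <- function() {
  list(
    all       = list(CD19 = 0.01, CD3 = 0.3,  CD33 = 0.06),
    pediatric = list(CD19 = 0.2,  CD3 = 0.9,  CD33 = 0.06),
    adult     = list(CD19 = 0.01, CD3 = 0.12, CD33 = 0.1)
  )
}
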