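#' Landmark filtration configuration
#'
#' @param post_hsct_exclusion_days measurements within this many days after
#'   transplantation are removed (engraftment-phase mixed chimerism reflects
#'   engraftment, not relapse). Default 30.
#' @param pre_relapse_exclusion_days measurements within this many days
#'   before relapse are removed, so that retained values predict relapse
#'   with time to intervene; non-relapsed transplants are truncated at the
#'   average relapse time minus the same margin to equalise observation
#'   time. Default 30.
#' @param average_kind how the relapse-group truncation day is averaged:
#'   "mean" (default) or "median".
#' @return list of class \code{filter_config}.
#' @export
filter_config <- function(post_hsct_exclusion_days = 30,
                          pre_relapse_exclusion_days = 30,
                          average_kind = c("mean", "median")) {
  average_kind <- match.arg(average_kind)
  stopifnot(post_hsct_exclusion_days >= 0, pre_relapse_exclusion_days >= 0)
  structure(list(post_hsct_exclusion_days = post_hsct_exclusion_days,
                 pre_relapse_exclusion_days = pre_relapse_exclusion_days,
                 average_kind = average_kind),
            class = "filter_config")
}

#' Average time to relapse among relapsed transplants
#'
#' @param x a \code{chim_cohort}.
#' @param kind "mean" or "median".
#' @return days (numeric scalar).
#' @export
average_time_to_relapse <- function(x, kind = c("mean", "median")) {
  kind <- match.arg(kind)
  d <- x$transplants$relapse_day[!is.na(x$transplants$relapse_day)]
  if (length(d) == 0)
    stop("no relapsed transplants: the non-relapse truncation day is undefined",
         call. = FALSE)
  if (kind == "mean") mean(d) else stats::median(d)
}

#' Apply the landmark filter to one measurement stratum
#'
#' Keeps a measurement of the requested compartment/lineage iff its day lies
#' in the closed interval [\code{post_hsct_exclusion_days}, upper], where
#' upper is \code{relapse_day - pre_relapse_exclusion_days} for relapsed
#' transplants and \code{avg_relapse_day - pre_relapse_exclusion_days} for
#' non-relapsed transplants (avg over the relapsed transplants of the same
#' cohort). A degenerate window retains nothing for that transplant.
#'
#' @param x a \code{chim_cohort} (subset it first if the analysis is per age
#'   group: the truncation day is recomputed from whatever cohort is given).
#' @param compartment,lineage measurement stratum to retain.
#' @param config a \code{\link{filter_config}}.
#' @return data.frame of retained measurements (same columns as
#'   \code{x$measurements}), with attribute \code{"upper_bound"} giving the
#'   per-transplant upper day bound used.
#' @export
apply_landmark_filter <- function(x, compartment = "marrow", lineage = "CD3",
                                  config = filter_config()) {
  stopifnot(inherits(x, "chim_cohort"), inherits(config, "filter_config"),
            compartment %in% COMPARTMENTS, lineage %in% LINEAGES)
  avg_day <- average_time_to_relapse(x, config$average_kind)
  tr <- x$transplants
  upper <- ifelse(is.na(tr$relapse_day),
                  avg_day - config$pre_relapse_exclusion_days,
                  tr$relapse_day - config$pre_relapse_exclusion_days)
  names(upper) <- tr$transplant_id
  m <- x$measurements
  m <- m[m$compartment == compartment & m$lineage == lineage, , drop = FALSE]
  keep <- m$day >= config$post_hsct_exclusion_days &
    m$day <= upper[m$transplant_id]
  out <- m[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "upper_bound") <- upper
  attr(out, "avg_relapse_day") <- avg_day
  out
}

#' Per-transplant maximum retained chimerism (%max)
#'
#' %max is the highest chimerism value that remains after the landmark
#' filtration; a single elevated value flags an at-risk transplant.
#' Transplants with no retained measurement are omitted from the summary and
#' listed in the \code{"dropped"} attribute (they leave all downstream
#' denominators).
#'
#' @param retained output of \code{\link{apply_landmark_filter}}.
#' @param all_ids optional character vector of all transplant ids in the
#'   analyzed cohort, used to fill the drop report.
#' @return data.frame with \code{transplant_id}, \code{pct_max},
#'   \code{day_of_pct_max} (earliest day on ties), \code{n_samples_used};
#'   attribute \code{"dropped"} lists transplant ids without retained data.
#' @export
compute_pct_max <- function(retained, all_ids = NULL) {
  if (nrow(retained) == 0) {
    out <- data.frame(transplant_id = character(0), pct_max = numeric(0),
                      day_of_pct_max = integer(0), n_samples_used = integer(0),
                      stringsAsFactors = FALSE)
    attr(out, "dropped") <- if (is.null(all_ids)) character(0) else all_ids
    return(out)
  }
  sp <- split(retained, retained$transplant_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    mx <- max(d$percent_recipient)
    at <- d$day[d$percent_recipient == mx]
    data.frame(transplant_id = d$transplant_id[1], pct_max = mx,
               day_of_pct_max = min(at), n_samples_used = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "dropped") <- if (is.null(all_ids)) character(0) else
    setdiff(all_ids, out$transplant_id)
  out
}

#' Marrow chimerism in a window around the relapse day
#'
#' For each relapsed transplant, extracts all marrow measurements with
#' |day - relapse_day| <= \code{window_days}, grouped by lineage (the basis
#' of an at-relapse boxplot across cell fractions).
#'
#' @param x a \code{chim_cohort}.
#' @param window_days half-width of the window (default 3).
#' @return data.frame with \code{transplant_id}, \code{lineage}, \code{day},
#'   \code{days_from_relapse}, \code{percent_recipient}.
#' @export
relapse_day_snapshot <- function(x, window_days = 3) {
  stopifnot(window_days >= 0)
  tr <- x$transplants[!is.na(x$transplants$relapse_day), , drop = FALSE]
  m <- x$measurements[x$measurements$compartment == "marrow" &
                        x$measurements$transplant_id %in% tr$transplant_id, ,
                      drop = FALSE]
  if (nrow(m) == 0) {
    return(data.frame(transplant_id = character(0), lineage = character(0),
                      day = integer(0), days_from_relapse = integer(0),
                      percent_recipient = numeric(0), stringsAsFactors = FALSE))
  }
  rd <- stats::setNames(tr$relapse_day, tr$transplant_id)
  off <- m$day - rd[m$transplant_id]
  keep <- abs(off) <= window_days
  out <- data.frame(transplant_id = m$transplant_id[keep],
                    lineage = m$lineage[keep],
                    day = m$day[keep],
                    days_from_relapse = as.integer(off[keep]),
                    percent_recipient = m$percent_recipient[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$transplant_id, out$lineage, out$day), , drop = FALSE]
}
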