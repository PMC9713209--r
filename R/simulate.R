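#' Simulation parameters for a synthetic chimerism cohort
#'
#' Defaults emulate a monocentric B-ALL transplant cohort: ~20\% of
#' transplants relapse after a log-normally distributed delay with median
#' 264 days; roughly 37\% of transplants are pediatric; blood is sampled at
#' a median interval of ~39 days and marrow ~80 days, with monitoring
#' front-loaded in the engraftment phase; engraftment-phase mixed chimerism
#' decays exponentially toward complete donor chimerism, faster in "fast
#' engrafter" transplants than in the mixed-chimerism minority; relapse is
#' preceded by a transient CD3+ recipient-chimerism bump and a terminal
#' surge in the disease lineage (CD19 for B-ALL).
#'
#' @param n_transplants number of transplantations to simulate.
#' @param pediatric_fraction probability a transplant is pediatric (<18 y).
#' @param relapse_prob marginal relapse probability (ignored when
#'   \code{cc_failure_link$enabled}; see \code{\link{cc_link}}).
#' @param relapse_day_median,relapse_day_sdlog log-normal time-to-relapse;
#'   median in days, dispersion on the log scale.
#' @param relapse_day_min earliest possible relapse day (truncation).
#' @param followup_years range (lo, hi) of uniform administrative follow-up.
#' @param sampling list: \code{blood_interval}/\code{marrow_interval} mean
#'   renewal gaps (days), \code{gap_shape} gamma shape of the gaps (sample-
#'   count dispersion), \code{early_days} fixed early blood-monitoring visit
#'   days, \code{early_jitter} uniform jitter (+/- days) on those visits,
#'   \code{horizon_median}/\code{horizon_sdlog} log-normal per-transplant
#'   monitoring horizon, \code{paired_fraction} probability a marrow sampling
#'   day is co-scheduled with (snapped to) the nearest blood day.
#' @param kinetics list: \code{engraftment_start_percent} typical day-0
#'   recipient percentage; \code{halflife_fast}/\code{halflife_slow} decay
#'   half-lives (days) of the two engrafter classes;
#'   \code{mc_fraction} fraction of slow ("mixed chimerism") engrafters;
#'   \code{start_sdlog}, \code{halflife_sdlog}, \code{lineage_sdlog}
#'   between-transplant / between-lineage log-scale spread;
#'   \code{noise_sd_log} multiplicative measurement noise (log sd);
#'   \code{noise_offset} small additive offset stabilising the noise model
#'   near zero; \code{lod_percent} detection limit (values below are
#'   reported as 0 with \code{below_detection = 1}); \code{marrow_offset}
#'   additive recipient percentage in marrow relative to blood (blood/marrow
#'   discordance); \code{cd3_bump_amplitude}/\code{cd3_bump_onset} peak
#'   height (percent) and duration (days before relapse) of the transient
#'   pre-relapse CD3 rise; \code{surge_amplitude}/\code{surge_onset} terminal
#'   disease-lineage surge reaching its peak at relapse;
#'   \code{disease_lineage} lineage carrying the surge.
#' @param cc_failure_link see \code{\link{cc_link}}; ties early mixed
#'   chimerism to a higher relapse hazard. Off by default.
#' @param seed root seed; per-transplant substreams are derived as
#'   \code{(seed + i * 1000003) mod 2^31 - 1} so cohorts are reproducible
#'   under reordering.
#' @return list of class \code{sim_params}.
#' @export
sim_params <- function(n_transplants = 138,
                       pediatric_fraction = 51 / 138,
                       relapse_prob = 0.20,
                       relapse_day_median = 264,
                       relapse_day_sdlog = 0.9,
                       relapse_day_min = 21,
                       followup_years = c(1, 16.8),
                       sampling = list(),
                       kinetics = list(),
                       cc_failure_link = cc_link(enabled = FALSE),
                       seed = 1L) {
  samp <- utils::modifyList(list(
    blood_interval  = 39, marrow_interval = 80, gap_shape = 2,
    early_days      = c(19, 33, 54), early_jitter = 3,
    horizon_median  = 300, horizon_sdlog = 0.4,
    paired_fraction = 0.7
  ), sampling)
  kin <- utils::modifyList(list(
    engraftment_start_percent = 10,
    halflife_fast   = 7,  halflife_slow = 30, mc_fraction = 0.27,
    start_sdlog     = 0.3, halflife_sdlog = 0.15, lineage_sdlog = 0.2,
    noise_sd_log    = 0.5, noise_offset = 0.01, lod_percent = 0.05,
    marrow_offset   = 0.5,
    cd3_bump_amplitude = 3, cd3_bump_onset = 180,
    surge_amplitude = 40, surge_onset = 30,
    disease_lineage = "CD19"
  ), kinetics)
  p <- list(n_transplants = n_transplants,
            pediatric_fraction = pediatric_fraction,
            relapse_prob = relapse_prob,
            relapse_day_median = relapse_day_median,
            relapse_day_sdlog = relapse_day_sdlog,
            relapse_day_min = relapse_day_min,
            followup_years = followup_years,
            sampling = samp, kinetics = kin,
            cc_failure_link = cc_failure_link,
            seed = as.integer(seed))
  stopifnot(p$pediatric_fraction >= 0, p$pediatric_fraction <= 1,
            p$relapse_prob >= 0, p$relapse_prob <= 1,
            p$relapse_day_median > 0, p$relapse_day_sdlog > 0,
            kin$cd3_bump_amplitude >= 0, kin$surge_amplitude >= 0,
            kin$cd3_bump_onset > 0, kin$surge_onset > 0,
            samp$blood_interval > 0, samp$marrow_interval > 0)
  class(p) <- "sim_params"
  p
}

#' Link between early mixed chimerism and relapse hazard
#'
#' When enabled, the relapse probability of each transplant is tilted by its
#' latent engrafter class (the slow class fails to reach early complete donor
#' chimerism). Per-class relapse probabilities are calibrated so that the
#' Kaplan-Meier relapse-free probability at \code{horizon_days}, estimated
#' after excluding relapses within \code{early_window_days} (as the early-CC
#' analysis does), equals \code{rfs_cc} in the fast class and \code{rfs_mc}
#' in the slow class:
#' \deqn{p = (1 - rfs) / (F(h) - rfs \cdot F(w))}
#' where F is the configured log-normal relapse-day CDF.
#'
#' @param enabled logical.
#' @param rfs_cc,rfs_mc target relapse-free probabilities at the horizon.
#' @param horizon_days evaluation horizon (default 730, i.e. 2 years).
#' @param early_window_days early window whose relapses the downstream
#'   analysis excludes (default 60).
#' @return list of class \code{cc_link}.
#' @export
cc_link <- function(enabled = TRUE, rfs_cc = 0.90, rfs_mc = 0.65,
                    horizon_days = 730, early_window_days = 60) {
  structure(list(enabled = enabled, rfs_cc = rfs_cc, rfs_mc = rfs_mc,
                 horizon_days = horizon_days,
                 early_window_days = early_window_days),
            class = "cc_link")
}

# Per-class relapse probability hitting the target post-exclusion RFS.
link_relapse_prob <- function(rfs, params) {
  lk <- params$cc_failure_link
  mlog <- log(params$relapse_day_median)
  Fh <- stats::plnorm(lk$horizon_days, mlog, params$relapse_day_sdlog)
  Fw <- stats::plnorm(lk$early_window_days, mlog, params$relapse_day_sdlog)
  p <- (1 - rfs) / (Fh - rfs * Fw)
  stopifnot(p >= 0, p <= 1)
  p
}

#' Latent trajectory state of one transplant
#'
#' Mostly used internally by \code{\link{generate_cohort}}; exposed so the
#' kinetic model can be probed directly (e.g. with noise off).
#'
#' @param params a \code{\link{sim_params}} object.
#' @param relapse logical; does this transplant relapse?
#' @param relapse_day day of relapse (required when \code{relapse}).
#' @param engrafter "fast" or "slow" latent class.
#' @param start,halflife,lineage_factor optional overrides of the latent
#'   kinetic draws (start percent, decay half-life in days, named
#'   multiplicative per-lineage factors).
#' @return list of class \code{trajectory_state}.
#' @export
trajectory_state <- function(params, relapse = FALSE, relapse_day = NA,
                             engrafter = c("fast", "slow"),
                             start = NULL, halflife = NULL,
                             lineage_factor = NULL) {
  engrafter <- match.arg(engrafter)
  kin <- params$kinetics
  if (is.null(start)) start <- kin$engraftment_start_percent
  if (is.null(halflife))
    halflife <- if (engrafter == "fast") kin$halflife_fast else kin$halflife_slow
  if (is.null(lineage_factor))
    lineage_factor <- stats::setNames(rep(1, 4), LINEAGES)
  if (relapse && is.na(relapse_day)) stop("relapse_day required when relapse = TRUE")
  structure(list(relapse = relapse, relapse_day = relapse_day,
                 engrafter = engrafter, start = start, halflife = halflife,
                 lineage_factor = lineage_factor, kinetics = kin),
            class = "trajectory_state")
}

# Raised-cosine pulse of width `width` ending at day `end`, peak `amp` at
# its midpoint.
raised_cosine <- function(day, end, width, amp) {
  centre <- end - width / 2
  inside <- abs(day - centre) <= width / 2
  out <- numeric(length(day))
  out[inside] <- amp / 2 * (1 + cos(2 * pi * (day[inside] - centre) / width))
  out
}

# Half-cosine ramp rising from 0 at `end - onset` to `amp` at `end`.
terminal_surge <- function(day, end, onset, amp) {
  inside <- day >= end - onset & day <= end
  out <- numeric(length(day))
  out[inside] <- amp / 2 * (1 + cos(pi * (end - day[inside]) / onset))
  out
}

#' Evaluate the latent chimerism trajectory
#'
#' Noiseless value: exponential engraftment decay, plus the transient CD3
#' bump (relapsed transplants, CD3 lineage), plus the terminal disease-
#' lineage surge, plus the additive marrow offset. With \code{noise = TRUE},
#' multiplicative log-normal noise is applied on (percent + offset), values
#' below the detection limit are reported as 0, and the result is clamped to
#' [0, 100]. Noise consumes the current RNG stream.
#'
#' @param state a \code{\link{trajectory_state}}.
#' @param lineage,compartment measurement stratum.
#' @param day vector of days post-HSCT (day 0 = transplantation).
#' @param noise apply the measurement-error model?
#' @return numeric vector of percent-recipient values.
#' @export
chimerism_value <- function(state, lineage, compartment, day, noise = TRUE) {
  stopifnot(inherits(state, "trajectory_state"),
            lineage %in% LINEAGES, compartment %in% COMPARTMENTS,
            all(day >= 0))
  kin <- state$kinetics
  v <- state$start * state$lineage_factor[[lineage]] * 2^(-day / state$halflife)
  if (state$relapse) {
    if (lineage == "CD3")
      v <- v + raised_cosine(day, state$relapse_day, kin$cd3_bump_onset,
                             kin$cd3_bump_amplitude)
    if (lineage == kin$disease_lineage)
      v <- v + terminal_surge(day, state$relapse_day, kin$surge_onset,
                              kin$surge_amplitude)
  }
  if (compartment == "marrow") v <- v + kin$marrow_offset
  if (noise) {
    eps <- stats::rnorm(length(day), 0, kin$noise_sd_log)
    v <- pmax(0, (v + kin$noise_offset) * exp(eps) - kin$noise_offset)
    v[v < kin$lod_percent] <- 0
  }
  pmin(pmax(v, 0), 100)
}

# Covariate frequencies loosely matching a mixed pediatric/adult B-ALL
# transplant population.
draw_covariates <- function(pediatric) {
  list(
    conditioning = if (stats::runif(1) < (if (pediatric) 0.94 else 0.63)) "MAC" else "RIC",
    atg          = as.integer(stats::runif(1) < 0.62),
    source       = if (stats::runif(1) < (if (pediatric) 0.20 else 0.92)) "PB" else "BM",
    donor        = sample(c("SIB", "HAPLO", "MUD"), 1, prob = c(0.30, 0.07, 0.63))
  )
}

#' Generate a synthetic cohort
#'
#' Deterministic given \code{params} (including its seed). Per transplant:
#' draws age group, latent engrafter class and kinetics, relapse outcome and
#' day, follow-up, sampling days per compartment (blood front-loaded around
#' engraftment then a renewal process; marrow a sparser renewal process,
#' partially co-scheduled with blood days), then evaluates the noisy
#' trajectory for every available (day, compartment, lineage). Relapsed
#' transplants stop being sampled at relapse.
#'
#' @param params a \code{\link{sim_params}} object.
#' @return a \code{\link{cohort}} object.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_transplants
  kin <- params$kinetics
  samp <- params$sampling
  lk <- params$cc_failure_link
  p_cc <- p_mc <- params$relapse_prob
  if (isTRUE(lk$enabled)) {
    p_cc <- link_relapse_prob(lk$rfs_cc, params)
    p_mc <- link_relapse_prob(lk$rfs_mc, params)
  }
  mlog <- log(params$relapse_day_median)

  tr_rows <- vector("list", n)
  me_rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed((params$seed + i * 1000003) %% (.Machine$integer.max - 1L) + 1L)
    pediatric <- stats::runif(1) < params$pediatric_fraction
    age <- if (pediatric) stats::runif(1, 2, 17.9) else stats::runif(1, 18, 69)
    slow <- stats::runif(1) < kin$mc_fraction
    start <- kin$engraftment_start_percent * exp(stats::rnorm(1, 0, kin$start_sdlog))
    hl <- (if (slow) kin$halflife_slow else kin$halflife_fast) *
      exp(stats::rnorm(1, 0, kin$halflife_sdlog))
    lf <- stats::setNames(exp(stats::rnorm(4, 0, kin$lineage_sdlog)), LINEAGES)
    relapse <- stats::runif(1) < (if (slow) p_mc else p_cc)
    relapse_day <- if (relapse) {
      max(params$relapse_day_min,
          as.integer(round(stats::rlnorm(1, mlog, params$relapse_day_sdlog))))
    } else NA_integer_
    censor_day <- as.integer(round(stats::runif(1, params$followup_years[1],
                                                params$followup_years[2]) * 365.25))
    state <- trajectory_state(params, relapse = relapse, relapse_day = relapse_day,
                              engrafter = if (slow) "slow" else "fast",
                              start = start, halflife = hl, lineage_factor = lf)

    horizon <- round(stats::rlnorm(1, log(samp$horizon_median), samp$horizon_sdlog))
    stop_day <- min(censor_day, horizon, if (relapse) relapse_day else Inf)

    early <- round(samp$early_days +
                     stats::runif(length(samp$early_days),
                                  -samp$early_jitter, samp$early_jitter))
    gaps <- stats::rgamma(80, shape = samp$gap_shape,
                          scale = samp$blood_interval / samp$gap_shape)
    renew <- max(early) + cumsum(round(pmax(gaps, 3)))
    blood_days <- sort(unique(c(early, renew)))
    blood_days <- blood_days[blood_days >= 0 & blood_days <= stop_day]

    mgaps <- stats::rgamma(40, shape = samp$gap_shape,
                           scale = samp$marrow_interval / samp$gap_shape)
    marrow_days <- round(samp$early_days[1]) + c(0, cumsum(round(pmax(mgaps, 7))))
    marrow_days <- marrow_days[marrow_days <= stop_day]
    if (length(marrow_days) > 0 && length(blood_days) > 0) {
      snap <- stats::runif(length(marrow_days)) < samp$paired_fraction
      nearest <- vapply(marrow_days, function(d)
        blood_days[which.min(abs(blood_days - d))], numeric(1))
      marrow_days[snap & abs(nearest - marrow_days) <= 21] <-
        nearest[snap & abs(nearest - marrow_days) <= 21]
      marrow_days <- sort(unique(marrow_days))
    }

    nb <- length(blood_days); nm <- length(marrow_days)
    if (nb + nm > 0) {
      day_v  <- c(rep(as.integer(blood_days), length(BLOOD_LINEAGES)),
                  rep(as.integer(marrow_days), length(MARROW_LINEAGES)))
      comp_v <- c(rep("blood", nb * length(BLOOD_LINEAGES)),
                  rep("marrow", nm * length(MARROW_LINEAGES)))
      lin_v  <- c(rep(BLOOD_LINEAGES, each = nb), rep(MARROW_LINEAGES, each = nm))
      val_v  <- c(unlist(lapply(BLOOD_LINEAGES, function(l)
                    chimerism_value(state, l, "blood", blood_days)),
                  use.names = FALSE),
                  unlist(lapply(MARROW_LINEAGES, function(l)
                    chimerism_value(state, l, "marrow", marrow_days)),
                  use.names = FALSE))
      me_rows[[i]] <- list(id = rep(paste0("tx", i), length(day_v)),
                           day = day_v, comp = comp_v, lin = lin_v,
                           val = if (is.null(val_v)) numeric(0) else val_v)
    }

    cov <- draw_covariates(pediatric)
    tr_rows[[i]] <- data.frame(
      transplant_id = paste0("tx", i),
      patient_id = paste0("pt", i),
      age_years = round(age, 1),
      relapse_day = relapse_day,
      censor_day = censor_day,
      conditioning = cov$conditioning, atg = cov$atg,
      source = cov$source, donor = cov$donor,
      stringsAsFactors = FALSE)
  }
  transplants <- do.call(rbind, tr_rows)
  rownames(transplants) <- NULL
  me_rows <- me_rows[!vapply(me_rows, is.null, logical(1))]
  grab <- function(f, how) how(lapply(me_rows, `[[`, f), use.names = FALSE)
  val <- grab("val", unlist)
  measurements <- data.frame(
    transplant_id = grab("id", unlist),
    day = grab("day", unlist),
    compartment = grab("comp", unlist),
    lineage = grab("lin", unlist),
    percent_recipient = val,
    below_detection = as.integer(val == 0),
    stringsAsFactors = FALSE)
  cohort(transplants, measurements)
}

#' Pediatric/adult age-group labels for a transplants table
#'
#' @param transplants the \code{transplants} data frame of a cohort.
#' @return character vector, "pediatric" (<18 years) or "adult".
#' @export
age_group <- function(transplants) {
  ifelse(transplants$age_years < 18, "pediatric", "adult")
}

#' Restrict a cohort to an age group
#'
#' @param x a \code{chim_cohort}.
#' @param group "all", "pediatric" or "adult".
#' @return a \code{chim_cohort} containing only the selected transplants.
#' @export
subset_age <- function(x, group = c("all", "pediatric", "adult")) {
  group <- match.arg(group)
  if (group == "all") return(x)
  keep <- x$transplants[age_group(x$transplants) == group, , drop = FALSE]
  cohort(keep,
         x$measurements[x$measurements$transplant_id %in% keep$transplant_id, ,
                        drop = FALSE])
}
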