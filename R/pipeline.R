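#' Analysis configuration
#'
#' @param age_group "all", "pediatric" or "adult"; the analysis (including
#'   the landmark truncation day and any derived cutoff) is run on that
#'   subset alone.
#' @param compartment,lineage primary stratum for the %max model and ROC.
#' @param filter a \code{\link{filter_config}}.
#' @param early an \code{\link{early_config}}.
#' @param early_lineage lineage for the early-CC (%min) analysis.
#' @param cutoff_mode "youden" to derive the CC cutoff from the data by
#'   Youden-optimal ROC on %min, or a fixed positive number.
#' @param covariates multivariable-model covariates, subset of
#'   \code{c("age_years", "conditioning", "source", "atg")} (coded MAC = 1 vs
#'   RIC = 0, BM = 1 vs PB = 0, ATG 1/0, age in years continuous).
#' @param horizon_days time point for the reported relapse-free probability
#'   (default 730 = 2 years).
#' @param seed recorded in report metadata (no resampling is performed by
#'   the core analyses).
#' @return list of class \code{analysis_config}.
#' @export
analysis_config <- function(age_group = "all", compartment = "marrow",
                            lineage = "CD3", filter = filter_config(),
                            early = early_config(), early_lineage = "CD3",
                            cutoff_mode = "youden",
                            covariates = c("age_years", "conditioning",
                                           "source", "atg"),
                            horizon_days = 730, seed = 1L) {
  stopifnot(age_group %in% c("all", "pediatric", "adult"),
            compartment %in% COMPARTMENTS, lineage %in% LINEAGES,
            early_lineage %in% LINEAGES,
            identical(cutoff_mode, "youden") ||
              (is.numeric(cutoff_mode) && cutoff_mode > 0),
            all(covariates %in% c("age_years", "conditioning", "source", "atg")))
  structure(list(age_group = age_group, compartment = compartment,
                 lineage = lineage, filter = filter, early = early,
                 early_lineage = early_lineage, cutoff_mode = cutoff_mode,
                 covariates = covariates, horizon_days = horizon_days,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

# 0/1 covariate design for the multivariable models.
covariate_design <- function(transplants, covariates) {
  cols <- list(age_years    = transplants$age_years,
               conditioning = as.integer(transplants$conditioning == "MAC"),
               source       = as.integer(transplants$source == "BM"),
               atg          = transplants$atg)
  as.data.frame(cols[covariates], stringsAsFactors = FALSE)
}

skip_section <- function(reason) list(skipped = TRUE, reason = reason)

#' Landmark %max relapse-prediction analysis
#'
#' Filters the requested age subset per the landmark rules, computes %max
#' per transplant, fits univariable logistic models of relapse on %max for
#' every lineage of the configured compartment, a multivariable model for
#' the configured lineage plus covariates, and the ROC with Youden cutoff
#' and sensitivity/specificity for the configured lineage.
#'
#' @param x a \code{chim_cohort}.
#' @param config an \code{\link{analysis_config}}.
#' @return list section: \code{summaries} (%max per transplant with relapse
#'   labels), \code{univariable}, \code{multivariable}, \code{roc_block},
#'   \code{dropped}, \code{n}; or a skip record when fewer than 2 relapses
#'   carry data.
#' @export
run_maxchim_analysis <- function(x, config = analysis_config()) {
  sub <- subset_age(x, config$age_group)
  if (sum(!is.na(sub$transplants$relapse_day)) < 2)
    return(skip_section("fewer than 2 relapsed transplants in subset"))
  lineages <- if (config$compartment == "blood") BLOOD_LINEAGES else MARROW_LINEAGES

  per_lineage <- list()
  for (lin in lineages) {
    ret <- apply_landmark_filter(sub, config$compartment, lin, config$filter)
    per_lineage[[lin]] <- compute_pct_max(ret, sub$transplants$transplant_id)
  }
  relapsed <- stats::setNames(!is.na(sub$transplants$relapse_day),
                              sub$transplants$transplant_id)

  uni <- list()
  for (lin in lineages) {
    s <- per_lineage[[lin]]
    if (nrow(s) < 3 || sum(relapsed[s$transplant_id]) < 2 ||
        sum(!relapsed[s$transplant_id]) < 2) {
      uni[[lin]] <- skip_section("too few transplants with retained data")
      next
    }
    uni[[lin]] <- logistic_fit(data.frame(pct_max = s$pct_max),
                               relapsed[s$transplant_id])
  }

  s <- per_lineage[[config$lineage]]
  y <- relapsed[s$transplant_id]
  roc_block <- multi <- skip_section("too few transplants with retained data")
  if (nrow(s) >= 3 && sum(y) >= 2 && sum(!y) >= 2) {
    r <- roc(s$pct_max, y)
    ss <- sens_spec_at(s$pct_max, y, r$youden_cutoff)
    roc_block <- list(roc = r, sensitivity = ss$sensitivity,
                      specificity = ss$specificity)
    tr <- sub$transplants[match(s$transplant_id, sub$transplants$transplant_id), ,
                          drop = FALSE]
    design <- cbind(data.frame(pct_max = s$pct_max),
                    covariate_design(tr, config$covariates))
    multi <- tryCatch(logistic_fit(design, y),
                      error = function(e) skip_section(conditionMessage(e)))
  }

  list(skipped = FALSE, age_group = config$age_group,
       compartment = config$compartment, lineage = config$lineage,
       summaries = cbind(s, relapse = unname(y)),
       univariable = uni, multivariable = multi, roc_block = roc_block,
       dropped = attr(s, "dropped"), n = nrow(s))
}

#' Early complete-chimerism risk stratification
#'
#' Excludes relapses within the early window, computes %min per transplant,
#' derives (Youden) or applies (fixed) the CC cutoff, dichotomizes into
#' CC/MC, fits a logistic model of relapse on the CC indicator, and compares
#' the groups' relapse-free survival (Kaplan-Meier per group, log-rank test,
#' and the relapse-free probability at the configured horizon).
#'
#' @param x a \code{chim_cohort}.
#' @param config an \code{\link{analysis_config}}.
#' @return list section: \code{pct_min}, \code{cutoff}, \code{cc},
#'   \code{logistic}, \code{km_cc}, \code{km_mc}, \code{logrank},
#'   \code{rfs_cc}, \code{rfs_mc} (each with CI), counts; or a skip record.
#' @export
run_early_cc_analysis <- function(x, config = analysis_config()) {
  sub <- exclude_early_relapses(subset_age(x, config$age_group), config$early)
  pm <- compute_pct_min(sub, config$early_lineage, config$early)
  if (nrow(pm) < 4)
    return(skip_section("too few transplants with early-window data"))
  tr <- sub$transplants[match(pm$transplant_id, sub$transplants$transplant_id), ,
                        drop = FALSE]
  relapsed <- !is.na(tr$relapse_day)
  if (sum(relapsed) < 2 || sum(!relapsed) < 2)
    return(skip_section("fewer than 2 transplants per outcome class"))

  cutoff <- if (identical(config$cutoff_mode, "youden")) {
    # %min scored like %max: higher early chimerism = higher risk; CC is
    # "below cutoff", so the Youden threshold itself defines the boundary
    roc(pm$pct_min, relapsed)$youden_cutoff
  } else config$cutoff_mode
  if (!is.finite(cutoff) || cutoff <= 0)
    return(skip_section("derived cutoff degenerate (no positive threshold)"))
  cc <- dichotomize_cc(pm, cutoff)

  if (length(unique(cc$label)) < 2)
    return(skip_section("all transplants fall in one chimerism class"))
  is_cc <- cc$label == "CC"
  fit <- tryCatch(logistic_fit(data.frame(early_cc = as.integer(is_cc)), relapsed),
                  error = function(e) skip_section(conditionMessage(e)))

  time <- ifelse(relapsed, tr$relapse_day, tr$censor_day)
  km_cc <- km(time[is_cc], relapsed[is_cc])
  km_mc <- km(time[!is_cc], relapsed[!is_cc])
  lr <- logrank(time[is_cc], relapsed[is_cc], time[!is_cc], relapsed[!is_cc])
  list(skipped = FALSE, age_group = config$age_group,
       lineage = config$early_lineage,
       pct_min = cbind(pm, relapse = relapsed, label = cc$label),
       cutoff = cutoff,
       cutoff_mode = if (identical(config$cutoff_mode, "youden")) "youden" else "fixed",
       logistic = fit, km_cc = km_cc, km_mc = km_mc, logrank = lr,
       rfs_cc = survival_at(km_cc, config$horizon_days),
       rfs_mc = survival_at(km_mc, config$horizon_days),
       n_cc = sum(is_cc), n_mc = sum(!is_cc), n = nrow(pm),
       dropped = attr(pm, "dropped"))
}

#' Relapse-aligned chimerism kinetics
#'
#' For relapsed transplants only, re-indexes measurement days relative to
#' relapse (relapse = day 0), pools CD3 and disease-lineage values per
#' compartment, and fits a LOESS line to each cell type (data-first figure:
#' the curves are returned as grids of fitted values).
#'
#' @param x a \code{chim_cohort}.
#' @param disease_lineage lineage carrying the leukemia signal ("CD19" for
#'   B-ALL).
#' @param span LOESS span.
#' @return list with one entry per compartment, each holding \code{points}
#'   (aligned raw data) and \code{curves} (per-lineage LOESS grids); or a
#'   skip record when no relapsed transplant has data.
#' @export
run_kinetics <- function(x, disease_lineage = "CD19", span = 0.75) {
  tr <- x$transplants[!is.na(x$transplants$relapse_day), , drop = FALSE]
  if (nrow(tr) == 0) return(skip_section("no relapsed transplants"))
  rd <- stats::setNames(tr$relapse_day, tr$transplant_id)
  m <- x$measurements[x$measurements$transplant_id %in% tr$transplant_id &
                        x$measurements$lineage %in% c("CD3", disease_lineage), ,
                      drop = FALSE]
  if (nrow(m) == 0) return(skip_section("no measurements on relapsed transplants"))
  m$days_from_relapse <- m$day - rd[m$transplant_id]
  out <- list(skipped = FALSE, disease_lineage = disease_lineage)
  for (comp in COMPARTMENTS) {
    mc <- m[m$compartment == comp, , drop = FALSE]
    if (nrow(mc) == 0) next
    curves <- list()
    for (lin in unique(mc$lineage)) {
      ml <- mc[mc$lineage == lin, , drop = FALSE]
      if (nrow(ml) < 4) next
      curves[[lin]] <- loess_fit(ml$days_from_relapse, ml$percent_recipient,
                                 span = span)
    }
    out[[comp]] <- list(points = mc[, c("transplant_id", "lineage",
                                        "days_from_relapse", "percent_recipient")],
                        curves = curves)
  }
  out
}

#' Run the full analysis and assemble a report
#'
#' Orchestrates paired blood/marrow correlation, the landmark %max analysis,
#' the early-CC stratification, and the relapse-aligned kinetics into one
#' report object. Identical cohort + config give an identical report.
#'
#' @param x a \code{chim_cohort}.
#' @param config an \code{\link{analysis_config}}.
#' @return list of class \code{analysis_report}.
#' @export
run_report <- function(x, config = analysis_config()) {
  pairs <- paired_samples(x, "CD3")
  paired_block <- if (nrow(pairs) >= 3 &&
                      stats::var(pairs$blood_percent) > 0 &&
                      stats::var(pairs$marrow_percent) > 0) {
    c(paired_correlation(pairs), list(skipped = FALSE))
  } else skip_section("fewer than 3 informative paired samples")
  structure(list(
    meta = list(n_transplants = nrow(x$transplants),
                n_measurements = nrow(x$measurements),
                n_relapsed = sum(!is.na(x$transplants$relapse_day)),
                age_group = config$age_group,
                compartment = config$compartment, lineage = config$lineage,
                seed = config$seed,
                note = "p-values are presented without correction for multiple testing"),
    paired = paired_block,
    maxchim = run_maxchim_analysis(x, config),
    early_cc = run_early_cc_analysis(x, config),
    kinetics = run_kinetics(x)
  ), class = "analysis_report")
}

# Strip heavyweight/recursive members down to plain serializable values.
report_json <- function(report) {
  simplify <- function(node) {
    if (inherits(node, "roc_result"))
      return(list(auc = node$auc, youden_cutoff = node$youden_cutoff,
                  j_at_cutoff = node$j_at_cutoff,
                  sensitivity_at_cutoff = node$sensitivity_at_cutoff,
                  specificity_at_cutoff = node$specificity_at_cutoff,
                  n_pos = node$n_pos, n_neg = node$n_neg))
    if (inherits(node, "logistic_fit"))
      return(logistic_rows(node, "fit"))
    if (inherits(node, "km_curve"))
      return(node$table)
    if (inherits(node, "test_result"))
      return(list(name = node$name, statistic = node$statistic,
                  p_value = node$p_value, df = node$df))
    if (is.list(node) && is.null(dim(node)) && !is.data.frame(node))
      return(lapply(node, simplify))
    node
  }
  jsonlite::toJSON(simplify(unclass(report)), auto_unbox = TRUE, digits = NA,
                   dataframe = "columns", na = "null", pretty = TRUE)
}

#' Write an analysis report to disk
#'
#' Emits \code{report.json} plus per-section TSVs (\code{roc_points.tsv},
#' \code{km_curves.tsv}, \code{logistic_fits.tsv}, \code{summaries.tsv},
#' \code{kinetics_curves.tsv}). Figures are emitted as data; identical
#' inputs yield byte-identical files.
#'
#' @param report output of \code{\link{run_report}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(report_json(report), file.path(dir, "report.json"))
  tsv <- function(df, name) utils::write.table(df, file.path(dir, name),
                                               sep = "\t", quote = FALSE,
                                               row.names = FALSE)
  mx <- report$maxchim
  if (!isTRUE(mx$skipped)) {
    tsv(mx$summaries, "summaries.tsv")
    if (!isTRUE(mx$roc_block$skipped)) {
      r <- mx$roc_block$roc
      tsv(data.frame(threshold = r$thresholds, tpr = r$tpr, fpr = r$fpr),
          "roc_points.tsv")
    }
    fits <- list()
    for (lin in names(mx$univariable))
      if (!isTRUE(mx$univariable[[lin]]$skipped))
        fits[[lin]] <- logistic_rows(mx$univariable[[lin]],
                                     paste0("univariable_", lin))
    if (!isTRUE(mx$multivariable$skipped))
      fits[["multi"]] <- logistic_rows(mx$multivariable, "multivariable")
    if (length(fits) > 0) tsv(do.call(rbind, fits), "logistic_fits.tsv")
  }
  ec <- report$early_cc
  if (!isTRUE(ec$skipped)) {
    kmt <- rbind(cbind(group = "CC", ec$km_cc$table),
                 cbind(group = "MC", ec$km_mc$table))
    tsv(kmt, "km_curves.tsv")
  }
  kn <- report$kinetics
  if (!isTRUE(kn$skipped)) {
    cur <- list()
    for (comp in COMPARTMENTS) {
      if (is.null(kn[[comp]])) next
      for (lin in names(kn[[comp]]$curves))
        cur[[paste(comp, lin)]] <- cbind(compartment = comp, lineage = lin,
                                         kn[[comp]]$curves[[lin]])
    }
    if (length(cur) > 0) tsv(do.call(rbind, cur), "kinetics_curves.tsv")
  }
  invisible(dir)
}
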