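#!/usr/bin/env Rscript
# Early complete-chimerism risk stratification: %min = lowest blood CD3
# value in the first 60 days; transplants are split into CC/MC at a
# Youden-derived cutoff and their relapse-free survival compared
# (Kaplan-Meier, log-rank, 2-year estimates), per age group.

suppressPackageStartupMessages(library(linchim))

co <- load_cohort("results/cohort/transplants.tsv",
                  "results/cohort/measurements.tsv")
dir.create("results/early_cc", recursive = TRUE, showWarnings = FALSE)

rows <- list()
for (grp in c("all", "pediatric", "adult")) {
  cfg <- analysis_config(age_group = grp, cutoff_mode = "youden")
  ec <- run_early_cc_analysis(co, cfg)
  if (isTRUE(ec$skipped)) {
    cat(sprintf("[%s] skipped: %s\n", grp, ec$reason))
    next
  }
  cat(sprintf("[%s] n = %d (early relapses excluded); derived CC cutoff %.2f%%\n",
              grp, ec$n, ec$cutoff))
  cat(sprintf("  CC %d vs MC %d; 2-yr relapse-free %.0f%% (%.0f-%.0f) vs %.0f%% (%.0f-%.0f); log-rank p = %.3g\n",
              ec$n_cc, ec$n_mc,
              100 * ec$rfs_cc$estimate, 100 * ec$rfs_cc$lower, 100 * ec$rfs_cc$upper,
              100 * ec$rfs_mc$estimate, 100 * ec$rfs_mc$lower, 100 * ec$rfs_mc$upper,
              ec$logrank$p_value))
  rows[[grp]] <- data.frame(age_group = grp, n = ec$n, cutoff = ec$cutoff,
                            n_cc = ec$n_cc, n_mc = ec$n_mc,
                            rfs2y_cc = ec$rfs_cc$estimate,
                            rfs2y_mc = ec$rfs_mc$estimate,
                            logrank_p = ec$logrank$p_value)
  write_report(list(meta = list(), paired = list(skipped = TRUE),
                    maxchim = list(skipped = TRUE), early_cc = ec,
                    kinetics = list(skipped = TRUE)),
               file.path("results/early_cc", grp))
}
utils::write.table(do.call(rbind, rows), "results/early_cc/summary.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("Kaplan-Meier curves written under results/early_cc/.\n")
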