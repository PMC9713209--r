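# Small hand-built cohorts used across test files.

make_transplants <- function(ids, relapse_day = NA, censor_day = 2000,
                             age_years = 40) {
  n <- length(ids)
  data.frame(transplant_id = ids,
             patient_id = paste0("p", seq_len(n), recycle0 = TRUE),
             age_years = rep_len(age_years, n),
             relapse_day = rep_len(relapse_day, n),
             censor_day = rep_len(censor_day, n),
             conditioning = rep_len("MAC", n), atg = rep_len(0L, n),
             source = rep_len("PB", n), donor = rep_len("MUD", n),
             stringsAsFactors = FALSE)
}

make_measurements <- function(transplant_id, day, compartment = "marrow",
                              lineage = "CD3", percent = 1) {
  n <- max(length(transplant_id), length(day),
           if (length(transplant_id) > 0) length(percent) else 0)
  data.frame(transplant_id = rep_len(transplant_id, n),
             day = rep_len(day, n),
             compartment = rep_len(compartment, n),
             lineage = rep_len(lineage, n),
             percent_recipient = rep_len(percent, n),
             stringsAsFactors = FALSE)
}

tiny_cohort <- function(relapse_day = NA, days = c(20, 100, 180),
                        percent = c(0.5, 1.7, 0.3), compartment = "marrow",
                        lineage = "CD3") {
  cohort(make_transplants("t1", relapse_day = relapse_day),
         make_measurements("t1", days, compartment, lineage, percent))
}

# Null-structure simulation kinetics: no pre-relapse CD3 signal.
null_kinetics <- function(...) {
  utils::modifyList(list(cd3_bump_amplitude = 1e-9), list(...))
}

# Study condition for the parameter-recovery analyses: balanced engrafter
# classes, the early-CC/relapse link calibrated to a 0.90 vs 0.65 two-year
# relapse-free contrast, and no competing pre-relapse CD3 signal.
recovery_params <- function(n = 500, seed = 1) {
  sim_params(n_transplants = n, seed = seed,
             cc_failure_link = cc_link(enabled = TRUE, rfs_cc = 0.90,
                                       rfs_mc = 0.65),
             kinetics = list(mc_fraction = 0.5, cd3_bump_amplitude = 1e-9))
}

# The interval that separates the two engrafter classes' early %min by
# construction: above the detection limit, below the slow class's latent
# day-60 value (10 * 2^(-60/30) = 2.5).
recovery_separating_interval <- function(params = recovery_params()) {
  kin <- params$kinetics
  c(kin$lod_percent,
    kin$engraftment_start_percent * 2^(-60 / kin$halflife_slow))
}
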