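# linchim

Lineage-specific donor–recipient chimerism analysis for relapse prediction
after allogeneic hematopoietic stem cell transplantation (HSCT).

After HSCT for acute lymphoblastic leukemia, recipient DNA re-appearing in
sorted cell fractions (CD3⁺, CD19⁺, CD33⁺, CD34⁺; "percent recipient",
0 = complete donor chimerism) can flag an emerging relapse while there is
still time to intervene. `linchim` implements two complementary analyses of
longitudinal chimerism monitoring data, the full supporting statistics, and
a synthetic-cohort generator so everything is testable without patient
data:

* **Landmark %max prediction** — per transplant, the highest chimerism
  value in the window from 30 days post-HSCT to 30 days before relapse
  (non-relapsed transplants truncated at the relapse group's mean relapse
  time minus 30 days); %max is evaluated as a relapse predictor by
  logistic regression and ROC analysis with a Youden-optimal cutoff
  (J = sensitivity + specificity − 1).
* **Early complete-chimerism stratification** — per transplant, the lowest
  blood value in the first 60 days (%min); transplants with at least one
  value strictly below a cutoff count as early complete chimerism (CC),
  the rest as mixed chimerism (MC), and the groups' relapse-free survival
  is compared by Kaplan–Meier with Greenwood intervals and the log-rank
  test.

The statistics engine (ROC/AUC/Youden, logistic IRLS with Wald intervals,
Kaplan–Meier, log-rank, Fisher exact, χ², Mann–Whitney U, LOESS) is
implemented from first principles and verified in the test suite against
brute-force oracles and the standard R implementations.

## Worked example

```r
library(linchim)

co <- generate_cohort(sim_params(n_transplants = 138, seed = 7))
co
#> <chim_cohort> 138 transplants (33 relapsed), 5747 measurements

mx <- run_maxchim_analysis(co, analysis_config(age_group = "adult"))
mx$roc_block$roc
#> <roc_result> AUC 0.673 | Youden cutoff 2.124 (J 0.413, sens 0.52, spec 0.89) | 21 pos / 63 neg
```

Among the 84 adult transplants with retained marrow CD3⁺ data, a single
chimerism value of ≥ 2.1% anywhere in the landmark window flags a future
relapse with 52% sensitivity and 89% specificity (AUC 0.68) on this
simulated cohort.

```r
ec <- run_early_cc_analysis(co, analysis_config())
round(c(cutoff = ec$cutoff, rfs2y_cc = ec$rfs_cc$estimate,
        rfs2y_mc = ec$rfs_mc$estimate, logrank_p = ec$logrank$p_value), 4)
#>    cutoff  rfs2y_cc  rfs2y_mc logrank_p
#>    0.3485    0.8815    0.6078    0.0000
```

Transplants reaching early complete donor chimerism in blood CD3⁺ cells
(at least one value < 0.35%, cutoff derived by Youden) have an 88%
probability of being relapse-free at 2 years versus 61% without it
(log-rank p = 4e-5) — the generator plants this structure via its latent
fast/slow engrafter classes.

The numbered scripts under `analysis/` run the full workflow on a simulated
cohort and write all tables under `results/`:

```sh
Rscript analysis/01_simulate.R           # cohort TSVs + parameter provenance
Rscript analysis/02_paired_correlation.R # same-day blood/marrow concordance
Rscript analysis/03_landmark_maxchim.R   # %max filtration, logistic, ROC
Rscript analysis/04_early_cc.R           # %min, CC/MC, Kaplan-Meier, log-rank
Rscript analysis/05_kinetics.R           # relapse-aligned LOESS kinetics
```

See `vignettes/chimerism-analysis.Rmd` for the model, every tunable
parameter, and the design decisions.

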