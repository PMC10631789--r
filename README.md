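# threatseg

Resting-state brain-network **segregation** and **top-down threat bias** in
pain perception: an end-to-end, fully testable R implementation of the
analysis chain used in cued-pain connectomics studies.

People differ in how much a threat cue ("the incoming heat stimulus is at
70–80% intensity") inflates their pain report when the actual stimulus is
held constant.  That *threat bias* is scored behaviorally from
constant-temperature runs, and related to how segregated the subject's
resting-state functional networks are.  The package provides every stage:

* **Synthetic cohorts** with planted effects (`generator_config()`,
  `generate_cohort()`, `generate_roi_timeseries()`, `generate_trials()`,
  `generate_motion()`, `write_cohort()`) — a factor-model connectome whose
  within/between-network coupling is controlled by a per-subject
  segregation latent, and pain ratings mixing cued expectation with
  thermal input.
* **Task behavior**: run schedules (`build_schedule()`), the threat-bias
  score (`compute_threat_bias()`), K-means bias groups with a stability
  band (`assign_bias_groups()`).
* **Connectivity**: Pearson matrices with negative/diagonal cleanup
  (`correlation_matrix()`), Fisher z (`fisher_z()`), proportional
  thresholding over the 0.20–0.50 grid (`proportional_threshold()`,
  `threshold_grid()`), and FD/DVARS quality control (`qc_metrics()`).
* **System segregation**: `system_segregation()` computes
  `SS = (z̄_w − z̄_b) / z̄_w` per network and whole-brain;
  `segregation_profile()` sweeps subjects × scans × parcellations ×
  thresholds; `connection_counts()` tallies surviving edges by network
  block.
* **Subject-specific modules**: from-scratch modularity (`modularity_q()`)
  and Louvain (`louvain()`), divisive Girvan–Newman (`girvan_newman()`),
  `subject_specific_segregation()`.
* **Inference**: Shapiro-gated Pearson/Spearman correlations with optional
  motion covariates (`brain_behavior_correlation()`), group t-tests
  (`group_difference()`), mixed repeated-measures ANOVA with
  Greenhouse–Geisser correction (`rm_anova()`), rest-to-task change
  (`rest_to_task_change()`).
* **Orchestration**: `run_pipeline(pipeline_config(...))` plus a CLI
  (`threatseg_cli()`; subcommands `simulate`, `bias`, `run`, ...).

## Worked example

```r
library(threatseg)
cfg <- pipeline_config(
  generator = generator_config(n_subjects = 30, seed = 42),
  scans = c("rest", "task1"), grid = threshold_grid())
res <- run_pipeline(cfg)
res$correlations[, c("threshold", "method", "R", "p_value", "n")]
#>  threshold   method          R   p_value  n
#>       0.20 spearman -0.2965517 0.1182624 29
#>       0.25 spearman -0.2857143 0.1329784 29
#>       0.30 spearman -0.2901478 0.1268048 29
#>       0.35 spearman -0.2876847 0.1302081 29
#>       0.40 spearman -0.2911330 0.1254619 29
#>       0.45 spearman -0.3014778 0.1119868 29
#>       0.50 spearman -0.3083744 0.1036215 29
table(res$groups$group)
#> high_bias  low_bias
#>        15        15
round(c(mean(res$bias$bias), sd(res$bias$bias)), 2)
#> [1] -34.16  19.54
```

Reading the output: each row correlates whole-brain resting-state system
segregation at one sparsity threshold with the threat-bias score (negative
R: more segregated subjects are more cue-reliant, i.e. have more negative
bias scores).  The generator planted a brain–behavior correlation of −0.4;
at n = 30 the estimate sits near −0.3 with wide error (one subject was
dropped by the DVARS quality rule, hence n = 29), while the acceptance
suite demonstrates recovery within ±0.1 at n = 500.  Bias scores average
−34 ± 20 rating points and K-means splits the cohort 15/15.

## Layout

* `R/` — implementation; `tests/testthat/` — unit, property and acceptance
  suites (oracle-backed: exhaustive partition enumeration, closed-form
  factor-model covariance, textbook formulas).
* `vignettes/threatseg-methods.Rmd` — the model, its assumptions, what the
  generator does and does not emulate, and all numerical choices.
* `scripts/acceptance.R` — the acceptance report; `inst/cli/threatseg` —
  command-line launcher.
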