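test_that("generator config validates its invariants", {
  expect_error(generator_config(brain_behavior_rho = 1.2), "\\[-1, 1\\]")
  expect_error(generator_config(within_coupling_range = c(0.2, 0.4),
                                between_coupling_range = c(0.3, 0.5)),
               "below within")
  expect_error(generator_config(n_timepoints = 5), "n_timepoints")
})

test_that("cohort latents are reproducible and live in [0,1]", {
  cfg <- generator_config(n_subjects = 50, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_true(all(a$segregation_latent >= 0 & a$segregation_latent <= 1))
  expect_true(all(a$bias_weight >= 0 & a$bias_weight <= 1))
})

test_that("planted latent correlations are recovered", {
  # independence case: |cor| < 3/sqrt(n)
  cfg0 <- generator_config(n_subjects = 2000, brain_behavior_rho = 0,
                           seed = 21)
  l0 <- generate_cohort(cfg0)
  expect_lt(abs(cor(l0$segregation_latent, l0$bias_weight)), 3 / sqrt(2000))

  # strong planted value: the (segregation, bias_weight) pair carries the
  # NEGATIVE of brain_behavior_rho because the bias score runs negative in
  # bias_weight (score convention: more negative = more biased)
  cfg <- generator_config(n_subjects = 5000, brain_behavior_rho = 0.9,
                          seed = 22)
  l <- generate_cohort(cfg)
  expect_equal(cor(l$segregation_latent, l$bias_weight), -0.9,
               tolerance = 0.03 / 0.9)
  # psych latent carries psych_rho with its own sign
  cfgp <- generator_config(n_subjects = 5000, psych_rho = 0.5, seed = 23)
  lp <- generate_cohort(cfgp)
  expect_equal(cor(lp$segregation_latent, lp$psych_latent), 0.5,
               tolerance = 0.06)
})

test_that("factor model plants the configured couplings", {
  # closed form: within-network r = a + b = r_w, between r = b = r_b
  cfg <- generator_config(n_subjects = 1, n_networks = 3,
                          rois_per_network = 4, n_timepoints = 20000,
                          within_coupling_range = c(0.6, 0.6),
                          between_coupling_range = c(0.2, 0.2), seed = 31)
  lat <- generate_cohort(cfg)
  parc <- threatseg:::generator_parcellation(3, 4)
  ts <- generate_roi_timeseries(lat[1, ], parc, cfg)
  r <- cor(ts)
  same <- outer(parc$network, parc$network, "==")
  iu <- upper.tri(r)
  expect_equal(mean(r[iu & same]), 0.6, tolerance = 0.02 / 0.6)
  expect_equal(mean(r[iu & !same]), 0.2, tolerance = 0.02 / 0.2)
})

test_that("degenerate coupling limits behave as the model predicts", {
  parc <- threatseg:::generator_parcellation(2, 3)
  # exchangeable limit: within == between coupling -> SS near 0
  cfg <- generator_config(n_subjects = 1, n_networks = 2,
                          rois_per_network = 3, n_timepoints = 5000,
                          within_coupling_range = c(0.4001, 0.4001),
                          between_coupling_range = c(0.4, 0.4), seed = 41)
  lat <- generate_cohort(cfg)
  ts <- generate_roi_timeseries(lat[1, ], parc, cfg)
  sr <- system_segregation(fisher_z(correlation_matrix(ts)), parc)
  expect_lt(abs(sr$ss[sr$scope == "whole_brain"]), 0.1)
})

test_that("trial ratings follow the generative mixture", {
  sched <- build_schedule("mismatch_level2_high", seed = 5)
  cfg <- generator_config(n_subjects = 1, noise_sd = 0, seed = 51)

  # w = 0: ratings depend on temperature only -> constant in level-2, bias 0
  lat0 <- list(subject_id = "s0", segregation_latent = 0.5, bias_weight = 0)
  t0 <- generate_trials(lat0, sched, cfg)
  b0 <- compute_threat_bias(t0)
  expect_equal(b0$bias, 0)

  # w = 1: rating = cue midpoint, bias = mean(low cues) - mean(high cues)
  lat1 <- list(subject_id = "s1", segregation_latent = 0.5, bias_weight = 1)
  t1 <- generate_trials(lat1, sched, cfg)
  b1 <- compute_threat_bias(t1)
  rng <- t1$cue_kind == "range"
  lo <- t1$cue_value[rng & t1$cue_value <= 32]
  hi <- t1$cue_value[rng & t1$cue_value >= 70]
  expect_equal(b1$bias, mean(lo) - mean(hi))

  # w = 0.5, noisy: bias matches direct recomputation of the formula from
  # the emitted table
  cfg2 <- generator_config(n_subjects = 1, noise_sd = 3, seed = 52)
  lat5 <- list(subject_id = "s5", segregation_latent = 0.5, bias_weight = 0.5)
  t5 <- generate_trials(lat5, sched, cfg2)
  b5 <- compute_threat_bias(t5)
  keep <- t5$cue_kind == "range" & t5$temperature_c == 47
  lo5 <- t5$rating[keep & t5$cue_value >= 8 & t5$cue_value <= 32]
  hi5 <- t5$rating[keep & t5$cue_value >= 70 & t5$cue_value <= 98]
  expect_equal(b5$bias, mean(lo5) - mean(hi5))
  expect_true(all(t5$rating >= 0 & t5$rating <= 100))
})

test_that("expected bias score decreases in bias_weight on level-2 runs", {
  sched <- build_schedule("mismatch_level2_high", seed = 6)
  cfg <- generator_config(n_subjects = 1, noise_sd = 0, seed = 61)
  bias_at <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(w) {
    lat <- list(subject_id = "s", segregation_latent = 0.5, bias_weight = w)
    compute_threat_bias(generate_trials(lat, sched, cfg))$bias
  }, numeric(1))
  expect_true(all(diff(bias_at) < 0))
})

test_that("schedules without a level-2 high run are rejected", {
  cfg <- generator_config(n_subjects = 1, seed = 7)
  lat <- list(subject_id = "s", segregation_latent = 0.5, bias_weight = 0.5)
  expect_error(
    generate_trials(lat, list(build_schedule("matched", 1)), cfg),
    "mismatch_level2_high")
})

test_that("motion generator: zero jitter, spikes, determinism", {
  cfg <- generator_config(n_subjects = 1, n_timepoints = 50, seed = 71)
  lat <- list(subject_id = "s", segregation_latent = 0.5, bias_weight = 0.5)
  m0 <- generate_motion(lat, cfg, jitter_sd_mm = 0, jitter_sd_rad = 0)
  expect_equal(framewise_displacement(m0), rep(0, 50))
  # injected 3.5 mm jump -> FD formula gives a frame above 3 mm
  ms <- generate_motion(lat, cfg, jitter_sd_mm = 0, jitter_sd_rad = 0,
                        spike_mm = 3.5)
  expect_gt(max(framewise_displacement(ms)), 3)
  expect_identical(generate_motion(lat, cfg), generate_motion(lat, cfg))
})

test_that("psych scores keep subscale identities and planted coupling", {
  cfg <- generator_config(n_subjects = 800, psych_rho = 0.6, seed = 81)
  lat <- generate_cohort(cfg)
  ps <- generate_psych_scores(lat, cfg)
  expect_true(all(ps$pcs_total >= ps$rumination))
  expect_true(all(ps$rumination + ps$magnification + ps$helplessness ==
                    ps$pcs_total))
  expect_true(all(ps$pcs_total >= 0))
  expect_gt(cor(lat$segregation_latent, ps$pcs_total, method = "spearman"),
            0.3)
})

test_that("write_cohort emits the documented file layout", {
  dir <- withr::local_tempdir()
  cfg <- generator_config(n_subjects = 2, n_networks = 2,
                          rois_per_network = 3, n_timepoints = 30, seed = 91)
  man <- write_cohort(cfg, dir, scans = c("rest", "task1"))
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(all(file.exists(file.path(dir, man$path))))
  expect_true("sub001_rest.tsv" %in% man$path)
  ts <- as.matrix(read.table(file.path(dir, "sub001_rest.tsv")))
  expect_equal(dim(ts), c(30, 6))
  # byte-identical rerun
  dir2 <- withr::local_tempdir()
  write_cohort(cfg, dir2, scans = c("rest", "task1"))
  for (f in man$path)
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
})
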