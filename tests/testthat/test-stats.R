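test_that("normality gate decides by Shapiro-Wilk at alpha = 0.05", {
  set.seed(31)
  g <- normality_gate(rnorm(200))
  expect_equal(g$decision, "normal")
  expect_true(g$W <= 1)
  # right-skewed exponential at n = 200 has essentially full power
  expect_equal(normality_gate(rexp(200))$decision, "non_normal")
  expect_error(normality_gate(c(1, 2)), "n >= 3")
  expect_error(normality_gate(rep(1, 10)), "constant")
})

test_that("brain-behavior correlation matches the textbook oracle", {
  x <- c(2.1, 3.3, 1.8, 4.0, 2.9, 3.6, 1.2, 4.4)
  y <- c(12, 9, 14, 6, 10, 8, 15, 5)
  r <- brain_behavior_correlation(x, y, method = "pearson")
  expect_equal(r$estimate, oracle_pearson(x, y), tolerance = 1e-12)
  expect_equal(r$df, 6)
  # exact anti-correlation
  expect_equal(brain_behavior_correlation(x, -x,
                                          method = "pearson")$estimate, -1)
  expect_error(brain_behavior_correlation(x, rep(1, 8),
                                          method = "pearson"), "variance")
  expect_error(brain_behavior_correlation(x[1:3], y[1:3]), "n >=")
})

test_that("the gate routes non-normal samples to Spearman", {
  set.seed(32)
  x <- rexp(60)^2                      # heavily skewed
  y <- x + rnorm(60, 0, 0.1)
  r <- brain_behavior_correlation(x, y)
  expect_equal(r$method, "spearman")
  # Spearman invariance under monotone transforms
  r2 <- brain_behavior_correlation(exp(x / 5), y)
  expect_equal(r2$estimate, r$estimate, tolerance = 1e-12)
  rn <- brain_behavior_correlation(rnorm(60), rnorm(60))
  expect_equal(rn$method, "pearson")
})

test_that("partial correlation residualizes on covariates", {
  set.seed(33)
  z <- rnorm(50)
  x <- z + rnorm(50, 0, 0.5)
  # y identical to the covariate -> partial correlation ~ 0, p ~ 1
  r <- brain_behavior_correlation(x, z, covariates = data.frame(z = z),
                                  method = "pearson")
  expect_lt(abs(r$estimate), 1e-10)
  expect_equal(r$df, 50 - 3)
  # oracle: residualize by hand and correlate
  y <- z + rnorm(50, 0, 0.5)
  rp <- brain_behavior_correlation(x, y, covariates = data.frame(z = z),
                                   method = "pearson")
  ex <- residuals(lm(x ~ z)); ey <- residuals(lm(y ~ z))
  expect_equal(rp$estimate, oracle_pearson(ex, ey), tolerance = 1e-12)
})

test_that("group difference matches the pooled-variance closed form", {
  g <- group_difference(c(1, 2, 3), c(4, 5, 6))
  # pooled sd = 1, se = sqrt(2/3), t = -3/se
  expect_equal(g$estimate, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(g$df, 4)
  # antisymmetry
  g2 <- group_difference(c(4, 5, 6), c(1, 2, 3))
  expect_equal(g2$estimate, -g$estimate)
  expect_equal(g2$p_value, g$p_value)
  # identical groups -> t = 0, p = 1
  set.seed(34)
  x <- rnorm(10)
  gi <- group_difference(x, x)
  expect_equal(gi$estimate, 0)
  expect_equal(gi$p_value, 1)
  expect_error(group_difference(1, c(1, 2)), "n >= 2")
  expect_equal(group_difference(c(1, 2, 3), c(4, 5, 6),
                                welch = TRUE)$method, "welch_t")
})

make_profile <- function(ss_array, subjects, scans, thresholds) {
  grid <- expand.grid(subject = subjects, scan = scans,
                      threshold = thresholds, stringsAsFactors = FALSE)
  grid$parcellation <- "p"
  grid$scope <- "whole_brain"
  grid$z_within <- NA; grid$z_between <- NA
  grid$ss <- as.vector(ss_array)
  grid
}

test_that("rm_anova recovers a hand-worked 2x2x2 decomposition", {
  # 2 subjects x 2 scans x 2 thresholds, within-only design
  # ss[subject, scan, threshold]
  ss <- array(c(1, 2,   3, 5,     # threshold 1: scan1 (1,2), scan2 (3,5)
                2, 3,   5, 8),    # threshold 2
              dim = c(2, 2, 2))
  prof <- make_profile(ss, c("s1", "s2"), c("rest", "task"), c(0.2, 0.5))
  res <- rm_anova(prof)
  # hand decomposition: scan effect from subject-by-scan means
  m_subj_scan <- apply(ss, c(1, 2), mean)       # s x scan
  ss_scan <- 2 * sum((colMeans(m_subj_scan) - mean(ss))^2) * 2
  err_scan <- 2 * sum((m_subj_scan - outer(rowMeans(m_subj_scan),
                                           colMeans(m_subj_scan), "+") +
                         mean(ss))^2)
  f_scan <- (ss_scan / 1) / (err_scan / 1)
  expect_equal(res$F[res$effect == "scan"], f_scan, tolerance = 1e-10)
  # permuting subject order leaves F unchanged
  prof2 <- prof
  prof2$subject <- ifelse(prof2$subject == "s1", "s2", "s1")
  res2 <- rm_anova(prof2)
  expect_equal(res2$F, res$F, tolerance = 1e-10)
})

test_that("rm_anova with a pure group offset loads on the between effect", {
  subjects <- sprintf("s%02d", 1:10)
  scans <- c("rest", "task1"); ths <- c(0.2, 0.3)
  prof <- expand.grid(subject = subjects, scan = scans, threshold = ths,
                      stringsAsFactors = FALSE)
  prof$parcellation <- "p"; prof$scope <- "whole_brain"
  prof$z_within <- NA; prof$z_between <- NA
  base <- ifelse(as.integer(sub("s", "", prof$subject)) <= 5, 0.8, 0.4)
  set.seed(35)
  prof$ss <- base + rnorm(nrow(prof), 0, 0.005)  # pure group offset + jitter
  groups <- data.frame(subject_id = subjects,
                       group = rep(c("high_bias", "low_bias"), each = 5),
                       stringsAsFactors = FALSE)
  res <- rm_anova(prof, groups)
  f_group <- res$F[res$effect == "group"]
  expect_gt(f_group, 100)              # offset dwarfs the jitter
  within_p <- res$p_value[res$effect %in% c("scan", "threshold",
                                            "scan:threshold")]
  expect_true(all(within_p > 0.05))    # no planted within-subject effect
})

test_that("rm_anova drops subjects with incomplete cells, with a warning", {
  ss <- array(rnorm(12), dim = c(3, 2, 2))
  prof <- make_profile(ss, c("s1", "s2", "s3"), c("a", "b"), c(0.2, 0.5))
  prof <- prof[!(prof$subject == "s3" & prof$scan == "b"), ]
  expect_warning(res <- rm_anova(prof), "incomplete")
  expect_true(all(res$df2[res$effect == "scan"] == 1))
})

test_that("greenhouse-geisser epsilon is 1 for 2-level factors and <= 1", {
  set.seed(36)
  ss <- array(rnorm(40, 1, 0.2), dim = c(5, 2, 4))
  prof <- make_profile(ss, sprintf("s%d", 1:5), c("a", "b"),
                       c(0.2, 0.3, 0.4, 0.5))
  res <- rm_anova(prof)
  eps_scan <- res$gg_epsilon[res$effect == "scan"]
  expect_equal(eps_scan, 1, tolerance = 1e-10)  # 2 levels: sphericity trivial
  eps_thr <- res$gg_epsilon[res$effect == "threshold"]
  expect_true(eps_thr <= 1 + 1e-10 && eps_thr >= 1 / 3 - 1e-10)
})

test_that("rest_to_task_change: deltas, planted shift, paired-t oracle", {
  # identical SS across scans -> all paired deltas 0
  subjects <- sprintf("s%02d", 1:8)
  prof <- expand.grid(subject = subjects,
                      scan = c("rest", "task1", "task2b"), threshold = 0.2,
                      stringsAsFactors = FALSE)
  prof$parcellation <- "p"; prof$scope <- "whole_brain"
  prof$z_within <- NA; prof$z_between <- NA
  set.seed(37)
  base <- runif(8, 0.4, 0.8)
  prof$ss <- base[match(prof$subject, subjects)]
  groups <- data.frame(subject_id = subjects,
                       group = rep(c("high_bias", "low_bias"), 4),
                       stringsAsFactors = FALSE)
  rc <- suppressWarnings(rest_to_task_change(prof, groups))
  expect_true(all(is.nan(rc$paired_tests$t) | rc$paired_tests$t == 0))

  # planted group-by-scan shift: detected in the shifted group only
  prof2 <- prof
  hi <- groups$subject_id[groups$group == "high_bias"]
  shift <- prof2$subject %in% hi & prof2$scan == "task2b"
  prof2$ss[shift] <- prof2$ss[shift] - 0.2
  prof2$ss <- prof2$ss + rnorm(nrow(prof2), 0, 0.01)
  rc2 <- rest_to_task_change(prof2, groups)
  t_hi <- rc2$paired_tests$t[rc2$paired_tests$group == "high_bias"]
  p_lo <- rc2$paired_tests$p_value[rc2$paired_tests$group == "low_bias"]
  expect_gt(t_hi, 4)                  # task1 - task2b > 0 strongly
  expect_gt(p_lo, 0.05)

  # 3-subject hand table against the closed-form paired t
  a <- c(0.9, 0.8, 0.7); b <- c(0.6, 0.65, 0.45)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  prof3 <- data.frame(subject = rep(c("x", "y", "z"), 2),
                      scan = rep(c("task1", "task2b"), each = 3),
                      threshold = 0.2, parcellation = "p",
                      scope = "whole_brain", z_within = NA, z_between = NA,
                      ss = c(a, b), stringsAsFactors = FALSE)
  g3 <- data.frame(subject_id = c("x", "y", "z"), group = "high_bias",
                   stringsAsFactors = FALSE)
  rc3 <- rest_to_task_change(prof3, g3)
  expect_equal(rc3$paired_tests$t, t_hand, tolerance = 1e-12)
  # leave-one-scan-out drops the scan from the means table
  rc4 <- rest_to_task_change(prof3, g3, drop_scan = "task2b")
  expect_false("task2b" %in% rc4$means$scan)
})
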