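#' Shapiro-Wilk normality gate
#'
#' Decides between parametric and nonparametric correlation: samples with
#' Shapiro-Wilk p < alpha are flagged non-normal and sent to Spearman.
#'
#' @param x numeric sample, n >= 3 (Shapiro-Wilk needs n in 3..5000).
#' @param alpha significance level of the gate.
#' @return list: `decision` ("normal"/"non_normal"), `W`, `p_value`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3) stop_ts("normality gate needs n >= 3")
  if (sd(x) == 0) stop_ts("constant sample: normality undefined")
  sw <- shapiro.test(x)
  list(decision = if (sw$p.value < alpha) "non_normal" else "normal",
       W = unname(sw$statistic), p_value = sw$p.value)
}

stats_result <- function(method, estimate, p_value, df = NA_real_, n) {
  structure(list(method = method, estimate = unname(estimate),
                 p_value = unname(p_value), df = df, n = n),
            class = "stats_result")
}

#' @export
print.stats_result <- function(x, ...) {
  dfs <- if (all(is.na(x$df))) "" else
    sprintf("(%s)", paste(signif(x$df, 4), collapse = ", "))
  cat(sprintf("<%s%s: estimate %.4f, p = %.4g, n = %d>\n",
              x$method, dfs, x$estimate, x$p_value, x$n))
  invisible(x)
}

residualize <- function(y, covariates) {
  d <- data.frame(y = y, covariates)
  residuals(lm(y ~ ., data = d))
}

#' Brain-behavior correlation with normality gating and nuisance covariates
#'
#' Pearson correlation when both variables pass the Shapiro-Wilk gate,
#' Spearman otherwise (the gate is skipped when `method` is forced).  With
#' covariates (e.g. maximum FD and maximum DVARS), both variables are
#' residualized on the covariates by linear regression and the residuals
#' are correlated (partial correlation); degrees of freedom are reduced
#' accordingly.
#'
#' @param x,y numeric vectors of equal length.
#' @param covariates optional data.frame / list of numeric nuisance
#'   variables.
#' @param method `"auto"` (normality-gated), `"pearson"` or `"spearman"`.
#' @param alpha gate level.
#' @return a `stats_result` (estimate = R).
#' @export
brain_behavior_correlation <- function(x, y, covariates = NULL,
                                       method = c("auto", "pearson",
                                                  "spearman"),
                                       alpha = 0.05) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop_ts("x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    ok <- ok & complete.cases(covariates)
  }
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  n_cov <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n < 4 + n_cov) stop_ts("need n >= %d observations", 4 + n_cov)
  if (sd(x) == 0 || sd(y) == 0) stop_ts("zero variance in x or y")
  if (method == "auto") {
    method <- if (normality_gate(x, alpha)$decision == "normal" &&
                  normality_gate(y, alpha)$decision == "normal")
      "pearson" else "spearman"
  }
  if (!is.null(covariates)) {
    covariates <- covariates[ok, , drop = FALSE]
    vx <- var(x); vy <- var(y)
    x <- residualize(x, covariates)
    y <- residualize(y, covariates)
    # a variable fully explained by the covariates has a null residual:
    # its partial correlation with anything is 0 by convention
    if (var(x) < 1e-12 * vx || var(y) < 1e-12 * vy)
      return(stats_result(paste0("partial_", method), 0, 1,
                          df = n - 2 - n_cov, n = n))
    r <- cor(x, y, method = method)
    df <- n - 2 - n_cov
    tval <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(-abs(tval), df)
    return(stats_result(paste0("partial_", method), r, p, df = df, n = n))
  }
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  stats_result(method, ct$estimate, ct$p.value,
               df = if (method == "pearson") unname(ct$parameter) else
                 NA_real_, n = n)
}

#' Independent-samples group difference
#'
#' Two-sided independent t-test, pooled-variance (Student) by default with
#' a Welch option.
#'
#' @param high,low numeric samples (convention: high-bias group first, so a
#'   negative t means lower values in `high`... sign follows `high - low`).
#' @param welch use Welch's unequal-variance test.
#' @return a `stats_result` (estimate = t).
#' @export
group_difference <- function(high, low, welch = FALSE) {
  if (length(high) < 2 || length(low) < 2)
    stop_ts("each group needs n >= 2")
  tt <- t.test(high, low, var.equal = !welch)
  stats_result(if (welch) "welch_t" else "student_t", tt$statistic,
               tt$p.value, df = unname(tt$parameter),
               n = length(high) + length(low))
}

# Greenhouse-Geisser epsilon for a within effect given the subject x cell
# matrix and an orthonormal contrast C (df x cells)
gg_epsilon <- function(Y, C) {
  S <- cov(Y)
  M <- C %*% S %*% t(C)
  d <- nrow(C)
  (sum(diag(M)))^2 / (d * sum(M^2))
}

# orthonormal polynomial-free contrast matrix with k-1 rows
effect_contrast <- function(k) {
  C <- contr.helmert(k)
  t(C) / sqrt(colSums(C^2))
}

#' Repeated-measures ANOVA on a segregation profile
#'
#' Mixed-design ANOVA with within-subject factors scan type and threshold
#' and an optional between-subject bias-group factor, computed by the
#' classical univariate (aov Error-strata) decomposition.  For each within
#' effect a Greenhouse-Geisser epsilon is reported alongside the
#' uncorrected F, with sphericity-corrected p.  Subjects missing any cell
#' of the scan x threshold grid are dropped with a warning.
#'
#' @param profile long data.frame from [segregation_profile()]; only
#'   `scope == "whole_brain"` rows are used.
#' @param groups optional data.frame from [assign_bias_groups()]; subjects
#'   marked `excluded` are dropped.  Omit for a within-only design.
#' @return data.frame: `effect`, `df1`, `df2`, `F`, `p_value`,
#'   `gg_epsilon`, `p_gg`.
#' @export
rm_anova <- function(profile, groups = NULL) {
  d <- profile[profile$scope == "whole_brain", ]
  d$scan <- factor(d$scan)
  d$threshold <- factor(d$threshold)
  d$subject <- factor(d$subject)
  cells <- nlevels(d$scan) * nlevels(d$threshold)
  cnt <- table(d$subject)
  bad <- names(cnt)[cnt != cells]
  if (length(bad)) {
    warning(sprintf("dropping %d subject(s) with incomplete cells: %s",
                    length(bad), paste(bad, collapse = ", ")), call. = FALSE)
    d <- d[!d$subject %in% bad, ]
    d$subject <- droplevels(d$subject)
  }
  if (!is.null(groups)) {
    groups <- groups[groups$group != "excluded", ]
    d <- d[d$subject %in% groups$subject_id, ]
    d$subject <- droplevels(d$subject)
    d$group <- factor(groups$group[match(d$subject, groups$subject_id)])
    fit <- aov(ss ~ group * scan * threshold +
                 Error(subject / (scan * threshold)), data = d)
  } else {
    fit <- aov(ss ~ scan * threshold + Error(subject / (scan * threshold)),
               data = d)
  }
  rows <- list()
  for (stratum in names(summary(fit))) {
    tab <- summary(fit)[[stratum]][[1]]
    eff <- trimws(rownames(tab))
    for (i in seq_len(nrow(tab))) {
      if (eff[i] == "Residuals") next
      rows[[length(rows) + 1]] <- data.frame(
        effect = eff[i], df1 = tab[i, "Df"],
        df2 = tab[nrow(tab), "Df"], F = tab[i, "F value"],
        p_value = tab[i, "Pr(>F)"], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  # GG epsilon per within effect from the subject x cell wide matrix
  wide <- tapply(d$ss, list(d$subject, interaction(d$scan, d$threshold,
                                                   lex.order = TRUE)), mean)
  ks <- nlevels(d$scan); kt <- nlevels(d$threshold)
  Cs <- effect_contrast(ks); Ct <- effect_contrast(kt)
  # main effects average over the other factor (unit uniform row); row
  # scaling cancels in the epsilon ratio
  us <- matrix(rep(1, ks) / sqrt(ks), 1)
  ut <- matrix(rep(1, kt) / sqrt(kt), 1)
  eps_for <- function(effect) {
    C <- switch(effect,
                scan = Cs %x% ut,
                threshold = us %x% Ct,
                `scan:threshold` = Cs %x% Ct,
                NULL)
    if (is.null(C)) return(NA_real_)
    gg_epsilon(wide, C)
  }
  res$gg_epsilon <- vapply(sub("^group:", "", res$effect), eps_for,
                           numeric(1))
  res$p_gg <- ifelse(is.na(res$gg_epsilon), res$p_value,
                     pf(res$F, res$df1 * res$gg_epsilon,
                        res$df2 * res$gg_epsilon, lower.tail = FALSE))
  rownames(res) <- NULL
  res
}

#' Rest-to-task segregation change
#'
#' Per-group mean SS for every scan and threshold, plus paired t-tests
#' between named scan pairs within each group, optionally excluding a scan
#' from the summary (leave-one-scan-out re-run).
#'
#' @param profile long data.frame from [segregation_profile()]
#'   (whole-brain rows are used).
#' @param groups data.frame from [assign_bias_groups()].
#' @param scan_pairs list of length-2 character vectors to compare
#'   (default: Task 1 vs the later task runs).
#' @param drop_scan optional scan label excluded from the means table.
#' @return list: `means` (group x scan x threshold mean SS) and
#'   `paired_tests` (per group/pair/threshold t, df, p).
#' @export
rest_to_task_change <- function(profile, groups,
                                scan_pairs = list(c("task1", "task2b")),
                                drop_scan = NULL) {
  d <- profile[profile$scope == "whole_brain", ]
  groups <- groups[groups$group != "excluded", ]
  d <- d[d$subject %in% groups$subject_id, ]
  d$group <- groups$group[match(d$subject, groups$subject_id)]
  md <- d[!(d$scan %in% drop_scan), ]
  means <- aggregate(ss ~ group + scan + threshold, data = md, FUN = mean)
  tests <- list()
  for (g in unique(d$group)) {
    for (pair in scan_pairs) {
      for (th in unique(d$threshold)) {
        a <- d[d$group == g & d$scan == pair[1] & d$threshold == th, ]
        b <- d[d$group == g & d$scan == pair[2] & d$threshold == th, ]
        common <- intersect(a$subject, b$subject)
        if (length(common) < 2) {
          warning(sprintf("group %s: fewer than 2 subjects for %s vs %s",
                          g, pair[1], pair[2]), call. = FALSE)
          next
        }
        av <- a$ss[match(common, a$subject)]
        bv <- b$ss[match(common, b$subject)]
        tt <- t.test(av, bv, paired = TRUE)
        tests[[length(tests) + 1]] <- data.frame(
          group = g, scan_a = pair[1], scan_b = pair[2], threshold = th,
          t = unname(tt$statistic), df = unname(tt$parameter),
          p_value = tt$p.value, n = length(common),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(means = means,
       paired_tests = if (length(tests)) do.call(rbind, tests) else NULL)
}
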