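#' Temperature mapping of the matched (training) run
#'
#' In the matched run each 10-point rise in cued threat maps to a 0.4 degree
#' C rise in stimulus temperature over the 43.8-47.0 degrees C range: decile
#' index `floor((cue_low - 1) / 10)`, temperature `43.8 + 0.4 * decile`,
#' clamped at 47.0.
#'
#' @param cue_low lower bound of the cued 10-point percentage range (>= 1).
#' @param origin temperature of the lowest decile, degrees C.
#' @param step per-decile increment, degrees C.
#' @param t_max ceiling temperature, degrees C.
#' @return temperature in degrees C.
#' @export
matched_temperature <- function(cue_low, origin = 43.8, step = 0.4,
                                t_max = 47.0) {
  stopifnot(all(cue_low >= 1))
  pmin(origin + step * floor((cue_low - 1) / 10), t_max)
}

# level-1 mismatched mapping: low cue band -> 45.0, high band -> 47.0
level1_temperature <- function(cue_value) {
  ifelse(cue_value <= 40, 45.0,
         ifelse(cue_value >= 60, 47.0, NA_real_))
}

schedule_trials <- function(cue_low, cue_high, temperature_c,
                            cue_kind = "range") {
  mid <- (cue_low + cue_high) / 2
  mid[cue_kind != "range"] <- NA_real_
  data.frame(cue_kind = cue_kind, cue_low = cue_low, cue_high = cue_high,
             cue_value = mid, temperature_c = temperature_c,
             stringsAsFactors = FALSE)
}

#' Build a pain-task run schedule
#'
#' Four run types mirror the cued-threat protocol:
#' \describe{
#'   \item{matched}{cues predict intensity linearly; temperature follows
#'     [matched_temperature()] (0.4 degrees C per cue decile from 43.8,
#'     capped at 47.0).}
#'   \item{mismatch_level1}{cues 1-40 paired with 45.0 degrees C, cues
#'     60-100 with 47.0 degrees C.}
#'   \item{mismatch_level2_high}{every trial at the 47.0 degrees C maximum;
#'     low cues span 8-32, high cues 70-98 - the run the threat-bias score
#'     is computed from.}
#'   \item{mismatch_level2_low}{every trial at 45.0 degrees C.}
#' }
#' Each run also carries a pair of "unknown"-cue trials, which never enter
#' quantitative scores.
#'
#' @param run_type one of the four run types above.
#' @param seed integer; trial order is shuffled reproducibly.
#' @param n_repeats how many times the run's cue set is repeated.
#' @return an object of class `pain_schedule`: list with `run_type` and a
#'   `trials` data.frame (`cue_kind`, `cue_low`, `cue_high`, `cue_value`
#'   = range midpoint, `temperature_c`).
#' @examples
#' build_schedule("mismatch_level2_high", seed = 1)
#' @export
build_schedule <- function(run_type = c("matched", "mismatch_level1",
                                        "mismatch_level2_high",
                                        "mismatch_level2_low"),
                           seed = 1L, n_repeats = 2L) {
  run_type <- match.arg(run_type)
  base <- switch(run_type,
    matched = {
      lo <- seq(1, 81, by = 10)                 # deciles 0..8; top decile at cap
      schedule_trials(lo, lo + 10, matched_temperature(lo))
    },
    mismatch_level1 = {
      lo <- c(1, 11, 21, 30, 60, 70, 80, 90)
      tr <- schedule_trials(lo, lo + 10, NA_real_)
      tr$temperature_c <- level1_temperature(tr$cue_value)
      tr
    },
    mismatch_level2_high = {
      lo <- c(8, 15, 22, 70, 78, 88)            # midpoints 13,20,27,75,83,93
      schedule_trials(lo, lo + 10, 47.0)
    },
    mismatch_level2_low = {
      lo <- c(8, 15, 22, 70, 78, 88)
      schedule_trials(lo, lo + 10, 45.0)
    })
  trials <- base[rep(seq_len(nrow(base)), n_repeats), ]
  unknown <- schedule_trials(NA_real_, NA_real_,
                             temperature_c = rep(if (run_type ==
                               "mismatch_level2_high") 47.0 else 45.0, 2),
                             cue_kind = "unknown")
  trials <- rbind(trials, unknown)
  ord <- with_seed(substream_seed(seed, "schedule", run_type),
                   sample.int(nrow(trials)))
  trials <- trials[ord, ]
  rownames(trials) <- NULL
  rng <- trials$cue_kind == "range"
  stopifnot(all(trials$cue_high[rng] - trials$cue_low[rng] == 10),
            all(trials$temperature_c >= 43.8 & trials$temperature_c <= 47.0))
  if (run_type == "mismatch_level2_high")
    stopifnot(all(trials$temperature_c == 47.0))
  structure(list(run_type = run_type, trials = trials),
            class = "pain_schedule")
}

#' Default four-run session
#'
#' One matched run, one level-1 mismatched run (Task 1) and two level-2
#' mismatched runs at the 47 degrees C maximum (Tasks 2a, 2b).
#'
#' @param seed integer seed for trial-order shuffles.
#' @return list of [build_schedule()] objects.
#' @export
default_schedules <- function(seed = 1L) {
  list(build_schedule("matched", seed),
       build_schedule("mismatch_level1", seed),
       build_schedule("mismatch_level2_high", substream_seed(seed, "2a")),
       build_schedule("mismatch_level2_high", substream_seed(seed, "2b")))
}

#' Compute the top-down threat-bias score
#'
#' The bias score is the difference between the averaged pain ratings for
#' low threat cues (cue values 8-32) and for maximum threat cues (70-98),
#' using only level-2 mismatched trials at the constant 47.0 degrees C
#' maximum.  Cues are matched inclusively on the trial's stored cue value
#' (range midpoint); "unknown"-cue trials are excluded.  Because the
#' stimulus is identical in both bands, any rating difference is
#' attributable to the cue: more negative scores mean stronger reliance on
#' top-down threat expectation.
#'
#' @param trials trial table with columns `subject_id`, `run_type`,
#'   `cue_kind`, `cue_value`, `temperature_c`, `rating`.
#' @param low_band,high_band inclusive cue-value bands.
#' @return data.frame with one row per subject: `subject_id`, `bias`,
#'   `n_low_trials`, `n_high_trials`.
#' @examples
#' tr <- data.frame(subject_id = "s1", run_type = "mismatch_level2_high",
#'                  cue_kind = "range", cue_value = c(13, 20, 75, 93),
#'                  temperature_c = 47, rating = c(30, 30, 70, 70))
#' compute_threat_bias(tr)   # bias = -40
#' @export
compute_threat_bias <- function(trials, low_band = c(8, 32),
                                high_band = c(70, 98)) {
  keep <- trials$run_type == "mismatch_level2_high" &
    trials$temperature_c == 47.0 & trials$cue_kind == "range" &
    !is.na(trials$cue_value)
  tr <- trials[keep, , drop = FALSE]
  out <- lapply(split(tr, tr$subject_id), function(d) {
    lo <- d$rating[d$cue_value >= low_band[1] & d$cue_value <= low_band[2]]
    hi <- d$rating[d$cue_value >= high_band[1] & d$cue_value <= high_band[2]]
    if (!length(lo))
      stop_ts("subject %s: no level-2 trials in the low cue band [%g, %g]",
              d$subject_id[1], low_band[1], low_band[2])
    if (!length(hi))
      stop_ts("subject %s: no level-2 trials in the high cue band [%g, %g]",
              d$subject_id[1], high_band[1], high_band[2])
    data.frame(subject_id = d$subject_id[1], bias = mean(lo) - mean(hi),
               n_low_trials = length(lo), n_high_trials = length(hi),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (is.null(res))
    stop_ts("no mismatch_level2_high trials at 47.0 degrees C in input")
  res
}

# one-dimensional 2-means: exhaustive scan over sorted split points gives
# the global within-cluster-SS optimum (clusters of 1-D 2-means are always
# intervals); Lloyd restarts are used only to measure assignment stability
split_scan_2means <- function(x) {
  ord <- order(x); xs <- x[ord]; n <- length(x)
  best <- NULL; best_w <- Inf
  for (k in seq_len(n - 1)) {
    w <- sum((xs[1:k] - mean(xs[1:k]))^2) +
      sum((xs[(k + 1):n] - mean(xs[(k + 1):n]))^2)
    if (w < best_w - 1e-12) { best_w <- w; best <- k }
  }
  lab <- integer(n); lab[ord[seq_len(best)]] <- 1L
  lab[ord[(best + 1):n]] <- 2L
  list(labels = lab, wcss = best_w,
       centers = c(mean(x[lab == 1L]), mean(x[lab == 2L])))
}

lloyd_1d <- function(x, centers, max_iter = 100) {
  for (it in seq_len(max_iter)) {
    d1 <- abs(x - centers[1]); d2 <- abs(x - centers[2])
    tie <- abs(d1 - d2) < 1e-9
    lab <- ifelse(d1 < d2, 1L, 2L)
    # equidistant points are genuinely ambiguous: coin-flip per restart so
    # the stability measure can see them
    if (any(tie)) lab[tie] <- sample(1:2, sum(tie), replace = TRUE)
    new_c <- c(mean(x[lab == 1L]), mean(x[lab == 2L]))
    if (anyNA(new_c)) return(NULL)
    if (max(abs(new_c - centers)) < 1e-12 && !any(tie))
      return(list(labels = lab, centers = new_c))
    centers <- new_c
  }
  list(labels = lab, centers = centers)
}

#' Assign subjects to high/low threat-bias groups by K-means
#'
#' Runs 1-D 2-means on the bias scores.  The reported partition is the
#' global within-cluster sum-of-squares optimum (exhaustive scan over
#' sorted split points).  Stability is measured by `n_restarts` seeded
#' Lloyd runs from random initializations, with equidistant points
#' re-assigned at random per restart: a subject's stability is the fraction
#' of restarts agreeing with the optimal partition's label, and subjects
#' below `stability_cutoff` are marked `excluded` - the analogue of the
#' cutoff band around the cluster boundary in the empirical analysis.  The
#' cluster with the more negative centroid (stronger bias) is `high_bias`.
#'
#' @param scores data.frame from [compute_threat_bias()] (columns
#'   `subject_id`, `bias`), or a named numeric vector of bias scores.
#' @param n_restarts number of Lloyd restarts (default 50).
#' @param stability_cutoff minimum agreement fraction (default 0.9).
#' @param seed integer seed.
#' @return data.frame: `subject_id`, `group` in
#'   `{high_bias, low_bias, excluded}`, `stability`.
#' @export
assign_bias_groups <- function(scores, n_restarts = 50L,
                               stability_cutoff = 0.9, seed = 1L) {
  if (is.numeric(scores))
    scores <- data.frame(subject_id = names(scores) %||%
                           sprintf("s%03d", seq_along(scores)),
                         bias = unname(scores), stringsAsFactors = FALSE)
  x <- scores$bias
  if (length(x) < 4) stop_ts("need >= 4 subjects with finite bias scores")
  if (any(!is.finite(x))) stop_ts("non-finite bias scores")
  if (diff(range(x)) < 1e-12)
    stop_ts("all bias scores identical: 2-means clustering is degenerate")
  opt <- split_scan_2means(x)
  # orientation: more negative centroid = high bias
  high_lab <- which.min(opt$centers)
  agree <- numeric(length(x))
  n_ok <- 0L
  with_seed(substream_seed(seed, "kmeans"), {
    for (r in seq_len(n_restarts)) {
      ctr <- sample(unique(x), 2L)
      fit <- lloyd_1d(x, ctr)
      if (is.null(fit)) next
      n_ok <- n_ok + 1L
      # align restart labels to the optimal partition via centroid order
      map <- integer(2)
      map[order(fit$centers)] <- order(opt$centers)
      agree <- agree + (map[fit$labels] == opt$labels)
    }
  })
  stability <- if (n_ok > 0) agree / n_ok else rep(NA_real_, length(x))
  group <- ifelse(opt$labels == high_lab, "high_bias", "low_bias")
  group[stability < stability_cutoff] <- "excluded"
  data.frame(subject_id = scores$subject_id, bias = x, group = group,
             stability = stability, stringsAsFactors = FALSE)
}
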