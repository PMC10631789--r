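#' Configuration for the synthetic cohort generator
#'
#' The generator emits everything the downstream pipeline consumes: ROI BOLD
#' time series with a planted modular correlation structure, per-trial pain
#' ratings mixing cued expectation with thermal input, motion-parameter
#' tables, and psychological scores coupled to the segregation latent.
#'
#' Per subject a `segregation_latent` s in \[0,1\] sets the within- and
#' between-network coupling by linear interpolation over the configured
#' ranges: within r_w rises with s, between r_b falls with s, so higher s
#' means a more segregated connectome.  A `bias_weight` w in \[0,1\] sets the
#' reliance on the threat cue versus the actual temperature when rating pain.
#' The two latents (plus a psychological latent) are tied by a Gaussian
#' copula so each planted pairwise correlation is independently controllable.
#'
#' `brain_behavior_rho` is the planted correlation between the segregation
#' latent and the *bias score*.  The bias score is mean(low-cue ratings) -
#' mean(high-cue ratings) and runs negative for cue-reliant subjects, so the
#' latent pair (s, w) is generated with correlation `-brain_behavior_rho`;
#' a planted rho of -0.4 yields segregated subjects that rely on the cue,
#' mirroring the direction of the empirical effect.
#'
#' @param n_subjects cohort size (the empirical cohort had 42 recruited, 39
#'   analyzed; default 39).
#' @param n_networks,rois_per_network connectome dimensions (default 5
#'   networks x 6 ROIs).
#' @param n_timepoints frames per scan; the resting scan of the emulated
#'   protocol has 500 volumes (default 500).
#' @param within_coupling_range,between_coupling_range numeric length-2:
#'   target Pearson r for within- and between-network ROI pairs at the
#'   extremes of the segregation latent.  Must satisfy max(between) <
#'   min(within).
#' @param brain_behavior_rho planted correlation between segregation latent
#'   and bias score, in \[-1, 1\].
#' @param psych_rho planted correlation between segregation latent and the
#'   psychological latent.
#' @param noise_sd standard deviation of the rating noise, NRS points.
#' @param task_integration_shift named numeric, per-scan downward shift of
#'   the segregation latent scaled by `bias_weight`: high-bias subjects
#'   integrate (desegregate) progressively across task runs, giving the
#'   rest-to-task analysis a plantable group-by-scan interaction.
#' @param seed integer root seed; every stage derives a named substream.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_subjects = 39L,
                             n_networks = 5L,
                             rois_per_network = 6L,
                             n_timepoints = 500L,
                             within_coupling_range = c(0.35, 0.70),
                             between_coupling_range = c(0.05, 0.30),
                             brain_behavior_rho = -0.4,
                             psych_rho = 0.3,
                             noise_sd = 5,
                             task_integration_shift = c(rest = 0, task1 = 0.08,
                                                        task2a = 0.16,
                                                        task2b = 0.24),
                             seed = 1L) {
  stopifnot(n_subjects >= 1, n_networks >= 2, rois_per_network >= 2,
            n_timepoints >= 10)
  if (abs(brain_behavior_rho) > 1 || abs(psych_rho) > 1)
    stop_ts("planted correlations must lie in [-1, 1]")
  wr <- sort(within_coupling_range); br <- sort(between_coupling_range)
  if (any(wr <= 0) || any(wr >= 1) || any(br < 0))
    stop_ts("coupling ranges must satisfy 0 < r_w < 1 and r_b >= 0")
  if (max(br) >= min(wr))
    stop_ts("between-network coupling must stay below within-network coupling")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_networks = as.integer(n_networks),
                 rois_per_network = as.integer(rois_per_network),
                 n_timepoints = as.integer(n_timepoints),
                 within_coupling_range = wr,
                 between_coupling_range = br,
                 brain_behavior_rho = brain_behavior_rho,
                 psych_rho = psych_rho,
                 noise_sd = noise_sd,
                 task_integration_shift = task_integration_shift,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Pearson correlation of two uniforms from a Gaussian copula with normal
# correlation rho is (6/pi) asin(rho/2); invert so planted values live on
# the uniform (latent) scale.
copula_rho <- function(target) 2 * sin(pi * target / 6)

#' Draw subject latents for a synthetic cohort
#'
#' Latents (segregation, bias weight, psychological) are uniforms in \[0,1\]
#' obtained by a Gaussian copula whose correlations are calibrated so the
#' *uniform-scale* Pearson correlations converge to the planted values:
#' cor(segregation, bias_weight) -> `-brain_behavior_rho` (see
#' [generator_config()] for the sign convention) and
#' cor(segregation, psych) -> `psych_rho`.
#'
#' @param config a [generator_config()].
#' @return data.frame of class `subject_latents` with columns `subject_id`,
#'   `segregation_latent`, `bias_weight`, `psych_latent`.
#' @examples
#' lat <- generate_cohort(generator_config(n_subjects = 10, seed = 7))
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  rho_sw <- copula_rho(-config$brain_behavior_rho)
  rho_sp <- copula_rho(config$psych_rho)
  # bias-psych coupling is induced only through the shared segregation
  # latent (conditional independence keeps the matrix PSD for any inputs)
  rho_wp <- rho_sw * rho_sp
  R <- matrix(c(1, rho_sw, rho_sp,
                rho_sw, 1, rho_wp,
                rho_sp, rho_wp, 1), 3, 3)
  L <- chol(R)
  n <- config$n_subjects
  z <- with_seed(substream_seed(config$seed, "cohort"),
                 matrix(rnorm(3 * n), n, 3)) %*% L
  u <- pnorm(z)
  structure(data.frame(subject_id = sprintf("sub%03d", seq_len(n)),
                       segregation_latent = u[, 1],
                       bias_weight = u[, 2],
                       psych_latent = u[, 3],
                       stringsAsFactors = FALSE),
            class = c("subject_latents", "data.frame"))
}

# coupling targets for one subject: latent interpolates r_w up, r_b down
coupling_for_latent <- function(s, config) {
  wr <- config$within_coupling_range; br <- config$between_coupling_range
  list(r_w = wr[1] + s * (wr[2] - wr[1]),
       r_b = br[2] - s * (br[2] - br[1]))
}

# latent used for a given scan: task scans shift segregated high-bias
# subjects toward integration
scan_latent <- function(latents, scan, config) {
  shift <- config$task_integration_shift[[scan]] %||% 0
  pmin(pmax(latents$segregation_latent - shift * latents$bias_weight, 0), 1)
}

#' Generate ROI time series for one subject
#'
#' Factor model: each ROI signal is `sqrt(a) * network factor +
#' sqrt(b) * global factor + sqrt(1 - a - b) * noise`, all factors i.i.d.
#' standard normal over time.  The population correlation is then `a + b`
#' for ROI pairs sharing a network and `b` otherwise, so `a = r_w - r_b`,
#' `b = r_b` plants the subject's coupling targets exactly (closed-form
#' oracle used by the tests).
#'
#' @param latents one row of [generate_cohort()] output (or a list with
#'   `subject_id`, `segregation_latent`, `bias_weight`).
#' @param parc a [parcellation()] covering the generated ROIs.
#' @param config a [generator_config()].
#' @param scan scan label; task scans shift the effective segregation latent
#'   (see [generator_config()]).
#' @return numeric T x N matrix (class `roi_timeseries`) with ROI ids as
#'   column names and attributes `subject_id`, `scan`.
#' @export
generate_roi_timeseries <- function(latents, parc, config, scan = "rest") {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_timepoints < 10) stop_ts("n_timepoints < 10")
  s <- scan_latent(latents, scan, config)
  cp <- coupling_for_latent(s, config)
  a <- cp$r_w - cp$r_b; b <- cp$r_b
  stopifnot(a >= 0, b >= 0, a + b < 1)
  nets <- factor(parc$network)
  N <- nrow(parc); Tn <- config$n_timepoints
  with_seed(substream_seed(config$seed, "ts", latents$subject_id, scan), {
    g <- rnorm(Tn)
    fnet <- matrix(rnorm(Tn * nlevels(nets)), Tn, nlevels(nets))
    eps <- matrix(rnorm(Tn * N), Tn, N)
    x <- sqrt(a) * fnet[, as.integer(nets), drop = FALSE] +
      sqrt(b) * g + sqrt(1 - a - b) * eps
    colnames(x) <- as.character(parc$roi_id)
    structure(x, subject_id = latents$subject_id, scan = scan,
              class = c("roi_timeseries", "matrix", "array"))
  })
}

# increasing map of temperature to [0,1] over the protocol's range
temp_to_unit <- function(temp_c) pmin(pmax((temp_c - 43.8) / (47.0 - 43.8), 0), 1)

#' Generate per-trial pain ratings for one subject
#'
#' Rating model: `rating = 100 * (w * cue/100 + (1 - w) * g(temp)) + noise`,
#' clamped to the 0-100 numerical rating scale, where `w` is the subject's
#' `bias_weight`, `cue` the cued threat midpoint (percent) and `g` the linear
#' map of temperature onto \[0,1\] over 43.8-47.0 degrees C.  Trials with an
#' "unknown" cue fall back to pure temperature drive.
#'
#' @inheritParams generate_roi_timeseries
#' @param schedule a [build_schedule()] object (or a list of them, which are
#'   concatenated).
#' @return a trial table data.frame: `subject_id`, `run_type`, `cue_kind`,
#'   `cue_value` (midpoint, NA for unknown cues), `temperature_c`, `rating`.
#' @export
generate_trials <- function(latents, schedule, config) {
  if (inherits(schedule, "pain_schedule")) schedule <- list(schedule)
  if (!length(schedule)) stop_ts("no schedules supplied")
  if (!any(vapply(schedule, function(s) s$run_type == "mismatch_level2_high",
                  logical(1))))
    stop_ts("schedule contains no mismatch_level2_high run; downstream threat bias would be undefined")
  w <- latents$bias_weight
  rows <- lapply(schedule, function(sch) {
    tr <- sch$trials
    cue_drive <- ifelse(is.na(tr$cue_value), temp_to_unit(tr$temperature_c),
                        tr$cue_value / 100)
    mu <- 100 * (w * cue_drive + (1 - w) * temp_to_unit(tr$temperature_c))
    data.frame(subject_id = latents$subject_id, run_type = sch$run_type,
               cue_kind = tr$cue_kind, cue_value = tr$cue_value,
               temperature_c = tr$temperature_c, mu = mu,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  noise <- with_seed(substream_seed(config$seed, "trials", latents$subject_id),
                     rnorm(nrow(out), 0, config$noise_sd))
  out$rating <- pmin(pmax(out$mu + noise, 0), 100)
  out$mu <- NULL
  out
}

#' Generate a motion-parameter table for one scan
#'
#' Emits the 6 rigid-body parameters (3 translations in mm, 3 rotations in
#' radians) as small seeded jitter, with an optional injected translation
#' spike to exercise the framewise-displacement exclusion rule.
#'
#' @inheritParams generate_roi_timeseries
#' @param jitter_sd_mm per-frame translation jitter SD, mm.
#' @param jitter_sd_rad per-frame rotation jitter SD, radians (rotations
#'   contribute to FD via a 50 mm sphere, so realistic values are ~1e-4).
#'   The defaults give mean FD around 0.1 mm, the scale typical of a
#'   compliant adult cohort.
#' @param spike_mm if nonzero, a translation jump of this many mm injected
#'   at `spike_frame`.
#' @param spike_frame frame index of the injected spike.
#' @return T x 6 numeric matrix, columns `trans_x..trans_z`, `rot_x..rot_z`.
#' @export
generate_motion <- function(latents, config, scan = "rest",
                            jitter_sd_mm = 0.02, jitter_sd_rad = 2e-4,
                            spike_mm = 0, spike_frame = NULL) {
  Tn <- config$n_timepoints
  m <- with_seed(substream_seed(config$seed, "motion", latents$subject_id, scan),
                 cbind(matrix(rnorm(Tn * 3, 0, jitter_sd_mm), Tn, 3),
                       matrix(rnorm(Tn * 3, 0, jitter_sd_rad), Tn, 3)))
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  if (spike_mm != 0) {
    i <- spike_frame %||% (Tn %/% 2)
    m[i:Tn, "trans_x"] <- m[i:Tn, "trans_x"] + spike_mm
  }
  m
}

#' Generate psychological scores coupled to the cohort latents
#'
#' Produces pain-catastrophizing (PCS total plus rumination, magnification
#' and helplessness subscales) and state/trait anxiety scores whose
#' correlation with the segregation latent is inherited from the planted
#' `psych_rho`, along with age and sex columns.  Subscale scores are
#' nonnegative and sum to the PCS total.
#'
#' @param latents output of [generate_cohort()].
#' @param config a [generator_config()].
#' @return data.frame, one row per subject.
#' @export
generate_psych_scores <- function(latents, config) {
  n <- nrow(latents)
  with_seed(substream_seed(config$seed, "psych"), {
    p <- latents$psych_latent
    jig <- function(sd) rnorm(n, 0, sd)
    # means / SDs in the range questionnaire norms report for healthy adults
    pcs_total <- pmax(0, round_half_up(12 + 10 * qnorm(p) + jig(3)))
    shares <- matrix(abs(rnorm(3 * n, c(0.45, 0.22, 0.33), 0.05)), n, 3,
                     byrow = TRUE)
    shares <- shares / rowSums(shares)
    rum <- round_half_up(pcs_total * shares[, 1])
    mag <- round_half_up(pcs_total * shares[, 2])
    help <- pcs_total - rum - mag
    data.frame(subject_id = latents$subject_id,
               pcs_total = pcs_total, rumination = rum, magnification = mag,
               helplessness = help,
               state_anxiety = pmax(20, round_half_up(32 + 9 * qnorm(p) + jig(3))),
               trait_anxiety = pmax(20, round_half_up(36 + 10 * qnorm(p) + jig(3))),
               age = pmin(56, pmax(20, round_half_up(31 + 11 * rnorm(n)))),
               sex = sample(c("F", "M"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

#' Write a synthetic cohort to disk
#'
#' Time series go to headerless TSV, one file per subject and scan, named
#' `<subject>_<scan>.tsv`; latents, trials, motion and psychological scores
#' to headered TSV; a `manifest.tsv` lists every emitted path.
#'
#' @param config a [generator_config()].
#' @param out_dir output directory (created if needed).
#' @param scans scan labels to emit.
#' @param parc parcellation; defaults to the generator-side balanced one.
#' @return invisibly, the manifest data.frame.
#' @export
write_cohort <- function(config, out_dir,
                         scans = c("rest", "task1", "task2a", "task2b"),
                         parc = NULL) {
  parc <- parc %||% generator_parcellation(config$n_networks,
                                           config$rois_per_network)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  latents <- generate_cohort(config)
  sched <- default_schedules(config$seed)
  paths <- character(0)
  emit <- function(obj, file, col.names = TRUE) {
    p <- file.path(out_dir, file)
    write.table(obj, p, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = col.names)
    paths <<- c(paths, file)
    p
  }
  emit(latents, "latents.tsv")
  write_parcellation(parc, file.path(out_dir, "parcellation.tsv"))
  paths <- c(paths, "parcellation.tsv")
  emit(generate_psych_scores(latents, config), "psych_scores.tsv")
  trials <- do.call(rbind, lapply(seq_len(nrow(latents)), function(i)
    generate_trials(latents[i, ], sched, config)))
  emit(trials, "trials.tsv")
  for (i in seq_len(nrow(latents))) {
    for (scan in scans) {
      ts <- generate_roi_timeseries(latents[i, ], parc, config, scan)
      emit(ts, sprintf("%s_%s.tsv", latents$subject_id[i], scan),
           col.names = FALSE)
      emit(generate_motion(latents[i, ], config, scan),
           sprintf("%s_%s_motion.tsv", latents$subject_id[i], scan))
    }
  }
  manifest <- data.frame(path = paths, stringsAsFactors = FALSE)
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
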