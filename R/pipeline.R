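#' Pipeline configuration
#'
#' A single config drives the whole analysis.  Either `input_dir` (a
#' directory written by [write_cohort()] or with the same layout) or
#' `generator` (a [generator_config()], data generated in memory) must be
#' given.
#'
#' @param generator a [generator_config()], or NULL when reading from disk.
#' @param input_dir cohort directory, or NULL when generating.
#' @param scans scan labels to process.
#' @param grid threshold proportions.
#' @param parcellations named list of [parcellation()]s; NULL means the
#'   generator-side balanced parcellation.
#' @param binarize binarize thresholded matrices.
#' @param community_method `"louvain"`, `"girvan-newman"` or `"none"`.
#' @param n_restarts,stability_cutoff K-means grouping settings.
#' @param use_motion_covariates partial out max FD / max DVARS in the
#'   brain-behavior correlation (verification variant; off by default).
#' @param seed root seed.
#' @param out_dir optional directory for stage outputs and the manifest.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(generator = generator_config(),
                            input_dir = NULL,
                            scans = c("rest", "task1", "task2a", "task2b"),
                            grid = threshold_grid(),
                            parcellations = NULL,
                            binarize = FALSE,
                            community_method = "none",
                            n_restarts = 50L,
                            stability_cutoff = 0.9,
                            use_motion_covariates = FALSE,
                            seed = 1L,
                            out_dir = NULL) {
  if (is.null(generator) && is.null(input_dir))
    stop_ts("either generator settings or an input directory is required")
  structure(list(generator = generator, input_dir = input_dir,
                 scans = scans, grid = grid, parcellations = parcellations,
                 binarize = binarize, community_method = community_method,
                 n_restarts = as.integer(n_restarts),
                 stability_cutoff = stability_cutoff,
                 use_motion_covariates = use_motion_covariates,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

read_cohort <- function(input_dir, scans) {
  latents <- read.table(file.path(input_dir, "latents.tsv"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
  parc <- read_parcellation(file.path(input_dir, "parcellation.tsv"))
  trials <- read.table(file.path(input_dir, "trials.tsv"), header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
  ts <- list(); motion <- list()
  for (sub in latents$subject_id) {
    ts[[sub]] <- list(); motion[[sub]] <- list()
    for (scan in scans) {
      f <- file.path(input_dir, sprintf("%s_%s.tsv", sub, scan))
      if (!file.exists(f)) next         # missing scan: recorded, not fatal
      m_ts <- as.matrix(read.table(f, sep = "\t"))
      dimnames(m_ts) <- list(NULL, as.character(parc$roi_id))
      ts[[sub]][[scan]] <- m_ts
      mf <- file.path(input_dir, sprintf("%s_%s_motion.tsv", sub, scan))
      if (file.exists(mf))
        motion[[sub]][[scan]] <- as.matrix(read.table(mf, sep = "\t",
                                                      header = TRUE))
    }
  }
  psych_path <- file.path(input_dir, "psych_scores.tsv")
  list(latents = latents, parc = parc, trials = trials, timeseries = ts,
       motion = motion,
       psych = if (file.exists(psych_path))
         read.table(psych_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE) else NULL)
}

simulate_cohort <- function(cfg) {
  gc <- cfg$generator
  latents <- generate_cohort(gc)
  parc <- generator_parcellation(gc$n_networks, gc$rois_per_network)
  sched <- default_schedules(gc$seed)
  trials <- do.call(rbind, lapply(seq_len(nrow(latents)), function(i)
    generate_trials(latents[i, ], sched, gc)))
  ts <- list(); motion <- list()
  for (i in seq_len(nrow(latents))) {
    sub <- latents$subject_id[i]
    ts[[sub]] <- list(); motion[[sub]] <- list()
    for (scan in cfg$scans) {
      ts[[sub]][[scan]] <- generate_roi_timeseries(latents[i, ], parc, gc,
                                                   scan)
      motion[[sub]][[scan]] <- generate_motion(latents[i, ], gc, scan)
    }
  }
  list(latents = latents, parc = parc, trials = trials, timeseries = ts,
       motion = motion, psych = generate_psych_scores(latents, gc))
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> QC -> connectivity -> segregation profile ->
#' optional subject-specific communities -> threat bias + groups -> stats.
#' Deterministic given the config: identical config and seed reproduce
#' identical outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return list of class `pipeline_result`: `profile`, `bias`, `groups`,
#'   `qc`, `correlations` (whole-brain SS vs bias per threshold),
#'   `group_tests`, `rm_anova`, `communities` (if requested), `psych`,
#'   `latents`, `manifest` (when `out_dir` is set).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  data <- if (!is.null(cfg$input_dir)) read_cohort(cfg$input_dir, cfg$scans)
          else simulate_cohort(cfg)
  parcs <- cfg$parcellations %||%
    setNames(list(data$parc), attr(data$parc, "name"))

  # --- QC stage
  qc <- list()
  for (sub in names(data$timeseries)) {
    qc[[sub]] <- list()
    for (scan in names(data$timeseries[[sub]])) {
      m <- data$motion[[sub]][[scan]]
      if (is.null(m)) next
      qc[[sub]][[scan]] <- qc_metrics(m, data$timeseries[[sub]][[scan]])
    }
  }

  # --- connectivity + segregation profile
  profile <- segregation_profile(data$timeseries, parcs, grid = cfg$grid,
                                 binarize = cfg$binarize, qc = qc)

  # --- behavior
  bias <- compute_threat_bias(data$trials)
  groups <- assign_bias_groups(bias, n_restarts = cfg$n_restarts,
                               stability_cutoff = cfg$stability_cutoff,
                               seed = cfg$seed)

  # --- optional subject-specific communities on the resting scan
  communities <- NULL
  if (cfg$community_method != "none") {
    communities <- lapply(names(data$timeseries), function(sub) {
      ts <- data$timeseries[[sub]][["rest"]]
      if (is.null(ts)) return(NULL)
      zm <- fisher_z(correlation_matrix(ts), clip = TRUE)
      tm <- proportional_threshold(zm, cfg$grid[1])
      part <- if (cfg$community_method == "louvain")
        louvain(tm, seed = substream_seed(cfg$seed, "louvain", sub))
      else girvan_newman(tm)
      seg <- subject_specific_segregation(tm, part)
      list(subject = sub, partition = part,
           ss = seg$ss[seg$scope == "whole_brain"])
    })
    names(communities) <- names(data$timeseries)
  }

  # --- stats: whole-brain rest SS vs bias per threshold
  rest <- profile[profile$scan == "rest" & profile$scope == "whole_brain", ]
  covs <- NULL
  if (cfg$use_motion_covariates) {
    covs <- data.frame(
      max_fd = vapply(names(qc), function(s)
        max(vapply(qc[[s]], `[[`, numeric(1), "max_fd")), numeric(1)),
      max_dvars = vapply(names(qc), function(s)
        max(vapply(qc[[s]], function(q) max(q$dvars), numeric(1))),
        numeric(1)))
    rownames(covs) <- names(qc)
  }
  correlations <- list()
  group_tests <- list()
  for (pn in names(parcs)) {
    for (th in cfg$grid) {
      r <- rest[rest$parcellation == pn & rest$threshold == th, ]
      m <- merge(r, bias, by.x = "subject", by.y = "subject_id")
      ct <- brain_behavior_correlation(m$ss, m$bias,
        covariates = if (is.null(covs)) NULL else covs[m$subject, ,
                                                       drop = FALSE])
      correlations[[length(correlations) + 1]] <- data.frame(
        parcellation = pn, threshold = th, method = ct$method,
        R = ct$estimate, p_value = ct$p_value, n = ct$n,
        stringsAsFactors = FALSE)
      mg <- merge(m, groups[, c("subject_id", "group")],
                  by.x = "subject", by.y = "subject_id")
      hi <- mg$ss[mg$group == "high_bias"]; lo <- mg$ss[mg$group == "low_bias"]
      if (length(hi) >= 2 && length(lo) >= 2) {
        # convention of the empirical report: low - high, negative t when
        # the high-bias group is more segregated
        gt <- group_difference(lo, hi)
        group_tests[[length(group_tests) + 1]] <- data.frame(
          parcellation = pn, threshold = th, t = gt$estimate,
          df = gt$df, p_value = gt$p_value, stringsAsFactors = FALSE)
      }
    }
  }
  correlations <- do.call(rbind, correlations)
  group_tests <- if (length(group_tests)) do.call(rbind, group_tests) else NULL

  anova_tab <- tryCatch(
    rm_anova(profile[profile$parcellation == names(parcs)[1], ], groups),
    error = function(e) NULL)

  out <- list(profile = profile, bias = bias, groups = groups, qc = qc,
              correlations = correlations, group_tests = group_tests,
              rm_anova = anova_tab, communities = communities,
              psych = data$psych, latents = data$latents, config = cfg)
  class(out) <- "pipeline_result"
  if (!is.null(cfg$out_dir)) out$manifest <- write_results(out, cfg$out_dir)
  out
}

write_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(obj, file) {
    write.table(obj, file.path(out_dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <<- c(paths, file)
  }
  put(res$profile, "segregation_profile.tsv")
  put(res$bias, "bias_scores.tsv")
  put(res$groups, "bias_groups.tsv")
  put(res$correlations, "brain_behavior_correlations.tsv")
  if (!is.null(res$group_tests)) put(res$group_tests, "group_tests.tsv")
  if (!is.null(res$rm_anova)) put(res$rm_anova, "rm_anova.tsv")
  manifest <- data.frame(path = paths, seed = res$config$seed,
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: %d subjects, %d profile rows>\n",
              length(unique(x$profile$subject)), nrow(x$profile)))
  cat("rest SS vs threat bias:\n")
  print(head(x$correlations, 10))
  invisible(x)
}

#' Command-line interface
#'
#' Subcommands: `simulate`, `qc`, `connectivity`, `segregation`,
#' `communities`, `bias`, `stats`, `run`.  Invoke via
#' `Rscript -e 'threatseg::threatseg_cli()' <subcommand> [options]`, or the
#' `inst/cli/threatseg` launcher.
#'
#' @param args character vector (defaults to the command line).
#' @return exit status, invisibly.
#' @export
threatseg_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: threatseg <simulate|qc|connectivity|segregation|communities|bias|stats|run> [options]\n")
    return(invisible(1L))
  }
  cmd <- args[1]; rest <- args[-1]
  opts <- list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = "threatseg_out"),
    optparse::make_option("--trials", type = "character", default = NULL),
    optparse::make_option("--timeseries", type = "character", default = NULL,
                          help = "cohort directory with <subject>_<scan>.tsv files"),
    optparse::make_option("--n-restarts", type = "integer", default = 50L,
                          dest = "n_restarts"),
    optparse::make_option("--stability-cutoff", type = "double",
                          default = 0.9, dest = "stability_cutoff"),
    optparse::make_option("--n-subjects", type = "integer", default = 39L,
                          dest = "n_subjects"),
    optparse::make_option("--method", type = "character", default = "louvain"),
    optparse::make_option("--binarize", action = "store_true",
                          default = FALSE))
  po <- optparse::parse_args(optparse::OptionParser(option_list = opts),
                             args = rest)
  gen <- generator_config(n_subjects = po$n_subjects, seed = po$seed)
  switch(cmd,
    simulate = {
      write_cohort(gen, po$out)
      message("cohort written to ", po$out)
    },
    bias = {
      if (is.null(po$trials)) stop_ts("bias: --trials is required")
      trials <- read.table(po$trials, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
      b <- compute_threat_bias(trials)
      g <- assign_bias_groups(b, n_restarts = po$n_restarts,
                              stability_cutoff = po$stability_cutoff,
                              seed = po$seed)
      dir.create(po$out, recursive = TRUE, showWarnings = FALSE)
      write.table(g, file.path(po$out, "bias_groups.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      message("bias groups written to ", po$out)
    },
    run = ,
    qc = ,
    connectivity = ,
    segregation = ,
    communities = ,
    stats = {
      cfg <- pipeline_config(
        generator = if (is.null(po$timeseries)) gen else NULL,
        input_dir = po$timeseries,
        community_method = if (cmd == "communities") po$method else "none",
        binarize = po$binarize, n_restarts = po$n_restarts,
        stability_cutoff = po$stability_cutoff, seed = po$seed,
        out_dir = po$out)
      run_pipeline(cfg)
      message("pipeline outputs written to ", po$out)
    },
    stop_ts("unknown subcommand '%s'", cmd))
  invisible(0L)
}
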