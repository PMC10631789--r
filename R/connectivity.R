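#' Connectivity-matrix container
#'
#' A symmetric N x N nonnegative edge-weight matrix with a processing-state
#' flag.  States form the pipeline order `raw_r` (Pearson r, negatives and
#' diagonal removed) -> `fisher_z` (atanh-transformed) -> `thresholded`
#' (proportional threshold applied, optionally binarized).
#'
#' @param values numeric N x N matrix.
#' @param state processing state.
#' @param threshold_p retained proportion (when thresholded).
#' @param binarized logical.
#' @return object of class `conn_matrix`.
#' @keywords internal
conn_matrix <- function(values, state = c("raw_r", "fisher_z", "thresholded"),
                        threshold_p = NA_real_, binarized = FALSE) {
  state <- match.arg(state)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (max(abs(values - t(values))) > 1e-10) stop_ts("matrix not symmetric")
  if (any(diag(values) != 0)) stop_ts("diagonal must be exactly 0")
  if (any(values < 0)) stop_ts("negative edge weights not allowed")
  structure(values, state = state, threshold_p = threshold_p,
            binarized = binarized, class = c("conn_matrix", "matrix", "array"))
}

cm_state <- function(cm) attr(cm, "state")

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix %d x %d, state=%s%s%s>\n", nrow(x), ncol(x),
              cm_state(x),
              if (!is.na(attr(x, "threshold_p")))
                sprintf(", p=%g", attr(x, "threshold_p")) else "",
              if (isTRUE(attr(x, "binarized"))) ", binarized" else ""))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' Pearson connectivity matrix from ROI time series
#'
#' Zero-lag Pearson correlations between all ROI pairs; the diagonal is
#' zeroed and negative correlations are removed (set to 0), following the
#' standard cleaning for segregation analyses.
#'
#' @param ts T x N numeric matrix (rows = timepoints, columns = ROIs).
#' @return a `conn_matrix` in state `raw_r`.
#' @export
correlation_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop_ts("need at least 3 timepoints")
  sds <- apply(ts, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0] %||% which(sds == 0)
    stop_ts("constant-valued ROI column(s): %s",
            paste(bad, collapse = ", "))
  }
  r <- cor(ts)
  diag(r) <- 0
  r[r < 0] <- 0
  dimnames(r) <- list(colnames(ts), colnames(ts))
  conn_matrix(r, "raw_r")
}

#' Fisher z-transform a connectivity matrix
#'
#' Elementwise `atanh`, the variance-stabilizing transform applied before
#' averaging correlations.  Entries at exactly 1 (duplicated signals) are
#' clipped to `r_max` first when `clip = TRUE`, otherwise raise an error.
#'
#' @param cm a `conn_matrix` in state `raw_r` with entries in \[0, 1\].
#' @param clip clip r >= 1 entries to `r_max` instead of erroring.
#' @param r_max clip value.
#' @return a `conn_matrix` in state `fisher_z`.
#' @export
fisher_z <- function(cm, clip = FALSE, r_max = 0.999999) {
  stopifnot(inherits(cm, "conn_matrix"))
  if (cm_state(cm) != "raw_r")
    stop_ts("fisher_z expects a raw_r matrix, got %s", cm_state(cm))
  v <- unclass(cm)
  if (any(v >= 1)) {
    if (!clip) stop_ts("correlation entries >= 1; rerun with clip = TRUE")
    v[v >= 1] <- r_max
  }
  conn_matrix(atanh(v), "fisher_z")
}

#' Proportional (sparsity) threshold
#'
#' Retains the `round(p * N(N-1)/2)` strongest edges (round half away from
#' zero, capped by the number of available positive edges) and zeroes the
#' rest.  Ties are broken by ascending node-index pair so results are
#' deterministic.  With `binarize = TRUE` surviving edges are set to 1,
#' turning weighted segregation into a connection-count density.
#'
#' @param cm a `conn_matrix` (`raw_r` or `fisher_z`).
#' @param p proportion of strongest connections to keep, in (0, 1\].
#' @param binarize map survivors to 1.
#' @return a `conn_matrix` in state `thresholded`.
#' @export
proportional_threshold <- function(cm, p, binarize = FALSE) {
  stopifnot(inherits(cm, "conn_matrix"))
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p > 1)
    stop_ts("threshold proportion must lie in (0, 1]")
  v <- unclass(cm)
  n <- nrow(v)
  iu <- which(upper.tri(v))
  w <- v[iu]
  k <- round_half_up(p * n * (n - 1) / 2)
  pos <- which(w > 0)
  k <- min(k, length(pos))
  keep <- integer(0)
  if (k > 0) {
    # order by weight desc, then ascending linear index (node-pair order)
    ord <- pos[order(-w[pos], iu[pos])]
    keep <- ord[seq_len(k)]
  }
  out <- matrix(0, n, n, dimnames = dimnames(v))
  out[iu[keep]] <- if (binarize) 1 else w[keep]
  out <- out + t(out)
  conn_matrix(out, "thresholded", threshold_p = p, binarized = binarize)
}

#' Default proportional-threshold grid
#'
#' Retention proportions from 0.20 to 0.50 in increments of 0.05 (seven
#' thresholds), the range over which result consistency is checked.
#'
#' @param from,to,by grid limits and step.
#' @return numeric vector of proportions.
#' @export
threshold_grid <- function(from = 0.20, to = 0.50, by = 0.05) {
  g <- seq(from, to, by = by)
  if (any(g <= 0 | g > 1)) stop_ts("threshold proportions must lie in (0, 1]")
  g
}

#' Framewise displacement from 6 rigid-body motion parameters
#'
#' FD per frame is the sum of absolute backward differences of the three
#' translations (mm) and the three rotations converted to arc length on a
#' 50 mm sphere.  The first frame has FD 0.
#'
#' @param motion T x 6 matrix: translations (mm) then rotations (radians).
#' @param radius_mm head-radius convention for rotations.
#' @return numeric length-T FD series.
#' @export
framewise_displacement <- function(motion, radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop_ts("motion table must have 6 columns")
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    radius_mm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' DVARS of an ROI time-series matrix
#'
#' Root-mean-square across ROIs of the backward temporal difference
#' (volume N to N+1); first frame is 0.
#'
#' @param ts T x N matrix.
#' @return numeric length-T DVARS series.
#' @export
dvars <- function(ts) {
  ts <- as.matrix(ts)
  c(0, sqrt(rowMeans(diff(ts)^2)))
}

#' Motion / signal quality control with exclusion rules
#'
#' Computes maximum FD and the DVARS series, flags DVARS outlier frames
#' (above median + 1.5 IQR of the series, first frame ignored) and applies
#' the exclusion rule: a scan is excluded when max FD exceeds `fd_limit_mm`
#' (3 mm) or when more than `dvars_outlier_limit` (10%) of frames are
#' DVARS outliers.
#'
#' @param motion T x 6 motion-parameter table.
#' @param ts T x N ROI time series from the same scan.
#' @param fd_limit_mm maximum-FD exclusion limit, mm.
#' @param dvars_outlier_limit maximum tolerated outlier fraction.
#' @return list of class `qc_metrics`: `max_fd`, `dvars` (series),
#'   `dvars_outlier_fraction`, `excluded`.
#' @export
qc_metrics <- function(motion, ts, fd_limit_mm = 3,
                       dvars_outlier_limit = 0.10) {
  motion <- as.matrix(motion); ts <- as.matrix(ts)
  if (nrow(motion) != nrow(ts))
    stop_ts("motion table (%d rows) does not align with time series (%d rows)",
            nrow(motion), nrow(ts))
  fd <- framewise_displacement(motion)
  dv <- dvars(ts)
  body <- dv[-1]
  cut <- median(body) + 1.5 * IQR(body)
  frac <- mean(body > cut)
  out <- list(max_fd = max(fd), dvars = dv, dvars_outlier_fraction = frac,
              excluded = max(fd) > fd_limit_mm || frac > dvars_outlier_limit)
  class(out) <- "qc_metrics"
  out
}

#' @export
print.qc_metrics <- function(x, ...) {
  cat(sprintf("<qc: max FD %.3f mm, DVARS outliers %.1f%%, %s>\n",
              x$max_fd, 100 * x$dvars_outlier_fraction,
              if (x$excluded) "EXCLUDED" else "retained"))
  invisible(x)
}

#' Read / write square connectivity matrices as delimited text
#' @param cm a `conn_matrix`; `path` file path; `sep` separator.
#' @param state,threshold_p,binarized state flags applied on read.
#' @export
write_conn_matrix <- function(cm, path, sep = "\t") {
  write.table(unclass(cm), path, sep = sep, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_conn_matrix
#' @export
read_conn_matrix <- function(path, sep = "\t", state = "raw_r",
                             threshold_p = NA_real_, binarized = FALSE) {
  v <- as.matrix(read.table(path, sep = sep, header = FALSE))
  dimnames(v) <- NULL
  conn_matrix(v, state, threshold_p = threshold_p, binarized = binarized)
}
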