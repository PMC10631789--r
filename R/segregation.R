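#' System segregation of a connectivity matrix under a parcellation
#'
#' System segregation (SS) contrasts mean within-network with mean
#' between-network connectivity:
#' \deqn{SS = (\bar z_w - \bar z_b) / \bar z_w}
#' where \eqn{\bar z_w} is the mean Fisher-z edge weight over all *possible*
#' within-network ROI pairs and \eqn{\bar z_b} the mean over all possible
#' between-network pairs; edges absent after thresholding contribute 0
#' weight, i.e. the denominators are possible-pair counts, not surviving
#' counts.  On a binarized matrix the same formula reduces to a
#' connection-count density contrast.  SS is at most 1, reaching 1 exactly
#' when no between-network edge survives while some within-network weight
#' does; higher values mean more autonomous subnetworks.
#'
#' The whole-brain value pools all same-network pairs against all
#' cross-network pairs.  Per-network values restrict to pairs touching that
#' network: within pairs inside it, between pairs linking it to any other
#' network.
#'
#' @param cm a `conn_matrix` in state `fisher_z` or `thresholded`.
#' @param parc a [parcellation()] whose `roi_id`s match the matrix columns
#'   (by name when present, by position otherwise).
#' @return data.frame with one `whole_brain` row plus one row per network:
#'   columns `scope`, `z_within`, `z_between`, `ss` (NA with a warning when
#'   `z_within` is 0), `n_within_pairs`, `n_between_pairs`.
#' @examples
#' v <- matrix(0, 4, 4)
#' v[1, 2] <- 0.6; v[3, 4] <- 0.4; v[1, 3] <- 0.2
#' v <- v + t(v)
#' cm <- threatseg:::conn_matrix(v, "fisher_z")
#' p <- parcellation(1:4, c("A", "A", "B", "B"))
#' system_segregation(cm, p)   # whole-brain ss = 0.9
#' @export
system_segregation <- function(cm, parc) {
  stopifnot(inherits(cm, "conn_matrix"))
  if (cm_state(cm) == "raw_r")
    stop_ts("system_segregation expects a fisher_z or thresholded matrix")
  v <- unclass(cm)
  n <- nrow(v)
  labs <- match_parcellation(parc, v)
  iu <- upper.tri(v)
  same <- outer(labs, labs, "==")
  res <- list(scope_row("whole_brain", v, iu & same, iu & !same))
  for (net in sort(unique(labs))) {
    inb <- outer(labs == net, labs == net, "&")
    # between pairs: exactly one endpoint in this network
    one_in <- xor(outer(labs == net, rep(TRUE, n), "&"),
                  outer(rep(TRUE, n), labs == net, "&"))
    res[[length(res) + 1]] <- scope_row(net, v, iu & inb, iu & one_in)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

scope_row <- function(scope, v, within_mask, between_mask) {
  nw <- sum(within_mask); nb <- sum(between_mask)
  zw <- if (nw > 0) sum(v[within_mask]) / nw else NA_real_
  zb <- if (nb > 0) sum(v[between_mask]) / nb else NA_real_
  ss <- if (!is.na(zw) && zw > 0) (zw - zb) / zw else {
    warning(sprintf("scope %s: mean within-network weight is 0, ss undefined",
                    scope), call. = FALSE)
    NA_real_
  }
  data.frame(scope = scope, z_within = zw, z_between = zb, ss = ss,
             n_within_pairs = nw, n_between_pairs = nb,
             stringsAsFactors = FALSE)
}

match_parcellation <- function(parc, v) {
  n <- nrow(v)
  if (nrow(parc) != n)
    stop_ts("parcellation covers %d ROIs but matrix has %d nodes",
            nrow(parc), n)
  if (!is.null(colnames(v))) {
    idx <- match(colnames(v), as.character(parc$roi_id))
    if (anyNA(idx))
      stop_ts("matrix columns not covered by parcellation: %s",
              paste(colnames(v)[is.na(idx)], collapse = ", "))
    parc$network[idx]
  } else parc$network
}

#' Count surviving connections within and between networks
#'
#' Summary used to ask whether a group shows more within-network or more
#' between-network connections after thresholding.
#'
#' @param cm a thresholded `conn_matrix`.
#' @param parc a [parcellation()].
#' @return list with `within` (named count per network), `between` (count
#'   per unordered network pair, names `"A|B"`), `n_within`, `n_between`,
#'   `n_total` (which always satisfies `n_within + n_between == n_total`).
#' @export
connection_counts <- function(cm, parc) {
  stopifnot(inherits(cm, "conn_matrix"))
  if (cm_state(cm) != "thresholded")
    stop_ts("connection_counts expects a thresholded matrix")
  v <- unclass(cm)
  labs <- match_parcellation(parc, v)
  iu <- which(upper.tri(v) & v > 0)
  i <- ((iu - 1) %% nrow(v)) + 1
  j <- ((iu - 1) %/% nrow(v)) + 1
  li <- labs[i]; lj <- labs[j]
  nets <- sort(unique(labs))
  within <- setNames(integer(length(nets)), nets)
  tw <- table(li[li == lj])
  within[names(tw)] <- as.integer(tw)
  pair_names <- apply(cbind(pmin(li, lj), pmax(li, lj)), 1, paste,
                      collapse = "|")
  all_pairs <- outer(nets, nets, function(a, b) paste(pmin(a, b),
                                                      pmax(a, b), sep = "|"))
  all_pairs <- unique(all_pairs[upper.tri(all_pairs)])
  between <- setNames(integer(length(all_pairs)), all_pairs)
  tb <- table(pair_names[li != lj])
  between[names(tb)] <- as.integer(tb)
  list(within = within, between = between,
       n_within = sum(within), n_between = sum(between),
       n_total = length(iu))
}

#' Segregation profile over subjects, scans, parcellations and thresholds
#'
#' Runs the full per-scan chain (correlation matrix, negative/diagonal
#' cleanup, Fisher z, proportional threshold, system segregation) for every
#' cell of the grid.  The whole-brain SS plus per-network SS values are
#' returned in long format, the pipeline's central outcome.
#'
#' @param timeseries nested list: `timeseries[[subject]][[scan]]` is a T x N
#'   matrix (a single matrix is accepted for one subject / one scan).
#' @param parcellations a [parcellation()] or named list of them.
#' @param grid numeric threshold proportions (default [threshold_grid()]).
#' @param binarize threshold to a binary adjacency before SS.
#' @param qc optional nested list of [qc_metrics()] mirroring `timeseries`;
#'   excluded scans are skipped.
#' @return long data.frame: `subject`, `scan`, `parcellation`, `threshold`,
#'   `scope`, `z_within`, `z_between`, `ss`.
#' @export
segregation_profile <- function(timeseries, parcellations,
                                grid = threshold_grid(), binarize = FALSE,
                                qc = NULL) {
  if (is.matrix(timeseries)) timeseries <- list(sub01 = list(scan = timeseries))
  if (inherits(parcellations, "parcellation"))
    parcellations <- setNames(list(parcellations),
                              attr(parcellations, "name"))
  out <- list()
  for (sub in names(timeseries)) {
    for (scan in names(timeseries[[sub]])) {
      if (!is.null(qc) && isTRUE(qc[[sub]][[scan]]$excluded)) next
      ts <- timeseries[[sub]][[scan]]
      if (is.null(ts)) next
      zm <- fisher_z(correlation_matrix(ts), clip = TRUE)
      for (pn in names(parcellations)) {
        for (p in grid) {
          tm <- proportional_threshold(zm, p, binarize = binarize)
          sr <- system_segregation(tm, parcellations[[pn]])
          sr$subject <- sub; sr$scan <- scan
          sr$parcellation <- pn; sr$threshold <- p
          out[[length(out) + 1]] <- sr
        }
      }
    }
  }
  if (!length(out)) stop_ts("no usable scans in input")
  res <- do.call(rbind, out)
  res[, c("subject", "scan", "parcellation", "threshold", "scope",
          "z_within", "z_between", "ss")]
}
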