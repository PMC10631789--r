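#' Create a parcellation (ROI-to-network labeling)
#'
#' A parcellation assigns every ROI to exactly one resting-state network and
#' defines which ROI pairs count as within-network versus between-network in
#' the system-segregation statistic.
#'
#' @param roi_id integer or character ROI identifiers (unique).
#' @param network network label per ROI (character or factor).
#' @param name scheme name, e.g. `"ho131_5net"`.
#' @return An object of class `parcellation`: a data.frame with columns
#'   `roi_id` and `network`, plus attributes `name` and `n_networks`.
#' @examples
#' p <- parcellation(1:6, rep(c("A", "B"), each = 3))
#' n_networks(p)
#' @export
parcellation <- function(roi_id, network, name = "custom") {
  if (length(roi_id) != length(network))
    stop_ts("roi_id and network must have equal length")
  if (anyDuplicated(roi_id))
    stop_ts("duplicate roi_id in parcellation '%s'", name)
  network <- as.character(network)
  tab <- table(network)
  if (length(tab) < 2)
    stop_ts("parcellation '%s' must contain at least 2 networks", name)
  if (any(tab < 2))
    stop_ts("every network needs >= 2 ROIs; too small: %s",
            paste(names(tab)[tab < 2], collapse = ", "))
  out <- data.frame(roi_id = roi_id, network = network,
                    stringsAsFactors = FALSE)
  structure(out, name = name, n_networks = length(tab),
            class = c("parcellation", "data.frame"))
}

#' @rdname parcellation
#' @param x a `parcellation`.
#' @export
n_networks <- function(x) attr(x, "n_networks")

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation '%s': %d ROIs in %d networks>\n",
              attr(x, "name"), nrow(x), attr(x, "n_networks")))
  print(table(x$network))
  invisible(x)
}

#' Read / write parcellation label tables
#'
#' Plain-text interchange format: a delimited table with columns
#' `roi_id` and `network_label`.
#'
#' @param path file path.
#' @param sep field separator.
#' @param name scheme name for the returned object (default: file name).
#' @return `read_parcellation()` returns a [parcellation()].
#' @export
read_parcellation <- function(path, sep = "\t", name = basename(path)) {
  d <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("roi_id", "network_label")
  if (!all(need %in% names(d)))
    stop_ts("parcellation file %s must have columns %s", path,
            paste(need, collapse = ", "))
  parcellation(d$roi_id, d$network_label, name = name)
}

#' @rdname read_parcellation
#' @param parc a `parcellation` to write.
#' @export
write_parcellation <- function(parc, path, sep = "\t") {
  write.table(data.frame(roi_id = parc$roi_id, network_label = parc$network),
              path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Built-in stand-in parcellation schemes
#'
#' Synthetic label tables mirroring the sizes of the three schemes used in
#' resting-state segregation work: a 131-ROI / 5-network scheme
#' (subcortical, sensory, default mode, attention/executive, language/memory),
#' a 52-ROI / 7-network scheme and a 114-ROI / 17-network scheme.  Only the
#' ROI counts and network counts are emulated; no atlas geometry is implied,
#' and ROI-to-network block sizes are balanced as evenly as the counts allow.
#'
#' @param scheme one of `"ho131_5net"`, `"yeo7_52roi"`, `"yeo17_114roi"`.
#' @return a [parcellation()].
#' @examples
#' builtin_parcellation("yeo7_52roi")
#' @export
builtin_parcellation <- function(scheme = c("ho131_5net", "yeo7_52roi",
                                            "yeo17_114roi")) {
  scheme <- match.arg(scheme)
  spec <- switch(scheme,
    ho131_5net = list(n = 131L, nets = c("subcortical", "sensory",
      "default_mode", "attention_executive", "language_memory")),
    yeo7_52roi = list(n = 52L, nets = c("visual", "somatomotor",
      "dorsal_attention", "ventral_attention", "limbic", "frontoparietal",
      "default_mode")),
    yeo17_114roi = list(n = 114L, nets = sprintf("net%02d", 1:17)))
  k <- length(spec$nets)
  sizes <- rep(spec$n %/% k, k)
  extra <- spec$n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  parcellation(seq_len(spec$n), rep(spec$nets, times = sizes), name = scheme)
}

# balanced generator-side parcellation used by the synthetic cohort
generator_parcellation <- function(n_networks, rois_per_network) {
  parcellation(seq_len(n_networks * rois_per_network),
               rep(sprintf("net%02d", seq_len(n_networks)),
                   each = rois_per_network),
               name = sprintf("synthetic_%dx%d", n_networks, rois_per_network))
}
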