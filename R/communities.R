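#' Newman-Girvan modularity of a partition
#'
#' Configuration-null modularity of a weighted undirected graph:
#' \deqn{Q = \frac{1}{2m} \sum_{ij} \left(A_{ij} - \frac{k_i k_j}{2m}\right)
#'   \delta(c_i, c_j)}
#' with \eqn{A} the symmetric edge-weight matrix, \eqn{k_i} weighted
#' degrees, \eqn{2m} the total weight and \eqn{\delta} the Kronecker delta.
#' A custom null matrix `P` may be supplied (general-null form); the
#' configuration null \eqn{P_{ij} = k_i k_j / 2m} is the default.
#'
#' @param cm a `conn_matrix` (any nonnegative symmetric state) or plain
#'   symmetric matrix.
#' @param membership integer/character community label per node.
#' @param null optional N x N expected-weight matrix replacing the
#'   configuration null.
#' @return scalar Q.
#' @export
modularity_q <- function(cm, membership, null = NULL) {
  A <- unclass(as.matrix(cm))
  n <- nrow(A)
  if (length(membership) != n) stop_ts("membership length != node count")
  two_m <- sum(A)
  if (two_m <= 0) stop_ts("empty graph: total edge weight is 0")
  P <- null %||% (rowSums(A) %o% colSums(A) / two_m)
  same <- outer(membership, membership, "==")
  sum((A - P)[same]) / two_m
}

as_partition <- function(membership, q) {
  m <- as.integer(factor(membership, levels = unique(membership)))
  list(assignment = m - 1L, n_communities = max(m), q = q)
}

#' Louvain community detection
#'
#' Standard two-phase heuristic at resolution 1: greedy local moves over a
#' seeded random sweep order until no move improves Q, then aggregation of
#' communities into super-nodes, repeated until convergence.  The best
#' partition over `n_runs` independently seeded runs is returned, and the
#' reported `q` is recomputed exactly with [modularity_q()].
#'
#' @param cm nonnegative symmetric weight matrix (or `conn_matrix`).
#' @param seed integer seed controlling sweep orders.
#' @param n_runs independent restarts (default 20).
#' @return list: `assignment` (0-based community per node),
#'   `n_communities`, `q`.
#' @export
louvain <- function(cm, seed = 1L, n_runs = 20L) {
  A <- unclass(as.matrix(cm))
  if (sum(A) <= 0) stop_ts("empty graph: total edge weight is 0")
  best <- NULL
  for (r in seq_len(n_runs)) {
    memb <- with_seed(substream_seed(seed, "louvain", r), louvain_once(A))
    q <- modularity_q(A, memb)
    if (is.null(best) || q > best$q + 1e-15) best <- as_partition(memb, q)
  }
  best
}

louvain_once <- function(A) {
  n <- nrow(A)
  node_comm <- seq_len(n)          # community of each original node
  W <- A                           # current aggregated graph
  repeat {
    res <- louvain_local_moves(W)
    # map original nodes through this level's assignment
    node_comm <- res$membership[node_comm]
    if (res$n_moves == 0 || length(unique(res$membership)) == nrow(W)) break
    W <- aggregate_graph(W, res$membership)
  }
  node_comm
}

# phase 1: greedy local moves; returns membership relabeled 1..k.
# W's diagonal may carry aggregated self-weight; it counts toward degree
# and total weight but is never a neighbor link.
louvain_local_moves <- function(W) {
  n <- nrow(W)
  two_m <- sum(W)
  k <- rowSums(W)
  comm <- seq_len(n)
  sigma_tot <- k                    # summed degree per community id
  n_moves_total <- 0
  repeat {
    n_moves <- 0
    for (i in sample.int(n)) {
      ci <- comm[i]
      links <- tapply(W[i, -i], comm[-i], sum)     # weight i -> community
      cand <- as.integer(names(links))
      sigma_tot[ci] <- sigma_tot[ci] - k[i]        # lift i out
      # Q contribution of placing i in community c (sigma excludes i):
      # 2*links_ic/2m - 2*k_i*sigma_c/(2m)^2
      val <- 2 * as.numeric(links) / two_m -
        2 * k[i] * sigma_tot[cand] / (two_m^2)
      stay <- val[match(ci, cand)]
      if (is.na(stay))                             # i had no links to ci
        stay <- -2 * k[i] * sigma_tot[ci] / (two_m^2)
      jbest <- which.max(val)
      if (length(jbest) && val[jbest] > stay + 1e-12) {
        comm[i] <- cand[jbest]
        n_moves <- n_moves + 1
      }
      sigma_tot[comm[i]] <- sigma_tot[comm[i]] + k[i]
    }
    n_moves_total <- n_moves_total + n_moves
    if (n_moves == 0) break
  }
  memb <- as.integer(factor(comm))
  list(membership = memb, n_moves = n_moves_total)
}

aggregate_graph <- function(W, membership) {
  k <- max(membership)
  M <- matrix(0, nrow(W), k)
  M[cbind(seq_len(nrow(W)), membership)] <- 1
  t(M) %*% W %*% M
}

#' Girvan-Newman community detection
#'
#' Divisive algorithm: repeatedly removes the edge with the highest
#' betweenness (recomputed after every removal; on weighted graphs shortest
#' paths use distance = 1/weight), tracking the component structure.  Among
#' the partitions in the resulting dendrogram the one maximizing
#' configuration-null modularity on the *original* graph is returned.
#' Betweenness ties are broken by ascending edge index, so the procedure is
#' deterministic.
#'
#' @param cm nonnegative symmetric weight matrix (or `conn_matrix`).
#' @return list: `assignment` (0-based), `n_communities`, `q`.
#' @export
girvan_newman <- function(cm) {
  A <- unclass(as.matrix(cm))
  if (sum(A) <= 0) stop_ts("empty graph: total edge weight is 0")
  n <- nrow(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  comp <- igraph::components(g)$membership
  best_memb <- comp
  best_q <- modularity_q(A, comp)
  while (igraph::ecount(g) > 0) {
    eb <- igraph::edge_betweenness(g, weights = 1 / igraph::E(g)$weight)
    # which.max returns the lowest index among ties -> deterministic
    g <- igraph::delete_edges(g, which.max(eb))
    memb <- igraph::components(g)$membership
    if (max(memb) > max(comp)) {        # a component split occurred
      q <- modularity_q(A, memb)
      if (q > best_q + 1e-15) { best_q <- q; best_memb <- memb }
      comp <- memb
    }
  }
  as_partition(best_memb, best_q)
}

#' Subject-specific system segregation over detected modules
#'
#' Treats a detected community partition as the subject's own parcellation
#' and delegates to [system_segregation()].  Modules with fewer than 2
#' nodes are merged into the module they connect to most strongly (logged
#' via message); fewer than 2 modules after merging means segregation is
#' undefined and `NA` is returned for the statistic.
#'
#' @param cm the subject's `conn_matrix` (state `fisher_z` or
#'   `thresholded`), the same matrix the partition was derived from.
#' @param part a partition from [louvain()] or [girvan_newman()].
#' @return as [system_segregation()], or a 1-row all-`NA` frame when fewer
#'   than 2 modules remain.
#' @export
subject_specific_segregation <- function(cm, part) {
  v <- unclass(cm)
  memb <- part$assignment + 1L
  # merge singleton modules into their strongest-connected neighbor module
  repeat {
    sizes <- table(memb)
    small <- names(sizes)[sizes < 2]
    if (!length(small)) break
    m <- as.integer(small[1])
    i <- which(memb == m)
    strength <- tapply(v[i, ], memb, sum)
    strength[as.character(m)] <- -Inf
    target <- as.integer(names(strength)[which.max(strength)])
    message(sprintf("merging singleton module %d into module %d", m, target))
    memb[i] <- target
  }
  if (length(unique(memb)) < 2) {
    warning("fewer than 2 modules detected: subject-specific ss undefined",
            call. = FALSE)
    return(data.frame(scope = "whole_brain", z_within = NA_real_,
                      z_between = NA_real_, ss = NA_real_,
                      n_within_pairs = NA_integer_,
                      n_between_pairs = NA_integer_))
  }
  parc <- parcellation(colnames(v) %||% seq_len(nrow(v)),
                       sprintf("module%02d", as.integer(factor(memb))),
                       name = "subject_specific")
  system_segregation(cm, parc)
}
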