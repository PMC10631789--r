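# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: textbook formulas, exhaustive enumeration,
# direct double sums.

# textbook Pearson correlation, direct sum formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# modularity by direct O(N^2) double sum with configuration null
oracle_modularity <- function(A, memb) {
  two_m <- sum(A)
  k <- rowSums(A)
  q <- 0
  for (i in seq_len(nrow(A)))
    for (j in seq_len(ncol(A)))
      if (memb[i] == memb[j])
        q <- q + A[i, j] - k[i] * k[j] / two_m
  q / two_m
}

# all set partitions of 1..n via restricted growth strings
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxv + 1))
      rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  out
}

# brute-force maximum-modularity partition for small graphs
oracle_best_partition <- function(A) {
  parts <- all_set_partitions(nrow(A))
  qs <- vapply(parts, function(p) oracle_modularity(A, p), numeric(1))
  list(q = max(qs), membership = parts[[which.max(qs)]])
}

# brute-force optimal 2-partition of 1-D data by within-cluster SS
oracle_best_2partition <- function(x) {
  n <- length(x)
  best_w <- Inf; best <- NULL
  for (code in 1:(2^n - 2)) {
    lab <- as.integer(intToBits(code))[1:n]
    if (all(lab == lab[1])) next
    w <- sum((x[lab == 0] - mean(x[lab == 0]))^2) +
      sum((x[lab == 1] - mean(x[lab == 1]))^2)
    if (w < best_w) { best_w <- w; best <- lab }
  }
  list(wcss = best_w, labels = best)
}

# symmetric nonnegative random weight matrix, zero diagonal
random_graph <- function(n, density = 0.6, seed = 1) {
  set.seed(seed)
  A <- matrix(0, n, n)
  iu <- which(upper.tri(A))
  on <- sample(iu, max(1, round(density * length(iu))))
  A[on] <- runif(length(on), 0.1, 1)
  A + t(A)
}

# planted k-block graph: strong within-block, weak between-block weights
planted_block_graph <- function(block_sizes, w_in = 1, w_out = 0.05,
                                seed = 1) {
  set.seed(seed)
  labs <- rep(seq_along(block_sizes), block_sizes)
  n <- length(labs)
  A <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    A[i, j] <- A[j, i] <- if (labs[i] == labs[j]) w_in else w_out
  list(A = A, labels = labs)
}

# strip conn_matrix state attributes, keep the bare numeric matrix
cm_values <- function(cm) {
  v <- unclass(cm)
  matrix(as.numeric(v), nrow(v), ncol(v), dimnames = dimnames(v))
}

expect_symmetric_zero_diag <- function(cm) {
  v <- unclass(cm)
  expect_equal(v, t(v))
  expect_true(all(diag(v) == 0))
}
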