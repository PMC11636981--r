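# Independent oracles and shared fixtures for the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force topological overlap: triple loop straight from the definition.
tom_oracle <- function(adjacency) {
  a <- adjacency
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { out[i, j] <- 1; next }
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  dimnames(out) <- dimnames(adjacency)
  out
}

# Exhaustive MCC: enumerate every vertex subset of size >= 2, keep cliques
# that are maximal, and sum (|C|-1)! for each member.
mcc_oracle <- function(adj01) {
  n <- nrow(adj01)
  stopifnot(n <= 14)
  verts <- seq_len(n)
  is_clique <- function(s) {
    if (length(s) < 2) return(TRUE)
    all(adj01[s, s][upper.tri(adj01[s, s])] == 1)
  }
  scores <- numeric(n)
  subsets <- unlist(lapply(2:n, function(k) combn(verts, k, simplify = FALSE)),
                    recursive = FALSE)
  cliques <- Filter(is_clique, subsets)
  for (cl in cliques) {
    outside <- setdiff(verts, cl)
    maximal <- !any(vapply(outside, function(v) {
      all(adj01[v, cl] == 1)
    }, logical(1)))
    if (maximal) scores[cl] <- scores[cl] + factorial(length(cl) - 1)
  }
  names(scores) <- rownames(adj01)
  scores
}

# Straight-line TMM: the published doubly-trimmed weighted mean of M-values,
# written independently of the normalization backend.
tmm_oracle <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(counts)
  q75 <- apply(sweep(counts, 2, lib, "/"), 2, stats::quantile, p = 0.75)
  ref <- which.min(abs(q75 - mean(q75)))
  one_factor <- function(j) {
    x <- counts[, j]; y <- counts[, ref]
    nx <- lib[j]; ny <- lib[ref]
    keep <- x > 0 & y > 0
    x <- x[keep]; y <- y[keep]
    m <- log2((x / nx) / (y / ny))
    a <- 0.5 * log2((x / nx) * (y / ny))
    v <- (nx - x) / (nx * x) + (ny - y) / (ny * y)
    n <- length(m)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
    keep2 <- rank(m) >= lo_m & rank(m) <= hi_m &
             rank(a) >= lo_a & rank(a) <= hi_a
    f <- sum(m[keep2] / v[keep2]) / sum(1 / v[keep2])
    if (!is.finite(f)) f <- 0
    2^f
  }
  f <- vapply(seq_len(ncol(counts)), one_factor, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# Two-treatment layout used for DE calibration and power simulations.
two_group_layout <- function(replicates = 6) {
  data.frame(treatment = c("A", "B"),
             sulfide = c("replete", "limiting"),
             oxygen = "replete", nitrate = "replete", hydrogen = "replete",
             replicates = replicates, stringsAsFactors = FALSE)
}

# Random symmetric weight matrix in [0, 1] with unit diagonal.
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  a
}

# Random simple graph as igraph + 0/1 adjacency, for the MCC oracle.
random_graph <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  a <- a + t(a)
  dimnames(a) <- list(sprintf("v%02d", 1:n), sprintf("v%02d", 1:n))
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  list(graph = g, adj = a)
}

adjusted_rand <- function(x, y) mclust::adjustedRandIndex(x, y)

# One shared default-configuration pipeline run, computed lazily.
.run_cache <- new.env(parent = emptyenv())
default_run <- function() {
  if (is.null(.run_cache$res)) {
    .run_cache$res <- run_pipeline(simulation_config())
  }
  .run_cache$res
}
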