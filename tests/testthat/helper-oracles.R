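# Independent oracles and small fixture builders shared across tests.
# These deliberately avoid the package's own code paths: the SparCC
# oracle is a direct loop-based transcription of the estimator's
# defining equations, used to cross-check the vectorised implementation.

# Brute-force SparCC: log-ratio variances by explicit double loop, the
# basis-variance linear system assembled element by element (no
# exclusions), and the correlation formula applied pairwise.
brute_force_sparcc <- function(f) {
  n <- nrow(f)
  p <- ncol(f)
  T <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i != j) T[i, j] <- stats::var(log(f[, i] / f[, j]))
    }
  }
  A <- matrix(0, p, p)
  b <- numeric(p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      A[i, i] <- A[i, i] + 1
      A[i, j] <- A[i, j] + 1
      b[i] <- b[i] + T[i, j]
    }
  }
  omega2 <- solve(A, b)
  omega2[omega2 <= 0] <- 1e-12
  rho <- diag(p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      r <- (omega2[i] + omega2[j] - T[i, j]) /
        (2 * sqrt(omega2[i]) * sqrt(omega2[j]))
      rho[i, j] <- min(1, max(-1, r))
    }
  }
  list(T = T, omega2 = omega2, rho = rho)
}

# Adjusted Rand index between two labelings (closed form from the
# pair-counting contingency table).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# Graph of k disjoint cliques of size s, named nodes.
disjoint_cliques <- function(k, s) {
  g <- igraph::make_full_graph(s)
  if (k > 1) {
    for (i in 2:k) g <- igraph::disjoint_union(g, igraph::make_full_graph(s))
  }
  igraph::set_vertex_attr(g, "name",
                          value = paste0("n", seq_len(k * s)))
}

# Small deterministic count table.
toy_table <- function(counts = NULL) {
  if (is.null(counts)) {
    counts <- matrix(c(5, 3, 10, 2, 0, 25,
                       1, 4, 8, 6, 2, 30,
                       2, 3, 7, 4, 1, 20), nrow = 3, byrow = TRUE)
  }
  dimnames(counts) <- list(paste0("s", seq_len(nrow(counts))),
                           paste0("OTU", seq_len(ncol(counts))))
  otu_table(counts)
}

# The published network summary rows used as formula fixtures: printed
# node/edge/sign counts with the printed derived columns.
published_network_rows <- function() {
  data.frame(
    compartment = c(rep("endosphere", 4), rep("rhizosphere", 4)),
    rootstock = rep(c("nongraft", "self-graft", "RST-04-106", "Maxifort"), 2),
    nodes = c(60, 67, 75, 77, 113, 102, 136, 158),
    edges = c(88, 101, 123, 136, 264, 252, 341, 721),
    node_degree = c(1.5, 1.5, 1.6, 1.8, 2.3, 2.5, 2.5, 4.6),
    density = c(0.05, 0.05, 0.04, 0.05, 0.04, 0.05, 0.04, 0.06),
    negative = c(8, 9, 8, 24, 62, 76, 62, 288),
    positive = c(75, 86, 110, 108, 195, 175, 271, 425),
    ratio = c(0.11, 0.10, 0.07, 0.22, 0.32, 0.43, 0.23, 0.68))
}
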