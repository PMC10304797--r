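make_model <- function(otus, coefs) {
  structure(list(
    selected_otus = otus,
    glm_coefficients = stats::setNames(coefs, otus),
    glm_pvalues = stats::setNames(rep(0.01, length(otus)), otus),
    sign = stats::setNames(ifelse(coefs > 0, "positive", "negative"), otus),
    intercept = 0, fit = NULL), class = "phenotype_model")
}

test_that("PhONA assembly links selected OTUs to one phenotype node with GLM signs", {
  edges <- data.frame(otu_i = c("a", "b"), otu_j = c("b", "c"),
                      weight = c(0.7, -0.6),
                      sign = c("positive", "negative"))
  model <- make_model(c("a", "z", "c"), c(1.5, -0.4, 2.0))
  g <- build_phona(edges, model)
  expect_true(igraph::is_igraph(g))
  # one phenotype node; z retained though isolated from the OTU network
  vt <- igraph::V(g)$node_type
  expect_equal(sum(vt == "phenotype"), 1L)
  expect_true("z" %in% igraph::V(g)$name)
  expect_equal(unname(igraph::degree(g, "phenotype")), 3)
  # phenotype link signs equal the model signs
  eids <- igraph::E(g)[igraph::E(g)$edge_kind == "otu-phenotype"]
  ends <- igraph::ends(g, eids)
  otu_end <- ifelse(ends[, 1] == "phenotype", ends[, 2], ends[, 1])
  expect_identical(eids$sign[order(otu_end)],
                   unname(model$sign[sort(model$selected_otus)]))
  # no self-loops, undirected
  expect_false(igraph::any_loop(g))
  expect_false(igraph::is_directed(g))
  # with retention off, z disappears and phenotype degree drops to 2
  g2 <- build_phona(edges, model, retain_isolated_predictive = FALSE)
  expect_false("z" %in% igraph::V(g2)$name)
  expect_equal(unname(igraph::degree(g2, "phenotype")), 2)
})

test_that("network attributes use the edges/nodes and pair-count formulas", {
  rows <- published_network_rows()
  for (r in seq_len(nrow(rows))) {
    at <- derived_attributes(rows$nodes[r], rows$edges[r],
                             rows$negative[r], rows$positive[r])
    expect_equal(at$node_degree, rows$node_degree[r])
    expect_equal(at$density, rows$density[r])
    expect_equal(at$neg_pos_ratio, rows$ratio[r])
  }
  # complete graph on 5 nodes -> density 1
  expect_equal(derived_attributes(5, 10)$density, 1.00)
  # no positive edges -> ratio NA
  expect_true(is.na(derived_attributes(4, 3, 3, 0)$neg_pos_ratio))
  # attributes from a built graph are internally consistent
  edges <- data.frame(otu_i = c("a", "a", "b"), otu_j = c("b", "c", "d"),
                      weight = c(0.6, -0.7, 0.8),
                      sign = c("positive", "negative", "positive"))
  g <- build_phona(edges, make_model("a", 2))
  at <- network_attributes(g)
  expect_equal(at$n_nodes, 4L) # phenotype node excluded
  expect_equal(at$n_edges, 3L)
  expect_equal(at$n_negative + at$n_positive, at$n_edges)
})

test_that("simulated annealing finds the two-clique partition with Q = 0.5", {
  g <- disjoint_cliques(2, 5)
  p <- detect_modules_sa(g, seed = 1)
  expect_equal(p$n_modules, 2L)
  expect_equal(p$Q, 0.5, tolerance = 1e-12)
  mem <- p$membership
  expect_true(all(mem[1:5] == mem[1]) && all(mem[6:10] == mem[6]))
})

test_that("degenerate graphs are handled: no edges, single edge", {
  g0 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g0)$name <- c("a", "b", "c")
  p0 <- detect_modules_sa(g0, seed = 1)
  expect_equal(p0$Q, 0)
  expect_equal(p0$n_modules, 3L)
  g1 <- igraph::make_graph(c("a", "b"), directed = FALSE)
  p1 <- detect_modules_sa(g1, seed = 2)
  expect_gte(p1$Q, 0)
})

test_that("SA recovers a planted two-block partition and beats random partitions", {
  set.seed(99)
  n <- 30
  blocks <- rep(1:2, each = 15)
  A <- matrix(0, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      pr <- if (blocks[i] == blocks[j]) 0.5 else 0.02
      A[i, j] <- A[j, i] <- rbinom(1, 1, pr)
    }
  }
  g <- igraph::graph_from_adjacency_matrix(A, "undirected")
  igraph::V(g)$name <- paste0("v", 1:n)
  p <- detect_modules_sa(g, seed = 2)
  expect_gte(adjusted_rand(p$membership, blocks), 0.9)
  # Q beats the trivial and 50 random partitions
  expect_gte(p$Q, 0)
  set.seed(100)
  for (k in 1:50) {
    rand_mem <- sample(1:3, n, replace = TRUE)
    expect_gte(p$Q, igraph::modularity(g, rand_mem))
  }
})

test_that("permuting node ids leaves Q and attributes unchanged", {
  set.seed(101)
  g <- igraph::sample_gnp(20, 0.2)
  igraph::V(g)$name <- paste0("v", 1:20)
  perm <- sample(20)
  g2 <- igraph::permute(g, perm)
  p1 <- detect_modules_sa(g, seed = 5)
  p2 <- detect_modules_sa(g2, seed = 5)
  expect_equal(p1$Q, p2$Q, tolerance = 0.05) # search is stochastic per labeling
  a1 <- network_attributes(g)
  a2 <- network_attributes(g2)
  expect_equal(a1$n_edges, a2$n_edges)
  expect_equal(a1$density, a2$density)
})

test_that("node roles follow the z/P threshold rule exactly and partition all nodes", {
  # node hub: all links inside its module -> P = 0
  g <- disjoint_cliques(2, 5)
  p <- detect_modules_sa(g, seed = 1)
  roles <- node_roles(g, p)
  expect_equal(nrow(roles), 10L)
  expect_true(all(roles$P == 0))
  expect_true(all(roles$role %in%
                    c("peripheral", "connector", "module hub", "network hub")))
  # degree-2 node split across 2 modules -> P = 0.5
  g2 <- igraph::make_graph(c("a", "b", "a", "c", "b", "b2", "c", "c2",
                             "b", "b3", "c", "c3", "b2", "b3", "c2", "c3"),
                           directed = FALSE)
  mem <- c(a = 1, b = 2, b2 = 2, b3 = 2, c = 3, c2 = 3, c3 = 3)
  roles2 <- node_roles(g2, mem)
  expect_equal(roles2$P[roles2$node == "a"], 0.5)
  # threshold boundaries are inclusive: at thresholds (0, 0) every
  # clique node (z = 0, P = 0) sits exactly on both boundaries
  r_incl <- node_roles(g, p, z_threshold = 0, p_threshold = 0)
  expect_true(all(r_incl$role == "network hub"))
  # isolated node: z = 0, P = 0, peripheral
  g3 <- igraph::make_empty_graph(1, directed = FALSE) +
    igraph::vertices("iso")
  g3 <- igraph::delete_vertices(g3, 1)
  g4 <- igraph::make_graph(c("x", "y"), directed = FALSE) +
    igraph::vertices("iso")
  r4 <- node_roles(g4, c(x = 1, y = 1, iso = 2))
  iso_row <- r4[r4$node == "iso", ]
  expect_equal(iso_row$z, 0)
  expect_equal(iso_row$P, 0)
  expect_identical(iso_row$role, "peripheral")
})

test_that("within-module degree z uses the module's sample sd", {
  # star inside one module: hub has high k_in, leaves low
  g <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(g)$name <- paste0("v", 1:6)
  mem <- stats::setNames(rep(1, 6), igraph::V(g)$name)
  roles <- node_roles(g, mem)
  k_in <- c(5, rep(1, 5))
  z_exp <- (k_in - mean(k_in)) / sd(k_in)
  expect_equal(roles$z, unname(z_exp), tolerance = 1e-12)
})
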