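#' Assemble a PhONA graph
#'
#' Merges the SparCC association edge set with the phenotype model for
#' one treatment x compartment subset into a single undirected graph:
#' OTU-OTU edges carry the SparCC correlation and its sign; each selected
#' OTU is linked to one phenotype node with the sign of its reduced-GLM
#' coefficient. Selected OTUs absent from the association network are by
#' default retained as nodes linked only to the phenotype (in real
#' communities not all predictive OTUs are associated with other OTUs).
#'
#' @param edges an `edge_set` from [filter_associations()] (may have 0
#'   rows).
#' @param model a `phenotype_model` from [phenotype_model()] /
#'   [fit_reduced_glm()]; may be empty.
#' @param phenotype_name node name for the phenotype (default
#'   `"phenotype"`).
#' @param retain_isolated_predictive keep selected OTUs that have no
#'   OTU-OTU edge (default TRUE).
#' @param taxonomy optional named character vector (OTU id -> label)
#'   stored as a node attribute.
#' @return an igraph object with node attributes `node_type`
#'   (`"otu"`/`"phenotype"`) and optionally `taxonomy`, and edge
#'   attributes `weight`, `sign`, `edge_kind`.
#' @export
build_phona <- function(edges, model, phenotype_name = "phenotype",
                        retain_isolated_predictive = TRUE,
                        taxonomy = NULL) {
  stopifnot(inherits(model, "phenotype_model"))
  sel <- model$selected_otus
  net_otus <- unique(c(edges$otu_i, edges$otu_j))
  otus <- if (retain_isolated_predictive) {
    unique(c(net_otus, sel))
  } else {
    net_otus
  }
  if (phenotype_name %in% otus) {
    stop("phenotype_name collides with an OTU id: ", phenotype_name)
  }
  edf <- data.frame(from = character(0), to = character(0),
                    weight = numeric(0), sign = character(0),
                    edge_kind = character(0), stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    edf <- rbind(edf, data.frame(
      from = edges$otu_i, to = edges$otu_j, weight = edges$weight,
      sign = edges$sign, edge_kind = "otu-otu",
      stringsAsFactors = FALSE))
  }
  ph_sel <- intersect(sel, otus)
  if (length(ph_sel) > 0) {
    edf <- rbind(edf, data.frame(
      from = ph_sel, to = phenotype_name,
      weight = unname(model$glm_coefficients[ph_sel]),
      sign = unname(model$sign[ph_sel]), edge_kind = "otu-phenotype",
      stringsAsFactors = FALSE))
  }
  vdf <- data.frame(name = c(otus, phenotype_name),
                    node_type = c(rep("otu", length(otus)), "phenotype"),
                    stringsAsFactors = FALSE)
  if (!is.null(taxonomy)) {
    vdf$taxonomy <- unname(taxonomy[vdf$name])
    vdf$taxonomy[is.na(vdf$taxonomy)] <- ""
  }
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
}

# OTU-OTU skeleton of a PhONA graph (drops the phenotype node and its
# links); plain association graphs pass through unchanged.
otu_subgraph <- function(g) {
  vt <- igraph::vertex_attr(g, "node_type")
  if (is.null(vt)) return(g)
  igraph::induced_subgraph(g, which(vt != "phenotype"))
}

#' Association-network attributes
#'
#' Computes the standard summary attributes of the OTU-OTU association
#' network (the phenotype node and its links are excluded): node and edge
#' counts, node degree (edges per node), density over unordered pairs,
#' and the negative/positive edge split.
#'
#' @param g an igraph association graph or PhONA graph with edge `sign`
#'   attributes.
#' @param n_modules optional module count to carry along in the row.
#' @return A one-row data.frame; see [derived_attributes()] for columns.
#' @export
network_attributes <- function(g, n_modules = NA_integer_) {
  g <- otu_subgraph(g)
  sg <- igraph::edge_attr(g, "sign")
  if (is.null(sg)) sg <- character(0)
  derived_attributes(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    n_negative = sum(sg == "negative"),
    n_positive = sum(sg == "positive"),
    n_modules = n_modules)
}

#' Network attributes from printed counts
#'
#' The formula layer behind [network_attributes()], usable directly on
#' published node/edge/sign counts: node_degree = edges/nodes (rounded to
#' 1 decimal), density = edges / (n(n-1)/2) (2 decimals), neg_pos_ratio =
#' negative/positive (2 decimals, `NA` when there are no positive edges).
#' Unrounded values and the conventional mean degree 2*edges/nodes are
#' included alongside.
#'
#' @param n_nodes,n_edges,n_negative,n_positive integer counts.
#' @param n_modules optional module count.
#' @return one-row data.frame with columns `n_nodes`, `n_edges`,
#'   `node_degree`, `density`, `n_modules`, `n_negative`, `n_positive`,
#'   `neg_pos_ratio`, plus unrounded `node_degree_raw`, `density_raw`,
#'   `neg_pos_ratio_raw`, `mean_degree`.
#' @export
derived_attributes <- function(n_nodes, n_edges, n_negative = NA_integer_,
                               n_positive = NA_integer_,
                               n_modules = NA_integer_) {
  stopifnot(n_nodes >= 1)
  deg <- n_edges / n_nodes
  dens <- if (n_nodes > 1) n_edges / (n_nodes * (n_nodes - 1) / 2) else 0
  ratio <- if (!is.na(n_positive) && n_positive > 0) {
    n_negative / n_positive
  } else {
    NA_real_
  }
  data.frame(
    n_nodes = n_nodes, n_edges = n_edges,
    node_degree = round(deg, 1), density = round(dens, 2),
    n_modules = n_modules,
    n_negative = n_negative, n_positive = n_positive,
    neg_pos_ratio = round(ratio, 2),
    node_degree_raw = deg, density_raw = dens,
    neg_pos_ratio_raw = ratio,
    mean_degree = 2 * n_edges / n_nodes)
}

#' Module detection by simulated annealing
#'
#' Partitions the OTU-OTU network into modules by maximising
#' Newman-Girvan modularity Q with a simulated-annealing search
#' (single-node moves plus whole-module merges, geometric cooling,
#' greedy local polish). Edge signs and weights are ignored: modules are
#' found on the unsigned presence/absence skeleton, consistent with the
#' role analysis. Deterministic for a fixed seed.
#'
#' @param g igraph graph (a PhONA graph is reduced to its OTU-OTU
#'   skeleton first).
#' @param seed integer seed (required: the search is stochastic).
#' @param t0 initial temperature (default 1.0).
#' @param cooling geometric cooling factor applied once per sweep of n
#'   proposals (default 0.995).
#' @param n_steps total proposal steps; default `1e4 * vcount(g)`.
#' @return A list of class `module_partition`: `membership` (named
#'   integer vector, modules numbered 1..k), `Q` (modularity of the
#'   returned partition), `n_modules`.
#' @export
detect_modules_sa <- function(g, seed, t0 = 1.0, cooling = 0.995,
                              n_steps = NULL) {
  g <- otu_subgraph(g)
  g <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  n <- igraph::vcount(g)
  if (n == 0) stop("graph has no nodes")
  if (is.null(n_steps)) n_steps <- 1e4 * n
  local_seed_if(seed)
  if (igraph::ecount(g) == 0) {
    membership <- stats::setNames(seq_len(n), igraph::V(g)$name)
    return(structure(list(membership = membership, Q = 0,
                          n_modules = n), class = "module_partition"))
  }
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  membership <- sa_partition_cpp(n, as.integer(el[, 1]),
                                 as.integer(el[, 2]),
                                 t0, cooling, as.double(n_steps))
  names(membership) <- igraph::V(g)$name
  Q <- igraph::modularity(g, membership)
  structure(list(membership = membership, Q = Q,
                 n_modules = length(unique(membership))),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d modules, Q = %.4f\n",
              x$n_modules, x$Q))
  invisible(x)
}

#' Topological node roles (within-module degree and participation)
#'
#' For each node, the within-module degree z-score
#' z_i = (k_is - mean_s) / sd_s (k_is = links of i inside its own module
#' s; mean and sample sd taken over the members of s; z = 0 when sd is 0)
#' and the participation coefficient P_i = 1 - sum_s (k_is / k_i)^2.
#' Roles follow the four-category scheme: `network hub` (z >= z_threshold
#' and P >= p_threshold), `module hub` (z >= z_threshold only),
#' `connector` (P >= p_threshold only), else `peripheral`. Isolated nodes
#' get z = 0, P = 0, peripheral. Link signs are ignored.
#'
#' @param g igraph graph (PhONA graphs are reduced to the OTU-OTU
#'   skeleton).
#' @param partition a `module_partition` from [detect_modules_sa()], or a
#'   named membership vector covering all nodes.
#' @param z_threshold within-module degree threshold (default 2.5).
#' @param p_threshold participation threshold (default 0.62).
#' @return data.frame with columns `node`, `module`, `z`, `P`, `role`.
#' @export
node_roles <- function(g, partition, z_threshold = 2.5,
                       p_threshold = 0.62) {
  g <- otu_subgraph(g)
  g <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  membership <- if (inherits(partition, "module_partition")) {
    partition$membership
  } else {
    partition
  }
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(g)))
  if (!all(nodes %in% names(membership))) {
    stop("partition must cover every node of the graph")
  }
  mem <- membership[nodes]
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  A <- (A > 0) + 0
  mods <- sort(unique(mem))
  # k_is: links of node i into each module s
  kis <- sapply(mods, function(s) {
    rowSums(A[, mem == s, drop = FALSE])
  })
  if (is.null(dim(kis))) kis <- matrix(kis, nrow = length(nodes))
  k <- rowSums(kis)
  k_in <- kis[cbind(seq_along(nodes), match(mem, mods))]
  z <- numeric(length(nodes))
  for (s in mods) {
    members <- which(mem == s)
    mu <- mean(k_in[members])
    sdv <- stats::sd(k_in[members])
    z[members] <- if (is.na(sdv) || sdv == 0) 0 else (k_in[members] - mu) / sdv
  }
  P <- ifelse(k > 0, 1 - rowSums((kis / pmax(k, 1))^2), 0)
  role <- ifelse(
    z >= z_threshold & P >= p_threshold, "network hub",
    ifelse(z >= z_threshold, "module hub",
           ifelse(P >= p_threshold, "connector", "peripheral")))
  data.frame(node = nodes, module = as.integer(mem), z = z, P = P,
             role = role, stringsAsFactors = FALSE)
}

#' Annotate a PhONA graph with modules and roles
#'
#' Stores module ids and role labels as node attributes so that GraphML
#' exports carry them.
#'
#' @param g a PhONA graph.
#' @param partition a `module_partition`.
#' @param roles data.frame from [node_roles()].
#' @return the annotated igraph object.
#' @export
annotate_phona <- function(g, partition, roles) {
  nm <- igraph::V(g)$name
  mem <- partition$membership[nm]
  rl <- roles$role[match(nm, roles$node)]
  igraph::set_vertex_attr(
    igraph::set_vertex_attr(g, "module",
                            value = ifelse(is.na(mem), -1L, as.integer(mem))),
    "role", value = ifelse(is.na(rl), "", rl))
}
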