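#' Run the full PhONA pipeline from a configuration
#'
#' Executes the stages in order: rare-OTU filtering, rarefaction, then —
#' per treatment x compartment subset — SparCC association inference,
#' edge filtering, lasso/GLM phenotype selection, PhONA assembly,
#' network attributes, module detection and node roles; followed by the
#' community statistics (alpha diversity, Bray-Curtis + PERMANOVA,
#' negative-binomial differential abundance) on the full table. All
#' stage outputs are written as TSV/GraphML under `output_dir` together
#' with a JSON run manifest recording the config snapshot, seeds, input
#' hashes and output paths.
#'
#' Config keys (YAML file or list): either `simulate` (a [synth_config()]
#' argument list) or `input` (`otu_table`, optional `metadata`,
#' `phenotype` TSV paths); `preprocess` (`min_total`, `depth`); `sparcc`
#' (`n_iterations`, `n_bootstraps`, `min_abs_rho`, `alpha`); `lasso`
#' (`k_folds`, `n_repeats`, `selection_rule`); `graph` (`z_threshold`,
#' `p_threshold`, `retain_isolated_predictive`, `sa_t0`, `sa_cooling`);
#' `community` (`n_perm`, `fdr_alpha`, `contrasts`); `subset_by`
#' (character vector of metadata columns defining the subsets); `seed`.
#' Defaults mirror the standard analysis: min_total 10, depth 6698 (or
#' the minimum sample total if lower), 20 SparCC iterations, 500
#' bootstraps, |rho| > 0.5 with p < 0.05, 5-fold x 500-repeat CV, FDR
#' 0.01, role thresholds 2.5 / 0.62, 1000 permutations.
#'
#' @param config list or path to a YAML file.
#' @param output_dir directory for stage outputs (created if missing).
#' @param quiet suppress progress messages (default FALSE).
#' @return the run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, output_dir, quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config_path <- config
    config <- yaml::read_yaml(config)
  } else {
    config_path <- NA_character_
  }
  cfg <- apply_pipeline_defaults(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  manifest <- list(
    package_version = as.character(utils::packageVersion("phona")),
    config = cfg, config_path = config_path,
    seed = cfg$seed, input_hashes = list(), outputs = list())
  op <- function(name) file.path(output_dir, name)
  record <- function(key, path) {
    manifest$outputs[[key]] <<- path
    path
  }

  # ---- inputs -------------------------------------------------------
  metadata <- NULL
  y <- NULL
  if (!is.null(cfg$simulate)) {
    say("simulating data (seed ", cfg$seed, ")")
    sc <- do.call(synth_config, c(cfg$simulate, list(seed = cfg$seed)))
    gen <- generate_counts(sc)
    tab <- gen$table
    metadata <- gen$design
    if (!is.null(sc$phenotype)) {
      ph <- generate_phenotype(tab, sc)
      y <- ph$y
      truth <- list(counts = gen$truth, phenotype = ph$truth)
    } else {
      truth <- list(counts = gen$truth)
    }
    write_otu_table(tab, record("otu_table", op("otu_table.tsv")))
    jsonlite::write_json(
      truth_to_json(truth),
      record("truth", op("truth.json")), auto_unbox = TRUE, digits = NA)
    if (!is.null(metadata)) {
      utils::write.table(metadata,
                         record("metadata", op("metadata.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(y)) {
      utils::write.table(
        data.frame(sample_id = names(y), phenotype = y),
        record("phenotype", op("phenotype.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else {
    inp <- cfg$input
    if (is.null(inp$otu_table)) stop("config needs `simulate` or `input`")
    tab <- read_otu_table(inp$otu_table,
                          format = inp$format %||% "tsv")
    manifest$input_hashes[[inp$otu_table]] <-
      unname(tools::md5sum(inp$otu_table))
    if (!is.null(inp$metadata)) {
      metadata <- utils::read.delim(inp$metadata, check.names = FALSE,
                                    stringsAsFactors = FALSE)
      manifest$input_hashes[[inp$metadata]] <-
        unname(tools::md5sum(inp$metadata))
    }
    if (!is.null(inp$phenotype)) {
      phd <- utils::read.delim(inp$phenotype, check.names = FALSE,
                               stringsAsFactors = FALSE)
      y <- stats::setNames(as.numeric(phd[[2]]), phd[[1]])
      manifest$input_hashes[[inp$phenotype]] <-
        unname(tools::md5sum(inp$phenotype))
    }
  }
  if (is.null(y)) {
    say("no phenotype supplied: graphs will lack phenotype links")
    warning("no phenotype supplied; PhONA graphs will contain only ",
            "the association network")
  }

  # ---- preprocessing ------------------------------------------------
  say("filtering rare OTUs (min_total = ", cfg$preprocess$min_total, ")")
  tab <- filter_rare_otus(tab, cfg$preprocess$min_total)
  depth <- min(cfg$preprocess$depth, min(rowSums(tab$counts)))
  say("rarefying to depth ", depth)
  tab <- rarefy_counts(tab, depth, seed = cfg$seed + 1L)
  write_otu_table(tab, record("rarefied", op("rarefied_otu_table.tsv")))

  # ---- per-subset network + phenotype stages ------------------------
  subsets <- pipeline_subsets(tab, metadata, cfg$subset_by)
  attr_rows <- list()
  for (si in seq_along(subsets)) {
    sname <- names(subsets)[si]
    rows <- subsets[[si]]
    sub <- otu_table(tab$counts[rows, , drop = FALSE])
    # drop OTUs absent from this subset; SparCC needs >= 4 OTUs
    nz <- colSums(sub$counts) > 0
    sub <- otu_table(sub$counts[, nz, drop = FALSE])
    if (ncol(sub$counts) < 4 || nrow(sub$counts) < 3) {
      say("subset ", sname, ": too small, skipped")
      next
    }
    say("subset ", sname, ": SparCC on ", ncol(sub$counts), " OTUs, ",
        nrow(sub$counts), " samples")
    assoc <- sparcc_association(
      sub, n_iterations = cfg$sparcc$n_iterations,
      n_bootstraps = cfg$sparcc$n_bootstraps,
      seed = cfg$seed + 100L + si)
    edges <- filter_associations(assoc, cfg$sparcc$min_abs_rho,
                                 cfg$sparcc$alpha)
    utils::write.table(
      as.data.frame(edges),
      record(paste0("edges_", sname), op(paste0("edges_", sname, ".tsv"))),
      sep = "\t", quote = FALSE, row.names = FALSE)
    model <- if (!is.null(y)) {
      ys <- y[sub$sample_ids]
      if (anyNA(ys)) stop("phenotype missing for sample(s): ",
                          paste(sub$sample_ids[is.na(ys)], collapse = ", "))
      phenotype_model(sub, ys, k_folds = min(cfg$lasso$k_folds,
                                             nrow(sub$counts)),
                      n_repeats = cfg$lasso$n_repeats,
                      selection_rule = cfg$lasso$selection_rule,
                      seed = cfg$seed + 200L + si)
    } else {
      empty_phenotype_model()
    }
    g <- build_phona(edges, model,
                     retain_isolated_predictive =
                       cfg$graph$retain_isolated_predictive)
    part <- detect_modules_sa(g, seed = cfg$seed + 300L + si,
                              t0 = cfg$graph$sa_t0,
                              cooling = cfg$graph$sa_cooling)
    roles <- node_roles(g, part, cfg$graph$z_threshold,
                        cfg$graph$p_threshold)
    g <- annotate_phona(g, part, roles)
    write_phona_graph(
      g, record(paste0("graph_", sname),
                op(paste0("phona_", sname, ".graphml"))), "graphml")
    write_phona_graph(
      g, record(paste0("edgelist_", sname),
                op(paste0("phona_", sname, ".edges.tsv"))), "edgelist")
    utils::write.table(
      roles, record(paste0("roles_", sname),
                    op(paste0("roles_", sname, ".tsv"))),
      sep = "\t", quote = FALSE, row.names = FALSE)
    at <- network_attributes(g, n_modules = part$n_modules)
    attr_rows[[sname]] <- data.frame(subset = sname, at)
  }
  if (length(attr_rows) > 0) {
    utils::write.table(
      do.call(rbind, attr_rows),
      record("network_attributes", op("network_attributes.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # ---- community statistics ----------------------------------------
  div <- alpha_diversity(tab)
  utils::write.table(div, record("alpha_diversity",
                                 op("alpha_diversity.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata) && !is.null(cfg$community$permanova_terms)) {
    d <- bray_curtis(tab)
    md <- metadata[match(tab$sample_ids, metadata$sample_id), ,
                   drop = FALSE]
    rhs <- stats::reformulate(cfg$community$permanova_terms)
    pm <- permanova(d, md, rhs, n_perm = cfg$community$n_perm,
                    seed = cfg$seed + 400L)
    utils::write.table(pm, record("permanova", op("permanova.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(metadata) && "treatment" %in% names(metadata) &&
      length(unique(metadata$treatment)) >= 2) {
    md <- metadata[match(tab$sample_ids, metadata$sample_id), ,
                   drop = FALSE]
    da <- fit_nb_per_otu(tab, md$treatment,
                         contrasts = cfg$community$contrasts,
                         alpha = cfg$community$fdr_alpha)
    utils::write.table(as.data.frame(da),
                       record("daotu", op("daotu.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest$outputs <- manifest$outputs[order(names(manifest$outputs))]
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  say("pipeline complete: ", length(manifest$outputs), " outputs in ",
      output_dir)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

apply_pipeline_defaults <- function(config) {
  dflt <- list(
    seed = 1L,
    preprocess = list(min_total = 10, depth = 6698),
    sparcc = list(n_iterations = 20, n_bootstraps = 500,
                  min_abs_rho = 0.5, alpha = 0.05),
    lasso = list(k_folds = 5, n_repeats = 500,
                 selection_rule = "min_mean_1se"),
    graph = list(z_threshold = 2.5, p_threshold = 0.62,
                 retain_isolated_predictive = TRUE,
                 sa_t0 = 1.0, sa_cooling = 0.995),
    community = list(n_perm = 1000, fdr_alpha = 0.01,
                     contrasts = NULL, permanova_terms = NULL),
    subset_by = NULL)
  out <- utils::modifyList(dflt, config, keep.null = TRUE)
  out$seed <- as.integer(out$seed)
  out
}

pipeline_subsets <- function(tab, metadata, subset_by) {
  if (is.null(metadata) || is.null(subset_by) ||
      length(subset_by) == 0) {
    return(list(all = seq_along(tab$sample_ids)))
  }
  missing_cols <- setdiff(subset_by, names(metadata))
  if (length(missing_cols) > 0) {
    stop("subset_by names unknown metadata column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  md <- metadata[match(tab$sample_ids, metadata$sample_id), ,
                 drop = FALSE]
  key <- interaction(md[, subset_by, drop = FALSE], sep = ".",
                     drop = TRUE)
  split(seq_along(tab$sample_ids), key)
}

truth_to_json <- function(truth) {
  # matrices serialise row-wise with ids; keep the sidecar readable
  tt <- truth
  # planted pairs carry the signal; full matrices stay in-memory only
  tt$counts$correlation <- NULL
  tt$counts$log_basis <- NULL
  tt
}
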