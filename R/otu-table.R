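#' Construct an OTU count table
#'
#' The central data container: a non-negative integer count matrix with
#' samples as rows and OTUs as columns. All downstream functions (SparCC,
#' phenotype selection, diversity, differential abundance) consume this
#' orientation, which matches the regression design matrix.
#'
#' @param counts numeric matrix of non-negative integers, samples x OTUs.
#' @param sample_ids character vector of unique sample identifiers
#'   (default: rownames of `counts`).
#' @param otu_ids character vector of unique OTU identifiers
#'   (default: colnames of `counts`).
#' @return An object of class `otu_table`: a list with elements `counts`
#'   (integer matrix with dimnames), `sample_ids`, `otu_ids`.
#' @examples
#' m <- matrix(rpois(12, 20), 3, 4,
#'             dimnames = list(paste0("s", 1:3), paste0("OTU", 1:4)))
#' otu_table(m)
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      otu_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids) || is.null(otu_ids)) {
    stop("`counts` must have sample and OTU identifiers ",
         "(rownames/colnames or explicit id vectors)")
  }
  sample_ids <- as.character(sample_ids)
  otu_ids <- as.character(otu_ids)
  if (length(sample_ids) != nrow(counts)) {
    stop("length(sample_ids) != nrow(counts)")
  }
  if (length(otu_ids) != ncol(counts)) {
    stop("length(otu_ids) != ncol(counts)")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(otu_ids)) {
    stop("duplicate OTU ids: ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  }
  if (!is.numeric(counts)) {
    stop("counts must be numeric")
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts %% 1 != 0,
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "invalid count %s at sample '%s', OTU '%s' (must be a non-negative integer)",
      format(counts[bad[1, 1], bad[1, 2]]),
      sample_ids[bad[1, 1]], otu_ids[bad[1, 2]]))
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, otu_ids)
  structure(list(counts = counts, sample_ids = sample_ids,
                 otu_ids = otu_ids),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs, total count %s\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Extract the count matrix from an otu_table
#' @param x an [otu_table()].
#' @return integer matrix, samples x OTUs.
#' @export
otu_counts <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  x$counts
}

#' Read an OTU count table from disk
#'
#' TSV layout: header row of OTU ids, first column sample ids.
#' BIOM-JSON tables (as written e.g. by QIIME/mothur exports) are accepted
#' read-only and transposed into the samples-x-OTUs orientation.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom-json"`.
#' @return an [otu_table()] with ids in file order.
#' @export
read_otu_table <- function(path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("TSV must have a sample-id column plus >= 1 OTU")
    sample_ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))),
                   arr.ind = TRUE)
      stop(sprintf("non-numeric count at sample '%s', OTU '%s'",
                   sample_ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
    }
    rownames(m) <- sample_ids
    otu_table(m)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("biomformat is required to read BIOM files")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix") # taxa x samples
    otu_table(t(m))
  }
}

#' Write an OTU count table as TSV
#'
#' @param x an [otu_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  stopifnot(inherits(x, "otu_table"))
  df <- data.frame(sample_id = x$sample_ids, x$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Remove rare OTUs
#'
#' Drops OTUs whose total count across all samples is below `min_total`.
#' The default of 10 removes the long tail of rare OTUs (in typical ITS
#' surveys these account for the large majority of observed OTUs while
#' contributing few reads). The threshold is community-level: the total
#' over samples, not a per-sample count.
#'
#' @param x an [otu_table()].
#' @param min_total minimum total count (OTUs with total < `min_total`
#'   are removed). Default 10.
#' @return an [otu_table()] with the same samples and the retained OTUs.
#' @export
filter_rare_otus <- function(x, min_total = 10) {
  stopifnot(inherits(x, "otu_table"), min_total >= 0)
  keep <- colSums(x$counts) >= min_total
  if (!any(keep)) {
    stop("all OTUs have total count < ", min_total,
         "; use a lower `min_total`")
  }
  otu_table(x$counts[, keep, drop = FALSE])
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) down to `depth`, equalising sequencing effort across
#' samples. Samples already at exactly `depth` are returned unchanged.
#'
#' @param x an [otu_table()].
#' @param depth target depth; must not exceed any sample's total.
#'   Default 6698 (a typical lowest-sample depth for a rarefied ITS run).
#' @param seed optional integer seed for reproducible subsampling.
#' @return an [otu_table()] in which every row sums to `depth`.
#' @export
rarefy_counts <- function(x, depth = 6698, seed = NULL) {
  stopifnot(inherits(x, "otu_table"), depth >= 0)
  local_seed_if(seed)
  rs <- rowSums(x$counts)
  shallow <- rs < depth
  if (any(shallow)) {
    stop("depth ", depth, " exceeds the total count of sample(s): ",
         paste(x$sample_ids[shallow], collapse = ", "))
  }
  out <- x$counts
  p <- ncol(out)
  for (i in seq_len(nrow(out))) {
    if (rs[i] == depth) next
    cum <- cumsum(out[i, ])
    pos <- sample.int(rs[i], depth)
    out[i, ] <- tabulate(findInterval(pos - 1L, cum) + 1L, nbins = p)
  }
  otu_table(out)
}

#' Write a PhONA graph to disk
#'
#' GraphML keeps all node attributes (type, module, role, taxonomy where
#' set) and edge attributes (weight, sign, edge_kind) and round-trips
#' through any GraphML-aware tool. The edge-list TSV has columns
#' `source`, `target`, `weight`, `sign`, `edge_kind`.
#'
#' @param g an igraph object, e.g. from [build_phona()].
#' @param path output path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_phona_graph <- function(g, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  stopifnot(igraph::is_igraph(g))
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g)
    df <- data.frame(
      source = el[, 1], target = el[, 2],
      weight = edge_attr_or(g, "weight", NA_real_),
      sign = edge_attr_or(g, "sign", NA_character_),
      edge_kind = edge_attr_or(g, "edge_kind", "otu-otu"),
      stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

edge_attr_or <- function(g, name, default) {
  v <- igraph::edge_attr(g, name)
  if (is.null(v)) rep(default, igraph::ecount(g)) else v
}

# Set the RNG seed in the caller's frame when one is given, restoring the
# previous RNG state on exit; seed = NULL leaves the current stream alone
# (needed so nested calls inside bootstrap loops consume one stream).
local_seed_if <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) {
    withr::local_seed(as.integer(seed), .local_envir = env)
  }
  invisible(NULL)
}
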