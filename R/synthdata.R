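#' Configuration for the synthetic data generator
#'
#' Describes a synthetic study with the statistical structure the PhONA
#' pipeline assumes: latent basis abundances that are multivariate
#' log-normal with a sparse planted correlation structure, compositional
#' multinomial sequencing at a fixed depth, a continuous phenotype driven
#' linearly by a known OTU subset, and an optional balanced treatment
#' design with planted per-OTU log2 fold changes.
#'
#' @param n_samples number of samples.
#' @param n_otus number of OTUs.
#' @param depth sequencing depth per sample (multinomial total).
#' @param correlations data.frame with columns `i`, `j`, `rho`: planted
#'   pairwise correlations of log basis abundances (all others 0).
#' @param phenotype list with `otus` (indices or ids), `betas` (effects
#'   on standardised relative abundance scale) and `sd` (noise sd); or
#'   NULL for no phenotype.
#' @param treatment list with `levels` (character) and optionally
#'   `effects`, a data.frame with columns `otu`, `level`, `log2fc`; or
#'   NULL for a single-condition study.
#' @param mu_log mean log basis abundances: either a vector (length
#'   `n_otus`) or the sd of the normal they are drawn from (default 1.5,
#'   giving the strongly uneven abundance distribution typical of ITS
#'   communities).
#' @param sigma_log per-OTU sd of log basis abundances (default 1.5:
#'   taxa fluctuate over roughly an order of magnitude across samples).
#' @param seed integer seed; the whole dataset is a deterministic
#'   function of the config.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_samples = 80, n_otus = 60, depth = 5000,
                         correlations = NULL, phenotype = NULL,
                         treatment = NULL, mu_log = 1.5, sigma_log = 1.5,
                         seed = 1) {
  stopifnot(n_samples >= 2, n_otus >= 2, depth >= 1)
  if (!is.null(correlations)) {
    stopifnot(all(c("i", "j", "rho") %in% names(correlations)),
              all(abs(correlations$rho) < 1),
              all(correlations$i != correlations$j))
  }
  structure(list(n_samples = n_samples, n_otus = n_otus, depth = depth,
                 correlations = correlations, phenotype = phenotype,
                 treatment = treatment, mu_log = mu_log,
                 sigma_log = sigma_log, seed = as.integer(seed)),
            class = "synth_config")
}

# Correlation matrix from the sparse spec; repaired to positive definite
# by eigenvalue flooring if the planted entries conflict.
build_correlation_matrix <- function(config) {
  p <- config$n_otus
  R <- diag(p)
  if (!is.null(config$correlations)) {
    for (r in seq_len(nrow(config$correlations))) {
      i <- config$correlations$i[r]
      j <- config$correlations$j[r]
      R[i, j] <- R[j, i] <- config$correlations$rho[r]
    }
  }
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) <= 1e-10) {
    warning("planted correlation spec is not positive definite; ",
            "repaired by eigenvalue flooring")
    vals <- pmax(ev$values, 1e-6)
    R <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    D <- diag(1 / sqrt(diag(R)))
    R <- D %*% R %*% D
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
        <= 0) {
      stop("correlation spec could not be repaired")
    }
  }
  R
}

#' Generate a synthetic OTU count table
#'
#' Draws per-sample latent log basis abundances from a multivariate
#' normal with the planted correlation structure (optionally shifted by
#' treatment fold changes), exponentiates to basis abundances, and draws
#' each sample's counts as multinomial(depth, normalised basis). The
#' multinomial step makes the observed data genuinely compositional, so
#' naive correlations of proportions are distorted and SparCC's
#' correction is actually exercised.
#'
#' @param config a [synth_config()].
#' @return list with `table` (an [otu_table()], every row summing to
#'   `depth`), `truth` (planted correlation matrix, log-abundance means,
#'   planted pairs, design, seed) and `design` (a data.frame of sample
#'   metadata, or NULL).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::local_seed(config$seed)
  n <- config$n_samples
  p <- config$n_otus
  R <- build_correlation_matrix(config)
  mu <- if (length(config$mu_log) == p) {
    as.numeric(config$mu_log)
  } else {
    stats::rnorm(p, 0, config$mu_log)
  }
  sig <- rep_len(config$sigma_log, p)
  Sigma <- diag(sig) %*% R %*% diag(sig)
  design <- if (!is.null(config$treatment)) generate_design(config) else NULL
  Ch <- chol(Sigma)
  Z <- matrix(stats::rnorm(n * p), n, p) %*% Ch
  Z <- sweep(Z, 2, mu, "+")
  if (!is.null(design) && !is.null(config$treatment$effects)) {
    ef <- config$treatment$effects
    for (r in seq_len(nrow(ef))) {
      rows <- design$treatment == ef$level[r]
      Z[rows, ef$otu[r]] <- Z[rows, ef$otu[r]] + ef$log2fc[r] * log(2)
    }
  }
  basis <- exp(Z)
  props <- basis / rowSums(basis)
  counts <- t(apply(props, 1, function(pr) {
    stats::rmultinom(1, config$depth, pr)[, 1]
  }))
  dimnames(counts) <- list(sprintf("sample_%03d", seq_len(n)),
                           sprintf("OTU_%03d", seq_len(p)))
  planted <- config$correlations
  if (!is.null(planted)) {
    planted$otu_i <- colnames(counts)[planted$i]
    planted$otu_j <- colnames(counts)[planted$j]
  }
  rownames(Z) <- rownames(counts)
  colnames(Z) <- colnames(counts)
  list(table = otu_table(counts),
       truth = list(correlation = R, mu_log = mu, sigma_log = sig,
                    planted_pairs = planted, design = design,
                    log_basis = Z, seed = config$seed),
       design = design)
}

#' Generate a phenotype driven by known OTUs
#'
#' y = sum_k beta_k * standardised relative abundance of OTU_k +
#' Normal(0, sd). The standardisation puts the betas on the same scale
#' the selection stage models, so they are directly comparable with
#' reduced-GLM coefficients.
#'
#' @param x an [otu_table()], typically from [generate_counts()].
#' @param config the same [synth_config()]; its `phenotype` element
#'   supplies `otus`, `betas`, `sd`.
#' @return list with `y` (named numeric vector) and `truth` (driver OTU
#'   ids, betas, signs, noise sd).
#' @export
generate_phenotype <- function(x, config) {
  stopifnot(inherits(x, "otu_table"), inherits(config, "synth_config"))
  ph <- config$phenotype
  if (is.null(ph)) stop("config has no phenotype spec")
  withr::local_seed(config$seed + 1000003L)
  otus <- ph$otus
  if (is.numeric(otus)) otus <- x$otu_ids[otus]
  if (!all(otus %in% x$otu_ids)) {
    stop("phenotype spec names unknown OTUs: ",
         paste(setdiff(otus, x$otu_ids), collapse = ", "))
  }
  betas <- ph$betas
  stopifnot(length(betas) == length(otus))
  rel <- x$counts / rowSums(x$counts)
  xs <- scale(rel[, otus, drop = FALSE])
  xs[!is.finite(xs)] <- 0
  y <- as.numeric(xs %*% betas) +
    stats::rnorm(nrow(rel), 0, ph$sd)
  names(y) <- x$sample_ids
  list(y = y,
       truth = list(otus = otus, betas = stats::setNames(betas, otus),
                    signs = stats::setNames(
                      ifelse(betas > 0, "positive", "negative"), otus),
                    sd = ph$sd))
}

#' Generate a balanced factorial design
#'
#' Assigns treatment levels (and optional compartment levels) to samples
#' in balanced blocks; errors if the level counts do not divide the
#' sample count.
#'
#' @param config a [synth_config()] with a `treatment` spec.
#' @return data.frame with `sample_id` and `treatment` (plus
#'   `compartment` when specified).
#' @export
generate_design <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  tr <- config$treatment
  if (is.null(tr)) stop("config has no treatment spec")
  levels <- tr$levels
  n <- config$n_samples
  comp <- tr$compartments
  cells <- if (is.null(comp)) {
    expand.grid(treatment = levels, stringsAsFactors = FALSE)
  } else {
    expand.grid(treatment = levels, compartment = comp,
                stringsAsFactors = FALSE)
  }
  if (n %% nrow(cells) != 0) {
    stop("n_samples (", n, ") is not a multiple of the ", nrow(cells),
         " design cells")
  }
  reps <- n / nrow(cells)
  df <- cells[rep(seq_len(nrow(cells)), each = reps), , drop = FALSE]
  df <- data.frame(sample_id = sprintf("sample_%03d", seq_len(n)), df,
                   row.names = NULL, stringsAsFactors = FALSE)
  df
}
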