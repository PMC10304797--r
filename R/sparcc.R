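#' Dirichlet-resampled relative abundances
#'
#' Draws one fraction matrix from the posterior Dirichlet(counts + 1) of
#' each sample's composition. The add-one prior resolves zero counts so
#' that log-ratios are defined for every OTU pair, and propagates the
#' sampling uncertainty of low-depth samples into the correlation
#' estimates (the SparCC convention).
#'
#' @param x an [otu_table()].
#' @param seed optional integer seed.
#' @return numeric matrix (samples x OTUs); rows strictly positive and
#'   summing to 1.
#' @export
dirichlet_fractions <- function(x, seed = NULL) {
  stopifnot(inherits(x, "otu_table"))
  local_seed_if(seed)
  cc <- x$counts
  g <- matrix(stats::rgamma(length(cc), shape = as.numeric(cc) + 1),
              nrow = nrow(cc), dimnames = dimnames(cc))
  g / rowSums(g)
}

#' Pairwise log-ratio variances
#'
#' T\[i, j\] = sample variance (denominator n - 1) over samples of
#' log(f_i / f_j). Log-ratios are invariant to the per-sample total, which
#' is what makes them usable on compositional data.
#'
#' @param f strictly positive fraction matrix (samples x OTUs).
#' @return symmetric OTU x OTU matrix with zero diagonal.
#' @export
logratio_variances <- function(f) {
  f <- as.matrix(f)
  if (nrow(f) < 2) stop("need at least 2 samples to compute variances")
  if (any(f <= 0)) stop("fractions must be strictly positive")
  L <- log(f)
  # var(Li - Lj) = var(Li) + var(Lj) - 2 cov(Li, Lj)
  C <- stats::cov(L)
  v <- diag(C)
  T <- outer(v, v, "+") - 2 * C
  T[T < 0] <- 0 # numerical noise on near-proportional pairs
  diag(T) <- 0
  T
}

#' Solve the SparCC basis-variance system
#'
#' Under the sparsity assumption (most true correlations near zero) the
#' expected log-ratio variance of a pair is the sum of the two latent
#' basis variances: summing over each OTU's non-excluded partners gives a
#' linear system in omega^2. Excluded pairs (identified as strongly
#' correlated in earlier rounds) are removed from both sides.
#'
#' @param T symmetric log-ratio variance matrix.
#' @param excluded optional logical OTU x OTU matrix marking excluded
#'   pairs (symmetric, FALSE diagonal).
#' @param epsilon floor applied to non-positive solutions (default 1e-12).
#' @return numeric vector of basis variances omega^2, one per OTU.
#' @export
basis_variances <- function(T, excluded = NULL, epsilon = 1e-12) {
  T <- as.matrix(T)
  p <- ncol(T)
  if (p < 4) stop("SparCC requires at least 4 OTUs (system under-determined)")
  if (max(abs(T - t(T))) > 1e-8) stop("T must be symmetric")
  M <- matrix(1, p, p)
  diag(M) <- 0
  if (!is.null(excluded)) M[excluded] <- 0
  A <- M
  diag(A) <- rowSums(M)
  b <- rowSums(T * M)
  omega2 <- tryCatch(solve(A, b),
                     error = function(e) {
                       # rank-deficient after heavy exclusion: least squares
                       as.vector(qr.coef(qr(A), b))
                     })
  omega2[!is.finite(omega2) | omega2 <= 0] <- epsilon
  names(omega2) <- colnames(T)
  omega2
}

# Correlation matrix from log-ratio variances and basis variances:
# rho_ij = (omega_i^2 + omega_j^2 - T_ij) / (2 omega_i omega_j), clipped.
rho_from_basis <- function(T, omega2) {
  om <- sqrt(omega2)
  den <- 2 * outer(om, om)
  num <- outer(omega2, omega2, "+") - T
  bad <- !is.finite(den) | den <= 0
  rho <- num / den
  if (any(bad)) {
    warning("degenerate basis variances; affected correlations set to 0")
    rho[bad] <- 0
  }
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  diag(rho) <- 1
  rho
}

#' SparCC correlations from one fraction matrix
#'
#' One inner SparCC pass: compute log-ratio variances, solve for basis
#' variances, then iteratively exclude the currently strongest |rho| pair
#' above `exclusion_threshold` (these violate the sparsity assumption)
#' and re-solve, up to `n_exclusion_rounds` times.
#'
#' @param f strictly positive fraction matrix (samples x OTUs), e.g. from
#'   [dirichlet_fractions()].
#' @param exclusion_threshold |rho| above which a pair may be excluded
#'   from the basis-variance system (default 0.1).
#' @param n_exclusion_rounds maximum exclusion rounds (default 10).
#' @return symmetric correlation matrix in \[-1, 1\] with unit diagonal.
#' @export
sparcc_from_fractions <- function(f, exclusion_threshold = 0.1,
                                  n_exclusion_rounds = 10) {
  T <- logratio_variances(f)
  p <- ncol(T)
  excluded <- matrix(FALSE, p, p)
  omega2 <- basis_variances(T, excluded)
  rho <- rho_from_basis(T, omega2)
  if (n_exclusion_rounds > 0) {
    for (round in seq_len(n_exclusion_rounds)) {
      cand <- abs(rho)
      diag(cand) <- 0
      cand[excluded] <- 0
      # never strip an OTU's last two partners: the row equation degenerates
      n_part <- p - 1 - rowSums(excluded)
      cand[n_part <= 2, ] <- 0
      cand[, n_part <= 2] <- 0
      top <- max(cand)
      if (top <= exclusion_threshold) break
      idx <- which(cand == top, arr.ind = TRUE)[1, ]
      excluded[idx[1], idx[2]] <- TRUE
      excluded[idx[2], idx[1]] <- TRUE
      omega2 <- basis_variances(T, excluded)
      rho <- rho_from_basis(T, omega2)
    }
  }
  dimnames(rho) <- dimnames(T)
  rho
}

#' SparCC correlation estimate for an OTU table
#'
#' Averages [sparcc_from_fractions()] over `n_iterations` independent
#' Dirichlet resamples of the count table (default 20), the usual SparCC
#' routine for propagating count uncertainty.
#'
#' @param x an [otu_table()] with >= 4 OTUs and >= 3 samples.
#' @param n_iterations number of Dirichlet resampling iterations
#'   (default 20).
#' @inheritParams sparcc_from_fractions
#' @param seed optional integer seed.
#' @return symmetric correlation matrix (OTU x OTU) in \[-1, 1\].
#' @export
sparcc_correlations <- function(x, n_iterations = 20,
                                exclusion_threshold = 0.1,
                                n_exclusion_rounds = 10, seed = NULL) {
  stopifnot(inherits(x, "otu_table"))
  if (ncol(x$counts) < 4) stop("SparCC requires at least 4 OTUs")
  if (nrow(x$counts) < 3) stop("SparCC requires at least 3 samples")
  stopifnot(n_iterations >= 1)
  local_seed_if(seed)
  acc <- 0
  for (it in seq_len(n_iterations)) {
    f <- dirichlet_fractions(x)
    acc <- acc + sparcc_from_fractions(f, exclusion_threshold,
                                       n_exclusion_rounds)
  }
  rho <- acc / n_iterations
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  diag(rho) <- 1
  dimnames(rho) <- list(x$otu_ids, x$otu_ids)
  rho
}

#' Bootstrap p-values for SparCC correlations
#'
#' Builds a pairwise null by resampling each OTU's counts over samples
#' with replacement, independently per OTU — this destroys inter-OTU
#' association while preserving each OTU's marginal distribution — and
#' re-running SparCC on every bootstrap table. Two-sided p-values use the
#' add-one correction p = (1 + #\{|rho_null| >= |rho_obs|\}) / (1 + B), so
#' the smallest attainable p is 1/(B + 1).
#'
#' @param x the [otu_table()] the observed correlations came from.
#' @param rho_obs observed correlation matrix from
#'   [sparcc_correlations()].
#' @param n_bootstraps number of bootstrap tables (default 500).
#' @param n_iterations Dirichlet iterations per bootstrap SparCC run
#'   (default 1, for tractability).
#' @inheritParams sparcc_from_fractions
#' @param seed optional integer seed.
#' @return symmetric matrix of p-values (diagonal `NA`).
#' @export
bootstrap_pvalues <- function(x, rho_obs, n_bootstraps = 500,
                              n_iterations = 1,
                              exclusion_threshold = 0.1,
                              n_exclusion_rounds = 10, seed = NULL) {
  stopifnot(inherits(x, "otu_table"))
  if (n_bootstraps < 1) stop("n_bootstraps must be >= 1")
  stopifnot(all(dim(rho_obs) == ncol(x$counts)))
  local_seed_if(seed)
  cc <- x$counts
  n <- nrow(cc)
  abs_obs <- abs(rho_obs)
  ge <- matrix(0L, ncol(cc), ncol(cc))
  for (b in seq_len(n_bootstraps)) {
    boot <- cc
    for (j in seq_len(ncol(cc))) {
      boot[, j] <- cc[sample.int(n, n, replace = TRUE), j]
    }
    bt <- otu_table(boot)
    rho_b <- sparcc_correlations(bt, n_iterations = n_iterations,
                                 exclusion_threshold = exclusion_threshold,
                                 n_exclusion_rounds = n_exclusion_rounds)
    ge <- ge + (abs(rho_b) >= abs_obs)
  }
  p <- (1 + ge) / (1 + n_bootstraps)
  p <- (p + t(p)) / 2 # exact symmetry (counts are already symmetric)
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(rho_obs)
  p
}

#' Full SparCC association analysis
#'
#' Convenience wrapper: estimates correlations and bootstrap p-values in
#' one call.
#'
#' @inheritParams sparcc_correlations
#' @inheritParams bootstrap_pvalues
#' @return A list of class `association_result` with elements `rho`,
#'   `pvals`, `n_iterations`, `n_bootstraps`.
#' @export
sparcc_association <- function(x, n_iterations = 20, n_bootstraps = 500,
                               exclusion_threshold = 0.1,
                               n_exclusion_rounds = 10,
                               bootstrap_iterations = 1, seed = NULL) {
  local_seed_if(seed)
  rho <- sparcc_correlations(x, n_iterations = n_iterations,
                             exclusion_threshold = exclusion_threshold,
                             n_exclusion_rounds = n_exclusion_rounds)
  pvals <- bootstrap_pvalues(x, rho, n_bootstraps = n_bootstraps,
                             n_iterations = bootstrap_iterations,
                             exclusion_threshold = exclusion_threshold,
                             n_exclusion_rounds = n_exclusion_rounds)
  structure(list(rho = rho, pvals = pvals, n_iterations = n_iterations,
                 n_bootstraps = n_bootstraps),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "SparCC association result: %d OTUs, %d iterations, %d bootstraps\n",
    ncol(x$rho), x$n_iterations, x$n_bootstraps))
  invisible(x)
}

#' Filter SparCC associations into an edge set
#'
#' Keeps a pair (i, j) iff |rho| > `min_abs_rho` (strict) and
#' p < `alpha` (strict). OTUs with no retained pair simply do not appear
#' in the edge list (they are dropped from the association network).
#'
#' @param assoc an `association_result` from [sparcc_association()], or a
#'   list with `rho` and `pvals` matrices.
#' @param min_abs_rho correlation magnitude threshold (default 0.5).
#' @param alpha p-value threshold (default 0.05).
#' @return data.frame of class `edge_set` with columns `otu_i`, `otu_j`,
#'   `weight`, `sign` — one row per unordered pair.
#' @export
filter_associations <- function(assoc, min_abs_rho = 0.5, alpha = 0.05) {
  rho <- assoc$rho
  pvals <- assoc$pvals
  stopifnot(all(dim(rho) == dim(pvals)))
  p <- ncol(rho)
  keep <- abs(rho) > min_abs_rho & pvals < alpha
  keep[is.na(keep)] <- FALSE
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  ids <- colnames(rho)
  if (is.null(ids)) ids <- paste0("OTU", seq_len(p))
  out <- data.frame(
    otu_i = ids[idx[, 1]],
    otu_j = ids[idx[, 2]],
    weight = rho[idx],
    sign = ifelse(rho[idx] > 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  out <- out[order(out$otu_i, out$otu_j), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("edge_set", "data.frame")
  out
}
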