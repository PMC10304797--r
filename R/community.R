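#' Per-sample alpha diversity
#'
#' Observed richness (number of OTUs with count > 0) and Shannon entropy
#' in nats, H = -sum p_i ln p_i over the nonzero relative abundances of
#' each (typically rarefied) sample. An all-zero sample has richness 0
#' and H = 0.
#'
#' @param x an [otu_table()].
#' @return data.frame with columns `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  cc <- x$counts
  data.frame(
    sample_id = x$sample_ids,
    richness = as.integer(rowSums(cc > 0)),
    shannon = vegan::diversity(cc, index = "shannon"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Fixed-effects comparison of alpha diversity across groups
#'
#' Group means plus a one-way fixed-effects ANOVA per diversity measure.
#' Intended for synthetic-pipeline summaries; field designs with random
#' site/year factors call for a mixed model, which is out of scope here.
#'
#' @param div data.frame from [alpha_diversity()].
#' @param group factor (or coercible) aligned with `div` rows.
#' @return list with `means` (per-group mean richness/Shannon) and
#'   `anova` (per-measure F and p).
#' @export
compare_diversity <- function(div, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("group must have at least 2 levels")
  means <- aggregate(div[, c("richness", "shannon")],
                     by = list(group = group), FUN = mean)
  anv <- lapply(c("richness", "shannon"), function(v) {
    a <- summary(stats::aov(div[[v]] ~ group))[[1]]
    data.frame(measure = v, F = a$`F value`[1], p = a$`Pr(>F)`[1])
  })
  list(means = means, anova = do.call(rbind, anv))
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(a, b) = sum |a_i - b_i| / sum (a_i + b_i), computed on counts.
#' Pairs of all-zero samples are undefined under the formula and are set
#' to 0 with a warning.
#'
#' @param x an [otu_table()].
#' @return a `dist` object over samples, values in \[0, 1\].
#' @export
bray_curtis <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  empty <- rowSums(x$counts) == 0
  d <- suppressWarnings(vegan::vegdist(x$counts, method = "bray"))
  if (any(empty)) {
    warning("all-zero sample(s): ",
            paste(x$sample_ids[empty], collapse = ", "),
            "; affected distances set to 0")
    m <- as.matrix(d)
    m[!is.finite(m)] <- 0 # empty-vs-empty pairs are 0/0 under the formula
    d <- stats::as.dist(m)
  }
  d
}

#' PERMANOVA on a dissimilarity matrix
#'
#' Sequential (type I) partition of the distance matrix over the terms of
#' `rhs`, with p-values from free permutation of sample labels
#' (vegan's `adonis2`). R-squared per term is SS_term / SS_total.
#'
#' @param d a `dist` object, e.g. from [bray_curtis()].
#' @param metadata data.frame of sample factors, rows aligned with `d`.
#' @param rhs one-sided formula of terms, e.g. `~ treatment + site`.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed.
#' @return data.frame with one row per term (plus Residual/Total):
#'   `term`, `df`, `sum_sq`, `r2`, `pseudo_f`, `p`.
#' @export
permanova <- function(d, metadata, rhs, n_perm = 1000, seed = NULL) {
  stopifnot(inherits(d, "dist"))
  vars <- all.vars(rhs)
  if (!all(vars %in% names(metadata))) {
    stop("metadata is missing term(s): ",
         paste(setdiff(vars, names(metadata)), collapse = ", "))
  }
  for (v in vars) {
    if (length(unique(metadata[[v]])) < 2) {
      stop("factor '", v, "' has a single level; PERMANOVA is undefined")
    }
  }
  local_seed_if(seed)
  form <- stats::as.formula(paste("d ~", as.character(rhs)[2]))
  env <- new.env(parent = environment())
  assign("d", d, envir = env)
  environment(form) <- env
  res <- vegan::adonis2(form, data = metadata, permutations = n_perm,
                        by = "terms")
  data.frame(term = rownames(res), df = res$Df, sum_sq = res$SumOfSqs,
             r2 = res$R2, pseudo_f = res$F, p = res$`Pr(>F)`,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR control (wraps `stats::p.adjust`).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return vector of BH-adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Negative-binomial differential abundance, per OTU
#'
#' For each contrast (a treatment level against a control level or a
#' pooled set of control levels) and each OTU, fits a negative-binomial
#' GLM with log link and log library-size offset on the samples of the
#' two groups:
#' count ~ group + offset(log(libsize)). The dispersion is estimated per
#' OTU by maximum likelihood (`MASS::glm.nb`); the group effect is
#' tested by a 1-df deviance likelihood-ratio test against the
#' intercept-only model at the fitted dispersion. The offset makes the model an implicit model of
#' proportions. q-values are BH-adjusted within each contrast family;
#' `status` is `enriched` / `depleted` at q < `alpha` by the sign of the
#' fold change, `ns` otherwise. OTUs whose fit does not converge (even
#' after a method-of-moments dispersion fallback) are flagged and
#' excluded from the BH family.
#'
#' @param x an [otu_table()] (raw or filtered counts; the library-size
#'   offset handles unequal depths).
#' @param group factor of treatment levels aligned with samples.
#' @param contrasts named list; each element `list(level = "A", control =
#'   c("B", ...))`. Default: every non-first level against the first
#'   level of `group`.
#' @param alpha FDR threshold for calling status (default 0.01).
#' @return data.frame of class `daotu_result`: `otu`, `contrast`,
#'   `log2fc`, `lrt_stat`, `p`, `q`, `status`, `converged`.
#' @export
fit_nb_per_otu <- function(x, group, contrasts = NULL, alpha = 0.01) {
  stopifnot(inherits(x, "otu_table"))
  group <- factor(group)
  if (length(group) != nrow(x$counts)) {
    stop("group must align with the samples of x")
  }
  if (is.null(contrasts)) {
    ref <- levels(group)[1]
    contrasts <- lapply(levels(group)[-1], function(l) {
      list(level = l, control = ref)
    })
    names(contrasts) <- paste0(levels(group)[-1], "_vs_", ref)
  }
  lib <- rowSums(x$counts)
  out <- list()
  for (cn in names(contrasts)) {
    ct <- contrasts[[cn]]
    sel <- group %in% c(ct$level, ct$control)
    g01 <- factor(ifelse(group[sel] == ct$level, "trt", "ctl"),
                  levels = c("ctl", "trt"))
    if (min(table(g01)) < 2) {
      stop("contrast '", cn, "' needs >= 2 samples per side")
    }
    cc <- x$counts[sel, , drop = FALSE]
    off <- log(lib[sel])
    res <- lapply(seq_len(ncol(cc)), function(j) {
      nb_one_otu(cc[, j], g01, off)
    })
    df <- do.call(rbind, res)
    df$otu <- x$otu_ids
    df$contrast <- cn
    df$q <- NA_real_
    ok <- df$converged
    df$q[ok] <- bh_adjust(df$p[ok])
    df$status <- "ns"
    df$status[ok & !is.na(df$q) & df$q < alpha & df$log2fc > 0] <- "enriched"
    df$status[ok & !is.na(df$q) & df$q < alpha & df$log2fc < 0] <- "depleted"
    out[[cn]] <- df
  }
  res <- do.call(rbind, out)
  res <- res[, c("otu", "contrast", "log2fc", "lrt_stat", "p", "q",
                 "status", "converged")]
  rownames(res) <- NULL
  if (any(!res$converged)) {
    warning(sum(!res$converged),
            " OTU fits did not converge; excluded from BH adjustment")
  }
  class(res) <- c("daotu_result", "data.frame")
  res
}

# One OTU's NB GLM: ML dispersion from the full model (MASS::glm.nb),
# then a 1-df deviance LRT of the group effect at that dispersion.
# When ML dispersion estimation fails (e.g. variance at or below the
# mean, where theta diverges) a method-of-moments theta takes over.
nb_one_otu <- function(y, g01, off) {
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(y ~ g01 + offset(off))),
    error = function(e) NULL)
  theta <- if (!is.null(fit) && fit$converged && is.finite(fit$theta)) {
    fit$theta
  } else {
    nb_theta_moments(y)
  }
  fam <- MASS::negative.binomial(theta)
  full <- tryCatch(
    suppressWarnings(stats::glm(y ~ g01 + offset(off), family = fam)),
    error = function(e) NULL)
  null <- tryCatch(
    suppressWarnings(stats::glm(y ~ 1 + offset(off), family = fam)),
    error = function(e) NULL)
  if (is.null(full) || is.null(null) || !full$converged) {
    return(data.frame(log2fc = NA_real_, lrt_stat = NA_real_,
                      p = NA_real_, converged = FALSE))
  }
  stat <- max(0, null$deviance - full$deviance)
  data.frame(
    log2fc = unname(stats::coef(full)["g01trt"]) / log(2),
    lrt_stat = stat,
    p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    converged = TRUE)
}

nb_theta_moments <- function(y) {
  mu <- mean(y)
  v <- stats::var(y)
  if (!is.finite(v) || v <= mu || mu == 0) return(1e8) # ~Poisson
  mu^2 / (v - mu)
}
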