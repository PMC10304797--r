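#' Standardised relative-abundance predictors
#'
#' Converts a (typically rarefied) count table into the predictor matrix
#' used for phenotype modelling: per-sample relative abundances, each
#' column centred to mean 0 and scaled to sd 1 so that the L1 penalty
#' treats all OTUs equally. Constant columns become all-zero (they carry
#' no information and can never be selected).
#'
#' @param x an [otu_table()].
#' @return numeric matrix (samples x OTUs).
#' @export
otu_predictors <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  rel <- x$counts / rowSums(x$counts)
  s <- apply(rel, 2, stats::sd)
  ctr <- scale(rel, center = TRUE, scale = FALSE)
  ctr[, s > 0] <- sweep(ctr[, s > 0, drop = FALSE], 2, s[s > 0], "/")
  ctr[, s == 0] <- 0
  m <- as.matrix(ctr)
  attr(m, "scaled:center") <- NULL
  attr(m, "scaled:scale") <- NULL
  m
}

#' Tune the lasso penalty by repeated k-fold cross-validation
#'
#' Fits the L1-regularised linear model of a continuous phenotype on OTU
#' predictors over a lambda grid and scores each lambda by held-out
#' squared error, repeating the k-fold split `n_repeats` times. The grid
#' (when not supplied) is the glmnet path: 100 values log-spaced from
#' lambda_max (smallest lambda that zeroes every coefficient) down to
#' 1e-4 * lambda_max.
#'
#' @param x predictor matrix (samples x OTUs), e.g. [otu_predictors()].
#'   Columns are standardised internally if `standardize = TRUE`.
#' @param y numeric phenotype vector aligned to the rows of `x`.
#' @param k_folds folds per repeat (default 5).
#' @param n_repeats CV repeats (default 500).
#' @param lambda optional explicit lambda grid (decreasing).
#' @param selection_rule `"min_mean_1se"` (default): the largest lambda
#'   whose mean CV error is within one standard error of the minimum
#'   (the usual one-SE rule; under a pure-noise phenotype the CV minimum
#'   rewards chance in-sample correlations, whereas the one-SE rule
#'   returns the empty model); `"min_mean_cv"`: lambda minimising the
#'   mean CV error; `"min_cv_variance"`: lambda minimising the variance
#'   of CV error across repeats. Ties go to the larger (sparser) lambda.
#' @param standardize standardise predictor columns before fitting
#'   (default TRUE).
#' @param seed optional integer seed controlling the fold splits.
#' @param thresh glmnet convergence threshold for the final refit.
#' @return A list of class `lasso_fit`: `lambda_grid`,
#'   `selected_lambda`, `coefficients` (named per-OTU vector at the
#'   selected lambda, intercept excluded), `intercept`, `cv_table`
#'   (lambda, cv_mean, cv_var), `selection_rule`, `n_repeats`, `k_folds`.
#' @export
tune_lambda <- function(x, y, k_folds = 5, n_repeats = 500,
                        lambda = NULL,
                        selection_rule = c("min_mean_1se",
                                           "min_mean_cv",
                                           "min_cv_variance"),
                        standardize = TRUE, seed = NULL,
                        thresh = 1e-10) {
  selection_rule <- match.arg(selection_rule)
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (length(y) != n) stop("rows of x must align with y")
  if (stats::sd(y) == 0) stop("phenotype y is constant; nothing to model")
  if (k_folds > n) stop("k_folds (", k_folds, ") exceeds sample size (", n, ")")
  if (k_folds < 2) stop("k_folds must be >= 2")
  local_seed_if(seed)
  if (standardize) {
    s <- apply(x, 2, stats::sd)
    x <- scale(x, center = TRUE, scale = FALSE)
    x[, s > 0] <- sweep(x[, s > 0, drop = FALSE], 2, s[s > 0], "/")
    x[, s == 0] <- 0
  }
  if (is.null(lambda)) {
    path <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                           nlambda = 100, lambda.min.ratio = 1e-4,
                           standardize = FALSE)
    lambda <- path$lambda
  }
  lambda <- sort(unique(as.numeric(lambda)), decreasing = TRUE)
  err <- matrix(NA_real_, n_repeats, length(lambda))
  fold_se <- matrix(0, n_repeats, length(lambda)) # per-repeat SE over folds
  for (r in seq_len(n_repeats)) {
    fold <- sample(rep_len(seq_len(k_folds), n))
    se <- matrix(NA_real_, n, length(lambda))
    fe <- matrix(NA_real_, k_folds, length(lambda))
    for (k in seq_len(k_folds)) {
      te <- fold == k
      fit <- glmnet::glmnet(x[!te, , drop = FALSE], y[!te],
                            family = "gaussian", alpha = 1,
                            lambda = lambda, standardize = FALSE)
      pred <- stats::predict(fit, newx = x[te, , drop = FALSE], s = lambda)
      se[te, ] <- (pred - y[te])^2
      fe[k, ] <- colMeans((pred - y[te])^2)
    }
    err[r, ] <- colMeans(se)
    fold_se[r, ] <- apply(fe, 2, stats::sd) / sqrt(k_folds)
  }
  cv_mean <- colMeans(err)
  cv_var <- apply(err, 2, stats::var)
  if (n_repeats == 1) cv_var <- rep(0, length(lambda))
  # the SE reflects fold-resampling uncertainty (averaged over repeats),
  # not repeat-averaging precision, so the one-SE rule does not collapse
  # onto the CV minimum as n_repeats grows
  cv_se <- colMeans(fold_se)
  sel <- switch(selection_rule,
    min_mean_cv = which(cv_mean <= min(cv_mean) + 1e-15)[1],
    min_cv_variance = which(cv_var <= min(cv_var) + 1e-15)[1],
    min_mean_1se = {
      i_min <- which.min(cv_mean)
      which(cv_mean <= cv_mean[i_min] + cv_se[i_min])[1]
    })
  selected_lambda <- lambda[sel]
  full <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                         lambda = lambda, standardize = FALSE,
                         thresh = thresh)
  beta <- stats::coef(full, s = selected_lambda)
  coefs <- as.numeric(beta)[-1]
  names(coefs) <- rownames(beta)[-1]
  coefs[abs(coefs) < 1e-10] <- 0 # numerical dust at the path boundary
  structure(list(
    lambda_grid = lambda,
    selected_lambda = selected_lambda,
    coefficients = coefs,
    intercept = as.numeric(beta)[1],
    cv_table = data.frame(lambda = lambda, cv_mean = cv_mean,
                          cv_var = cv_var, cv_se = cv_se),
    selection_rule = selection_rule,
    n_repeats = n_repeats, k_folds = k_folds,
    glmnet_fit = full), class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf(
    "lasso_fit: %d-fold CV x %d repeats, rule '%s'\n  selected lambda %.4g, %d nonzero coefficients\n",
    x$k_folds, x$n_repeats, x$selection_rule, x$selected_lambda,
    sum(x$coefficients != 0)))
  invisible(x)
}

#' OTUs selected by the lasso fit
#'
#' Returns the ids whose coefficient at the selected lambda is nonzero,
#' ranked by importance (absolute standardised coefficient, largest
#' first). An empty character vector is a legitimate result.
#'
#' @param fit a `lasso_fit` from [tune_lambda()].
#' @return character vector of OTU ids.
#' @export
select_predictive_otus <- function(fit) {
  stopifnot(inherits(fit, "lasso_fit"))
  nz <- fit$coefficients[fit$coefficients != 0]
  names(nz)[order(abs(nz), decreasing = TRUE)]
}

#' Reduced GLM of phenotype on the selected OTUs
#'
#' Refits the phenotype on the lasso-selected OTUs only, without penalty,
#' to obtain per-OTU coefficients, Wald p-values and association signs.
#' The sign (positive/negative) styles each OTU's link to the phenotype
#' node in the PhONA graph.
#'
#' @param x_sel matrix of selected-OTU predictors (samples x selected).
#' @param y numeric phenotype vector.
#' @param family currently `"gaussian"` (identity link), suitable for a
#'   continuous yield phenotype.
#' @return A list of class `phenotype_model`: `selected_otus`,
#'   `glm_coefficients`, `glm_pvalues`, `sign` (named "positive" /
#'   "negative"), `intercept`, `fit` (the underlying `glm` object).
#' @export
fit_reduced_glm <- function(x_sel, y, family = "gaussian") {
  family <- match.arg(family, "gaussian")
  x_sel <- as.matrix(x_sel)
  y <- as.numeric(y)
  if (ncol(x_sel) < 1) stop("at least one selected OTU is required")
  if (nrow(x_sel) != length(y)) stop("rows of x_sel must align with y")
  if (nrow(x_sel) <= ncol(x_sel) + 1) {
    stop("need n > number of selected OTUs + 1 for the reduced GLM")
  }
  df <- data.frame(.y = y, x_sel, check.names = FALSE)
  fit <- stats::glm(.y ~ ., data = df, family = stats::gaussian())
  cf <- stats::coef(fit)
  aliased <- setdiff(names(cf)[is.na(cf)], "(Intercept)")
  if (length(aliased) > 0) {
    warning("dropping aliased (rank-deficient) predictors: ",
            paste(gsub("`", "", aliased), collapse = ", "))
    keep <- setdiff(colnames(x_sel), gsub("`", "", aliased))
    return(fit_reduced_glm(x_sel[, keep, drop = FALSE], y, family))
  }
  sm <- summary(fit)$coefficients
  otus <- colnames(x_sel)
  rn <- gsub("`", "", rownames(sm))
  coefs <- sm[match(otus, rn), "Estimate"]
  pvals <- sm[match(otus, rn), "Pr(>|t|)"]
  names(coefs) <- names(pvals) <- otus
  structure(list(
    selected_otus = otus,
    glm_coefficients = coefs,
    glm_pvalues = pvals,
    sign = stats::setNames(ifelse(coefs > 0, "positive", "negative"), otus),
    intercept = unname(cf["(Intercept)"]),
    fit = fit), class = "phenotype_model")
}

#' @export
print.phenotype_model <- function(x, ...) {
  cat(sprintf("phenotype_model: %d selected OTUs (%d positive, %d negative)\n",
              length(x$selected_otus), sum(x$sign == "positive"),
              sum(x$sign == "negative")))
  invisible(x)
}

# An empty phenotype model (no OTU selected); downstream PhONA assembly
# then yields a phenotype node with zero phenotype links.
empty_phenotype_model <- function() {
  structure(list(selected_otus = character(0),
                 glm_coefficients = stats::setNames(numeric(0), character(0)),
                 glm_pvalues = stats::setNames(numeric(0), character(0)),
                 sign = stats::setNames(character(0), character(0)),
                 intercept = NA_real_, fit = NULL),
            class = "phenotype_model")
}

#' Phenotype-predictive OTU selection, end to end
#'
#' Runs the full selection stage on one treatment x compartment subset:
#' standardised relative-abundance predictors, repeated-CV lasso tuning,
#' nonzero-coefficient selection, then the unpenalised reduced GLM that
#' signs each selected OTU's association with the phenotype.
#'
#' @param x an [otu_table()] (typically rarefied).
#' @param y numeric phenotype vector aligned to the samples (e.g.
#'   marketable yield).
#' @inheritParams tune_lambda
#' @param ... further arguments to [tune_lambda()].
#' @return A `phenotype_model` (possibly empty) with the `lasso_fit`
#'   attached as attribute `"lasso_fit"`.
#' @export
phenotype_model <- function(x, y, k_folds = 5, n_repeats = 500,
                            seed = NULL, ...) {
  stopifnot(inherits(x, "otu_table"))
  preds <- otu_predictors(x)
  fit <- tune_lambda(preds, y, k_folds = k_folds, n_repeats = n_repeats,
                     standardize = FALSE, seed = seed, ...)
  sel <- select_predictive_otus(fit)
  model <- if (length(sel) == 0) {
    empty_phenotype_model()
  } else {
    fit_reduced_glm(preds[, sel, drop = FALSE], y)
  }
  attr(model, "lasso_fit") <- fit
  model
}
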