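test_that("generated counts honour depth, dimensions, and determinism", {
  cfg <- synth_config(n_samples = 12, n_otus = 8, depth = 500, seed = 5)
  g1 <- generate_counts(cfg)
  g2 <- generate_counts(cfg)
  expect_identical(otu_counts(g1$table), otu_counts(g2$table))
  expect_true(all(rowSums(otu_counts(g1$table)) == 500))
  expect_identical(dim(g1$table), c(12L, 8L))
  # different seed, different draw
  g3 <- generate_counts(synth_config(n_samples = 12, n_otus = 8,
                                     depth = 500, seed = 6))
  expect_false(identical(otu_counts(g1$table), otu_counts(g3$table)))
})

test_that("planted log-abundance correlations converge to the configured values", {
  cfg <- synth_config(n_samples = 5000, n_otus = 6, depth = 50000,
                      correlations = data.frame(i = c(1, 3), j = c(2, 4),
                                                rho = c(0.7, -0.5)),
                      seed = 7)
  gen <- generate_counts(cfg)
  Z <- gen$truth$log_basis
  expect_lt(abs(cor(Z[, 1], Z[, 2]) - 0.7), 0.05)
  expect_lt(abs(cor(Z[, 3], Z[, 4]) - (-0.5)), 0.05)
  # off-spec pairs stay near zero
  expect_lt(abs(cor(Z[, 5], Z[, 6])), 0.05)
})

test_that("a non-positive-definite correlation spec is repaired or rejected", {
  bad <- data.frame(i = c(1, 2, 1), j = c(2, 3, 3),
                    rho = c(0.9, 0.9, -0.9))
  cfg <- synth_config(n_samples = 10, n_otus = 4, depth = 100,
                      correlations = bad, seed = 8)
  expect_warning(gen <- generate_counts(cfg), "positive definite")
  expect_true(all(rowSums(otu_counts(gen$table)) == 100))
  expect_error(synth_config(correlations = data.frame(i = 1, j = 2,
                                                      rho = 1.2)))
})

test_that("phenotype generation follows the planted linear model", {
  cfg0 <- synth_config(n_samples = 60, n_otus = 10, depth = 2000,
                       phenotype = list(otus = 3, betas = 2, sd = 0),
                       seed = 9)
  gen <- generate_counts(cfg0)
  ph <- generate_phenotype(gen$table, cfg0)
  # sd = 0, one driver: phenotype is an exact linear function -> R^2 = 1
  rel <- otu_counts(gen$table) / 2000
  r2 <- suppressWarnings(summary(lm(ph$y ~ rel[, 3]))$r.squared)
  expect_gt(r2, 0.999)
  expect_identical(ph$truth$otus, "OTU_003")
  # truth records the planted signs
  cfg1 <- synth_config(n_samples = 60, n_otus = 10, depth = 2000,
                       phenotype = list(otus = c(1, 2), betas = c(2, -3),
                                        sd = 0.1), seed = 10)
  gen1 <- generate_counts(cfg1)
  ph1 <- generate_phenotype(gen1$table, cfg1)
  expect_identical(unname(ph1$truth$signs), c("positive", "negative"))
  m <- phenotype_model(gen1$table, ph1$y, n_repeats = 10, seed = 11)
  common <- intersect(ph1$truth$otus, m$selected_otus)
  expect_true(length(common) == 2)
  expect_identical(m$sign[common], ph1$truth$signs[common])
})

test_that("a null phenotype yields (almost always) an empty selection", {
  empties <- 0
  for (s in 1:5) {
    cfg <- synth_config(n_samples = 50, n_otus = 30, depth = 2000,
                        phenotype = list(otus = 1, betas = 0, sd = 1),
                        seed = 500 + s)
    gen <- generate_counts(cfg)
    ph <- generate_phenotype(gen$table, cfg)
    m <- phenotype_model(gen$table, ph$y, n_repeats = 50, seed = 600 + s)
    if (length(m$selected_otus) == 0) empties <- empties + 1
  }
  expect_gte(empties, 4)
})

test_that("balanced designs are generated and imbalance is rejected", {
  cfg <- synth_config(n_samples = 40, n_otus = 5, depth = 100,
                      treatment = list(levels = c("a", "b", "c", "d")),
                      seed = 12)
  d <- generate_design(cfg)
  expect_equal(nrow(d), 40L)
  expect_true(all(table(d$treatment) == 10))
  cfg2 <- synth_config(n_samples = 41, n_otus = 5, depth = 100,
                       treatment = list(levels = c("a", "b", "c", "d")),
                       seed = 12)
  expect_error(generate_design(cfg2), "not a multiple")
})

test_that("planted treatment fold changes are recovered and nulls stay quiet", {
  # effects planted on minor OTUs (low mu) so the compositional squeeze
  # on the remaining community stays well below the biological noise
  cfg <- synth_config(
    n_samples = 20, n_otus = 40, depth = 4000,
    mu_log = c(rep(0, 4), seq(0.5, 3, length.out = 36)), sigma_log = 1,
    treatment = list(levels = c("ctl", "trt"),
                     effects = data.frame(otu = 1:4, level = "trt",
                                          log2fc = 4)),
    seed = 13)
  gen <- generate_counts(cfg)
  res <- suppressWarnings(
    fit_nb_per_otu(gen$table, gen$design$treatment,
                   contrasts = list(tc = list(level = "trt",
                                              control = "ctl")),
                   alpha = 0.01))
  hit <- res$otu[res$status == "enriched"]
  expect_gte(sum(sprintf("OTU_%03d", 1:4) %in% hit), 3)
  # zero planted effects: 0-2 calls in 200 OTUs across replicates
  calls <- c()
  for (s in 1:3) {
    cfg0 <- synth_config(n_samples = 20, n_otus = 200, depth = 4000,
                         sigma_log = 1,
                         treatment = list(levels = c("ctl", "trt")),
                         seed = 700 + s)
    gen0 <- generate_counts(cfg0)
    res0 <- suppressWarnings(
      fit_nb_per_otu(gen0$table, gen0$design$treatment, alpha = 0.01))
    calls <- c(calls, sum(res0$status != "ns"))
  }
  expect_lte(max(calls), 2)
})
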