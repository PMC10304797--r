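test_that("alpha diversity matches closed forms", {
  counts <- rbind(rep(5L, 10),            # uniform over 10 OTUs
                  c(7L, rep(0L, 9)),      # single OTU
                  c(1L, 1L, 2L, rep(0L, 7)),
                  rep(0L, 10))            # empty sample
  t <- toy_table(counts)
  d <- alpha_diversity(t)
  expect_equal(d$richness, c(10L, 1L, 3L, 0L))
  expect_equal(d$shannon[1], log(10), tolerance = 1e-12)
  expect_equal(d$shannon[2], 0)
  expect_equal(d$shannon[3],
               -(2 * 0.25 * log(0.25) + 0.5 * log(0.5)),
               tolerance = 1e-12)
  expect_equal(d$shannon[4], 0)
  # H never exceeds ln(richness); equality only for the uniform row
  nz <- d$richness >= 1
  expect_true(all(d$shannon[nz] <= log(d$richness[nz]) + 1e-12))
  expect_lt(d$shannon[3], log(3))
})

test_that("Bray-Curtis matches hand computation and stays in [0, 1]", {
  t <- toy_table(rbind(c(6L, 2L), c(2L, 2L), c(6L, 2L), c(0L, 7L)))
  d <- as.matrix(bray_curtis(t))
  expect_equal(d["s1", "s2"], 1 / 3, tolerance = 1e-12)
  expect_equal(d["s1", "s3"], 0)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  # disjoint supports -> 1
  t2 <- toy_table(rbind(c(5L, 0L), c(0L, 4L)))
  expect_equal(as.matrix(bray_curtis(t2))[1, 2], 1)
  # two all-zero samples -> distance 0 with a warning
  t3 <- toy_table(rbind(c(0L, 0L), c(0L, 0L), c(1L, 2L)))
  expect_warning(d3 <- as.matrix(bray_curtis(t3)), "all-zero")
  expect_equal(d3["s1", "s2"], 0)
})

test_that("PERMANOVA partitions variance sequentially with valid R2", {
  set.seed(71)
  m <- matrix(rpois(24 * 40, 15), 24, 40,
              dimnames = list(paste0("s", 1:24), paste0("O", 1:40)))
  # plant a group shift on a few OTUs
  grp <- rep(c("a", "b"), each = 12)
  m[grp == "b", 1:5] <- m[grp == "b", 1:5] + 30L
  md <- data.frame(g = grp, block = rep(c("x", "y"), 12))
  t <- toy_table(m)
  res <- permanova(bray_curtis(t), md, ~ g + block, n_perm = 199,
                   seed = 72)
  expect_identical(res$term[1:2], c("g", "block"))
  r2 <- res$r2[seq_len(nrow(res) - 1)]
  expect_true(all(r2 >= 0))
  expect_lte(sum(r2), 1 + 1e-12)
  expect_lt(res$p[1], 0.05) # planted structure is detected
  # single-level factor errors
  md1 <- data.frame(g = rep("a", 24))
  expect_error(permanova(bray_curtis(t), md1, ~g, n_perm = 99), "single level")
})

test_that("PERMANOVA rejects at roughly the nominal rate under the null", {
  rej <- 0
  for (r in 1:30) {
    set.seed(300 + r)
    m0 <- matrix(rpois(20 * 30, 20), 20, 30,
                 dimnames = list(paste0("s", 1:20), paste0("O", 1:30)))
    res0 <- permanova(bray_curtis(toy_table(m0)),
                      data.frame(g = rep(c("a", "b"), each = 10)), ~g,
                      n_perm = 199, seed = r)
    if (res0$p[1] < 0.05) rej <- rej + 1
  }
  expect_lte(rej, 5) # nominal expectation 1.5 of 30
})

test_that("BH adjustment reproduces the step-up values and preserves order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(75)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_identical(order(p), order(q, p))
  expect_true(all(q >= p - 1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("NB differential abundance recovers planted enrichment with controlled FDR", {
  flagged_frac <- c()
  fdr <- c()
  for (s in 1:3) {
    set.seed(80 + s)
    n_otu <- 200
    n <- 20
    grp <- factor(rep(c("ctl", "trt"), each = 10), levels = c("ctl", "trt"))
    mu <- exp(rnorm(n_otu, 4.5, 1))
    planted <- 1:20
    # the effect sits on low-abundance OTUs so that the planted mass
    # barely moves the total library size (a large shift would make
    # every null OTU look depleted through the offset)
    mu[planted] <- exp(3)
    cc <- sapply(seq_len(n_otu), function(j) {
      m <- rep(mu[j], n)
      if (j %in% planted) m[grp == "trt"] <- m[grp == "trt"] * 4
      rnbinom(n, mu = m, size = 2)
    })
    dimnames(cc) <- list(paste0("s", 1:n), paste0("OTU", 1:n_otu))
    res <- suppressWarnings(
      fit_nb_per_otu(otu_table(cc), grp,
                     contrasts = list(t_vs_c = list(level = "trt",
                                                    control = "ctl")),
                     alpha = 0.01))
    hit <- res$otu[res$status != "ns"]
    flagged_frac <- c(flagged_frac,
                      mean(paste0("OTU", planted) %in% hit))
    if (length(hit) > 0) {
      fdr <- c(fdr, mean(!(hit %in% paste0("OTU", planted))))
    }
    # planted OTUs are enriched, not depleted
    st <- res$status[res$otu %in% paste0("OTU", planted) & res$status != "ns"]
    expect_true(all(st == "enriched"))
  }
  expect_gte(mean(flagged_frac), 0.7)
  expect_lte(mean(fdr), 0.05)
})

test_that("an OTU with identical counts across groups is a clear null", {
  set.seed(90)
  cc <- cbind(OTUflat = rep(8L, 12),
              matrix(rpois(12 * 5, 20), 12,
                     dimnames = list(NULL, paste0("O", 1:5))))
  rownames(cc) <- paste0("s", 1:12)
  grp <- rep(c("a", "b"), each = 6)
  res <- suppressWarnings(fit_nb_per_otu(otu_table(cc), grp))
  flat <- res[res$otu == "OTUflat", ]
  expect_lt(abs(flat$log2fc), 0.25) # offset varies slightly across samples
  expect_gt(flat$p, 0.2)
})

test_that("NB q-values never undercut their p-values within a contrast", {
  set.seed(91)
  cc <- matrix(rnbinom(16 * 30, mu = 25, size = 1), 16,
               dimnames = list(paste0("s", 1:16), paste0("O", 1:30)))
  res <- suppressWarnings(fit_nb_per_otu(otu_table(cc),
                                         rep(c("a", "b"), each = 8)))
  ok <- res$converged
  expect_true(all(res$q[ok] >= res$p[ok] - 1e-12))
})

test_that("diversity group comparison reports means and a fixed-effects test", {
  set.seed(92)
  t <- toy_table(matrix(rpois(20 * 15, 10), 20,
                        dimnames = list(paste0("s", 1:20),
                                        paste0("O", 1:15))))
  div <- alpha_diversity(t)
  cmp <- compare_diversity(div, rep(c("a", "b"), each = 10))
  expect_equal(nrow(cmp$means), 2L)
  expect_true(all(c("richness", "shannon") %in% cmp$anova$measure))
  expect_true(all(cmp$anova$p >= 0 & cmp$anova$p <= 1))
})
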