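samples4 <- c("i1", "i2", "c1", "c2")
meta4 <- toy_metadata(samples4, c("injured", "injured", "control", "control"))

test_that("upper-quartile factors: symmetry, scale equivariance, quantile oracle", {
  cnt <- toy_counts(rep(c(5L, 10L, 20L, 40L), 4), 4, samples4)
  f <- size_factors_upper_quartile(cnt)
  expect_equal(f$size_factor, rep(1, 4))

  doubled <- cnt
  doubled$i1 <- doubled$i1 * 2L
  f2 <- size_factors_upper_quartile(doubled)
  expect_equal(f2$size_factor[1] / f2$size_factor[2], 2)

  # 4-gene 2-sample toy: hand-checkable type-7 quantile then geometric-mean rescale
  toy <- toy_counts(c(1L, 2L, 3L, 4L, 2L, 4L, 6L, 8L), 4, c("s1", "s2"))
  q <- c(stats::quantile(1:4, 0.75, type = 7, names = FALSE),
         stats::quantile(c(2, 4, 6, 8), 0.75, type = 7, names = FALSE))
  expected <- q / exp(mean(log(q)))
  f3 <- size_factors_upper_quartile(toy)
  expect_equal(f3$size_factor, expected)

  allzero <- toy_counts(c(1L, 2L, 0L, 0L), 2, c("ok", "bad"))
  expect_error(size_factors_upper_quartile(allzero), "bad")
})

test_that("median-of-ratios factors: symmetry, doubling, zero-gene exclusion", {
  cnt <- toy_counts(rep(c(5L, 10L, 20L, 40L), 4), 4, samples4)
  expect_equal(size_factors_median_of_ratios(cnt)$size_factor, rep(1, 4))

  doubled <- cnt
  doubled$i1 <- doubled$i1 * 2L
  f <- size_factors_median_of_ratios(doubled)
  expect_equal(f$size_factor[1] / f$size_factor[2], 2)

  # gene with a zero drops out of the reference set
  withzero <- toy_counts(c(3L, 8L, 0L, 6L, 16L, 9L), 3, c("s1", "s2"))
  f2 <- size_factors_median_of_ratios(withzero)
  keep <- matrix(c(3, 8, 6, 16), nrow = 2, byrow = FALSE)
  gm <- exp(rowMeans(log(keep)))
  expected <- apply(keep / gm, 2, median)
  expect_equal(f2$size_factor, expected)

  nozero <- toy_counts(c(3L, 0L, 0L, 6L), 2, c("s1", "s2"))
  expect_error(size_factors_median_of_ratios(nozero), "all-positive")
})

test_that("FPKM matches its definition", {
  cnt <- toy_counts(c(10L, 999990L, 250L, 4999750L), 2, c("s1", "s2"))
  lengths <- tibble::tibble(gene_id = c("g01", "g02"),
                            length = c(1000L, 2500L))
  fpkm <- fpkm_matrix(cnt, lengths)
  expect_equal(fpkm$s1[1], 10 * 1e9 / (1000 * 1e6))          # = 10
  expect_equal(fpkm$s2[1], 250 * 1e9 / (1000 * 5e6))
  expect_equal(fpkm$s2[2], 4999750 * 1e9 / (2500 * 5e6))
  zero <- toy_counts(c(0L, 5L), 2, "s1")
  fz <- fpkm_matrix(zero, tibble::tibble(gene_id = c("g01", "g02"),
                                         length = c(500L, 500L)))
  expect_equal(fz$s1[1], 0)
  expect_error(fpkm_matrix(cnt, lengths[1, ]), "g02")
})

test_that("dispersion estimation recovers simulation truth", {
  n <- 2000
  nrep <- 50
  samples <- c(sprintf("a%d", 1:nrep), sprintf("b%d", 1:nrep))
  meta <- toy_metadata(samples, rep(c("injured", "control"), each = nrep))

  withr::with_seed(21, {
    pois <- toy_counts(rpois(n * 2 * nrep, lambda = 50), n, samples)
    nb <- toy_counts(rnbinom(n * 2 * nrep, mu = 100, size = 1 / 0.2), n, samples)
  })
  d_pois <- estimate_dispersion(pois, meta, unit_factors(samples), shrink = FALSE)
  expect_lt(abs(median(d_pois$dispersion)), 0.01)

  d_nb <- estimate_dispersion(nb, meta, unit_factors(samples), shrink = FALSE)
  expect_gt(median(d_nb$dispersion), 0.15)
  expect_lt(median(d_nb$dispersion), 0.25)

  const <- toy_counts(rep(7L, 8), 2, samples4)
  d_const <- estimate_dispersion(const, meta4, unit_factors(samples4),
                                 shrink = FALSE)
  expect_equal(d_const$dispersion, c(0, 0))

  single <- toy_metadata(samples4, c("injured", "control", "control", "control"))
  expect_error(estimate_dispersion(const, single, unit_factors(samples4)),
               "fewer than 2")
})

test_that("exact NB test: null symmetry, binomial limit, monotonicity", {
  disp0 <- tibble::tibble(gene_id = "g01", dispersion = 0)

  # identical group means -> log2FC 0, p = 1
  sym <- toy_counts(c(5L, 7L, 5L, 7L), 1, samples4)
  r <- nb_test(sym, meta4, unit_factors(samples4),
               tibble::tibble(gene_id = "g01", dispersion = 0.1))
  expect_equal(r$log2FC, 0)
  expect_equal(r$pvalue, 1)

  # dispersion 0, totals 30 vs 10 at equal depth: exact binomial on 40 trials
  cnt <- toy_counts(c(14L, 16L, 4L, 6L), 1, samples4)
  r2 <- nb_test(cnt, meta4, unit_factors(samples4), disp0)
  expected <- 2 * min(pbinom(30, 40, 0.5), pbinom(29, 40, 0.5, lower.tail = FALSE))
  expect_equal(r2$pvalue, expected, tolerance = 1e-14)
  expect_equal(r2$log2FC, log2((15 + 1) / (5 + 1)))

  # pushing the injured totals further from the null never raises the p-value
  pvals <- vapply(seq(10L, 40L, by = 2L), function(k) {
    cc <- toy_counts(c(k, k, 10L, 10L), 1, samples4)
    nb_test(cc, meta4, unit_factors(samples4), disp0)$pvalue
  }, numeric(1))
  expect_true(all(diff(pvals) <= 1e-12))
})

test_that("exact NB test matches an independent conditional-pmf oracle", {
  withr::with_seed(31, {
    for (i in 1:25) {
      n_a <- sample(2:5, 1)
      n_b <- sample(2:5, 1)
      phi <- runif(1, 0.02, 0.5)
      s_a <- rpois(1, 60)
      s_b <- rpois(1, 40)
      samples <- c(sprintf("a%d", 1:n_a), sprintf("b%d", 1:n_b))
      meta <- toy_metadata(samples, rep(c("injured", "control"), c(n_a, n_b)))
      # spread the group totals over samples
      a_counts <- as.integer(rmultinom(1, s_a, rep(1, n_a)))
      b_counts <- as.integer(rmultinom(1, s_b, rep(1, n_b)))
      cnt <- toy_counts(c(a_counts, b_counts), 1, samples)
      got <- nb_test(cnt, meta, unit_factors(samples),
                     tibble::tibble(gene_id = "g01", dispersion = phi))$pvalue
      want <- nb_conditional_oracle(s_a, s_b, n_a, n_b, phi)
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
})

test_that("BH adjustment matches the step-up oracle and its boundary cases", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  withr::with_seed(41, {
    for (i in 1:1000) {
      p <- runif(sample(1:30, 1))
      adj <- adjust_bh(p)
      expect_equal(adj, bh_oracle(p), tolerance = 1e-14)
      expect_true(all(adj >= p))
      expect_true(all(adj <= 1))
    }
  })
})

test_that("scale invariance: integer rescaling of one sample moves its factor by c", {
  withr::with_seed(51, {
    cnt <- toy_counts(rnbinom(100 * 4, mu = 80, size = 10) + 1L, 100, samples4)
  })
  for (fn in list(size_factors_upper_quartile, size_factors_median_of_ratios)) {
    base <- fn(cnt)
    scaled <- cnt
    scaled$i1 <- scaled$i1 * 3L
    f <- fn(scaled)
    ratio_base <- base$size_factor[1] / base$size_factor[2]
    ratio_scaled <- f$size_factor[1] / f$size_factor[2]
    expect_equal(ratio_scaled / ratio_base, 3)
  }
})

test_that("the suite's scorers coincide when the normalizations coincide", {
  # equal-depth, no-zero data: UQ and MOR factors are all 1, so their
  # p-values agree gene by gene
  withr::with_seed(61, {
    base <- rnbinom(200, mu = 100, size = 10) + 1L
    cnt <- toy_counts(rep(base, 4), 200, samples4)
  })
  lengths <- tibble::tibble(gene_id = cnt$gene_id, length = 1000L)
  de <- run_de_suite(cnt, meta4, lengths)
  uq <- de[de$method_id == "UQ", ]
  mor <- de[de$method_id == "MOR", ]
  expect_equal(uq$pvalue, mor$pvalue)
  expect_equal(uq$padj, mor$padj)
})

test_that("each scorer has power on planted signal at study-like settings", {
  cfg <- simulation_config(n_genes = 1500, fraction_de = 0.05,
                           lfc_magnitude = 2, dispersion = 0.1, seed = 71)
  sim <- simulate_counts(cfg)
  de <- run_de_suite(sim$counts, sim$metadata, sim$lengths)
  planted <- sim$truth$gene_id[sim$truth$is_de]
  filtered <- threshold_filter(de)
  for (m in c("UQ", "MOR", "FPKM")) {
    hits <- filtered$gene_id[filtered$method_id == m]
    expect_gte(mean(planted %in% hits), 0.7)
  }
})
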