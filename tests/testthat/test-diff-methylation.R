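make_nb_counts <- function(n_windows, n_per_group, mu, phi, seed,
                           lib_factors = NULL) {
  set.seed(seed)
  n <- 2L * n_per_group
  if (is.null(lib_factors)) lib_factors <- rep(1, n)
  mu_w <- mu * exp(rnorm(n_windows, 0, 0.4))  # window-to-window abundance
  m <- outer(mu_w, lib_factors)
  counts <- matrix(as.integer(
    if (phi == 0) rpois(length(m), m) else
      rnbinom(length(m), mu = m, size = 1 / phi)),
    n_windows, n)
  counts_fixture(counts)
}

test_that("TMM: identical columns give unit factors with geometric mean 1", {
  counts <- matrix(rep(c(5L, 20L, 100L, 7L, 15L, 60L), 4), ncol = 4)
  cm <- counts_fixture(counts)
  f <- tmm_factors(cm)
  expect_equal(unname(unclass(f)[1:4]), rep(1, 4), tolerance = 1e-12)
  expect_lt(abs(exp(mean(log(f))) - 1), 1e-9)
})

test_that("TMM compensates a pure library-size scaling", {
  set.seed(1)
  col <- as.integer(rnbinom(2000, mu = 40, size = 20)) + 1L
  counts <- unname(cbind(col * 2L, col, col, col))  # sample 1: same
  cm <- counts_fixture(counts)  # composition, doubled sequencing effort
  f <- tmm_factors(cm)
  eff <- attr(f, "effective_lib_sizes")
  # the doubling lands entirely in the effective library size ...
  expect_lt(abs(eff[1] / eff[2] - 2), 1e-6)
  # ... so normalized means agree across samples
  norm_means <- colMeans(sweep(cm$counts, 2, mean(eff) / eff, `*`))
  expect_lt(abs(norm_means[1] / mean(norm_means[-1]) - 1), 1e-6)
})

test_that("TMM factors are invariant to a global count rescaling", {
  cm <- make_nb_counts(500, 2, mu = 30, phi = 0.1, seed = 2)
  cm10 <- medip_counts(cm$windows, cm$counts * 10L, cm$design)
  expect_equal(unclass(tmm_factors(cm))[seq_len(4)],
               unclass(tmm_factors(cm10))[seq_len(4)], tolerance = 1e-10)
})

test_that("TMM factors agree with the reference edgeR implementation", {
  skip_if_not_installed("edgeR")
  cm <- make_nb_counts(3000, 3, mu = 35, phi = 0.1, seed = 3,
                       lib_factors = c(0.7, 1, 1.3, 0.9, 1.1, 1.5))
  f <- unclass(tmm_factors(cm))[seq_len(6)]
  ref <- edgeR::calcNormFactors(cm$counts, lib.size = cm$library_sizes,
                                method = "TMM")
  expect_equal(unname(f), unname(ref), tolerance = 0.02)
})

test_that("common dispersion is recovered from simulated data", {
  cm <- make_nb_counts(4000, 10, mu = 30, phi = 0.1, seed = 4)
  est <- estimate_common_dispersion(cm, tmm_factors(cm))
  expect_gte(est$phi, 0.05)
  expect_lte(est$phi, 0.2)

  cm0 <- make_nb_counts(4000, 10, mu = 30, phi = 0, seed = 5)
  est0 <- estimate_common_dispersion(cm0, tmm_factors(cm0))
  expect_lte(est0$phi, 0.02)
})

test_that("dispersion estimation survives an all-zero group", {
  counts <- cbind(matrix(0L, 50, 3),
                  matrix(as.integer(rpois(150, 20)), 50, 3))
  colnames(counts) <- sprintf("s%d", 1:6)
  cm <- counts_fixture(counts, groups = rep(c("case", "control"), each = 3))
  est <- estimate_common_dispersion(cm)
  expect_true(is.finite(est$phi))
  expect_gte(est$phi, 0)
})

test_that("dispersion estimate tracks the edgeR qCML estimator", {
  skip_if_not_installed("edgeR")
  cm <- make_nb_counts(3000, 5, mu = 30, phi = 0.2, seed = 6)
  est <- estimate_common_dispersion(cm)
  d <- edgeR::DGEList(counts = cm$counts, group = cm$design$group)
  d <- edgeR::estimateCommonDisp(d)
  expect_equal(est$phi, d$common.dispersion, tolerance = 0.05)
})

test_that("exact test: balanced identical group sums give p = 1", {
  expect_equal(nb_exact_pvalue(12, 12, 3, 3, 0.1), 1)
  expect_equal(nb_exact_pvalue(0, 0, 2, 2, 0.3), 1)
})

test_that("exact test p values match brute-force enumeration on a grid", {
  # spot grid here; the exhaustive y1+y2 <= 40 sweep runs in acceptance
  for (phi in c(0, 0.1, 0.5)) {
    for (s in c(1, 7, 19)) {
      for (y1 in 0:s) {
        expect_equal(nb_exact_pvalue(y1, s - y1, 2, 2, phi),
                     oracle_nb_exact_p(y1, s - y1, 2, 2, phi),
                     tolerance = 1e-12,
                     label = sprintf("p(y1=%d, s=%d, phi=%g)", y1, s, phi))
      }
    }
  }
  # unbalanced designs too
  for (y1 in c(0, 3, 11)) {
    expect_equal(nb_exact_pvalue(y1, 14 - y1, 3, 5, 0.2),
                 oracle_nb_exact_p(y1, 14 - y1, 3, 5, 0.2),
                 tolerance = 1e-12)
  }
})

test_that("exact test converges to the conditional binomial as phi -> 0", {
  for (y1 in c(0, 4, 9, 15)) {
    y2 <- 20 - y1
    ref <- binom.test(y1, 20, 2 / 5)$p.value  # n1=2 of 5 samples
    expect_equal(nb_exact_pvalue(y1, y2, 2, 3, 1e-8), ref,
                 tolerance = 1e-6)
  }
})

test_that("exact test p is monotone in the imbalance at fixed total", {
  for (phi in c(0, 0.2)) {
    s <- 30
    p <- vapply(0:s, function(y1) nb_exact_pvalue(y1, s - y1, 4, 4, phi),
                numeric(1))
    dev <- abs((0:s) - s / 2)
    expect_true(all(diff(p[order(dev)]) <= 1e-12))
  }
})

test_that("swapping group labels negates log2fc and preserves p", {
  cm <- make_nb_counts(300, 3, mu = 40, phi = 0.1, seed = 7)
  f <- tmm_factors(cm)
  t1 <- exact_test(cm, f, 0.1, contrast = c("case", "control"))
  t2 <- exact_test(cm, f, 0.1, contrast = c("control", "case"))
  expect_equal(t1$p_value, t2$p_value)
  expect_equal(t1$log2fc, -t2$log2fc)
})

test_that("window-level results agree with edgeR's small-p exact test", {
  skip_if_not_installed("edgeR")
  set.seed(8)
  counts <- matrix(as.integer(rnbinom(400 * 6, mu = 30, size = 10)), 400, 6)
  cm <- counts_fixture(counts)
  lib <- cm$library_sizes
  # equalize library sizes exactly so both routes see the same pseudodata
  cm_eq <- medip_counts(cm$windows, cm$counts, cm$design,
                        library_sizes = setNames(rep(mean(lib), 6),
                                                 colnames(cm$counts)))
  mine <- exact_test(cm_eq, NULL, phi = 0.1,
                     contrast = c("case", "control"))
  d <- edgeR::DGEList(counts = cm$counts[, c(1, 3, 5, 2, 4, 6)],
                      group = rep(c("case", "control"), each = 3),
                      lib.size = rep(mean(lib), 6))
  d$common.dispersion <- 0.1
  ref <- edgeR::exactTest(d, pair = c("control", "case"),
                          rejection.region = "smallp")$table$PValue
  expect_equal(mine$p_value, ref, tolerance = 1e-6)
})

test_that("BH adjustment follows the step-up formula and its invariants", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(9)
  p <- runif(200)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  perm <- sample(200)
  expect_equal(bh_fdr(p[perm]), adj[perm])
  expect_error(bh_fdr(c(0.5, 0)), "p values")
  expect_error(bh_fdr(c(0.5, 1.2)), "p values")
})

test_that("s = 0 windows report p = 1 and log2fc = 0", {
  counts <- rbind(c(0L, 0L, 0L, 0L), c(30L, 35L, 28L, 33L))
  cm <- counts_fixture(counts)
  res <- exact_test(cm, NULL, 0.1, contrast = c("case", "control"))
  expect_equal(res$p_value[1], 1)
  expect_equal(res$log2fc[1], 0)
})
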