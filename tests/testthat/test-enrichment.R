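# The window-level mixture model: densities, EM fitting, z-scores, and
# FDR-based selection of enriched regions.

test_that("the unbound density matches direct evaluation", {
  # equal frequencies, sigma = 0: v = 1/100 + 1/100, exponent vanishes
  expect_equal(prob_unbound(100, 100, 1e4, 1e4, sigma = 0, mu = 0),
               1 / sqrt(0.04 * pi))
  # exponent vanishes whenever the log ratio equals mu
  expect_equal(prob_unbound(200, 100, 2e4, 1e4, sigma = 0.3, mu = 0),
               1 / sqrt(2 * pi * (2 * 0.09 + 1 / 200 + 1 / 100)))
  # ten-fold enrichment at sigma = 0.5
  v <- 2 * 0.25 + 1 / 100 + 1 / 10
  expect_equal(prob_unbound(100, 10, 1e6, 1e6, sigma = 0.5, mu = 0),
               (1 / sqrt(2 * pi * v)) * exp(-log(10)^2 / (2 * v)))
  expect_error(prob_unbound(0, 10, 100, 100, 0, 0), "positive")
})

test_that("the bound density is the reciprocal delta range, constant across windows", {
  expect_equal(prob_bound(-0.001, 0.001), 500)
  expect_equal(prob_bound(0, 1), 1)
  expect_error(prob_bound(0.5, 0.5), "degenerate")
})

test_that("z-scores standardize the unbound exponent", {
  fit <- manual_fit(rho = 0.9, sigma = 0.5, mu = 0.25, delta_min = -1,
                    delta_max = 1, N = 1e6, M = 1e6, pseudocount = 0)
  counts <- tibble::tibble(n = c(100, 128), m = c(10, 100))
  sc <- window_zscores(counts, fit)
  expect_equal(sc$z[1], (log(10) - 0.25) / sqrt(0.61))
  # a window whose log ratio equals mu scores exactly zero
  fit0 <- manual_fit(0.9, 0.5, mu = 0, -1, 1, 1e6, 1e6, pseudocount = 0)
  sc0 <- window_zscores(tibble::tibble(n = 50, m = 50), fit0)
  expect_equal(sc0$z, 0)
  # strictly increasing in n at fixed m
  ns <- tibble::tibble(n = c(10, 20, 40, 80), m = 20)
  expect_true(all(diff(window_zscores(ns, fit0)$z) > 0))
})

test_that("z is antisymmetric under sample swap with mu negated", {
  set.seed(4)
  for (i in 1:25) {
    n <- sample(1:500, 1); m <- sample(1:500, 1)
    mu <- rnorm(1, 0, 0.3); sigma <- runif(1, 0, 1)
    fit_f <- manual_fit(0.9, sigma, mu, -1, 1, N = 1e5, M = 2e5,
                        pseudocount = 0)
    fit_r <- manual_fit(0.9, sigma, -mu, -1, 1, N = 2e5, M = 1e5,
                        pseudocount = 0)
    n0 <- n; m0 <- m
    zf <- window_zscores(tibble::tibble(n = n0, m = m0), fit_f)$z
    zr <- window_zscores(tibble::tibble(n = m0, m = n0), fit_r)$z
    expect_equal(zf, -zr)
  }
})

test_that("on null data rho stays near one and nothing passes FDR selection", {
  # the uniform component's density is set by the observed delta range, so
  # on a pure null it softly absorbs a few tail windows: rho converges
  # near, not exactly at, the boundary, and the posterior-based FDR keeps
  # the selection empty
  set.seed(21)
  fx <- generate_fixture(n_peaks = 0, genome_length = 60000,
                         sigma_shared = 0, seed = 21)
  w <- make_windows(c(chrF = fx$params$genome_length), strands = "+")
  cc <- count_windows(w, fx$fg, fx$bg)
  fit <- em_fit(cc)
  expect_gte(fit$rho, 0.95)
  expect_true(all(diff(fit$loglik_trace) >= -1e-6))
  sc <- window_zscores(cc, fit)
  expect_true(all(sc$posterior_unbound >= 0 & sc$posterior_unbound <= 1))
  # at most the single most extreme null window can slip past the FDR rule
  # (it is the window that defines the delta range)
  expect_lte(nrow(select_enriched(sc, fdr = 0.1)), 1)
})

test_that("EM requires a minimum number of windows", {
  cc <- tibble::tibble(n = c(5, 6), m = c(5, 6))
  expect_error(em_fit(cc, totals = c(N = 100, M = 100)), "at least 10")
})

test_that("FDR selection follows the cumulative posterior mean", {
  base <- tibble::tibble(
    chrom = "chrA", start = c(0L, 600L, 1200L), end = c(300L, 900L, 1500L),
    strand = "+", n = 0, m = 0,
    z = c(9, 7, 5), posterior_unbound = c(0.01, 0.02, 0.50)
  )
  sel <- select_enriched(base, fdr = 0.1)
  # top-2 mean 0.015 <= 0.1 but adding the third gives 0.177
  expect_equal(attr(sel, "z_threshold"), 7)
  expect_equal(nrow(attr(sel, "windows")), 2)
  expect_equal(nrow(sel), 2)

  # all-zero posteriors: every window above the hard z floor is selected
  all0 <- dplyr::mutate(base, posterior_unbound = 0, z = c(9, 2.5, 1))
  sel0 <- select_enriched(all0, fdr = 0.1)
  expect_equal(nrow(attr(sel0, "windows")), 2) # z = 1 fails z > 2

  # nothing passes a tiny fdr when posteriors are positive
  none <- dplyr::mutate(base, posterior_unbound = c(0.5, 0.6, 0.7))
  seln <- select_enriched(none, fdr = 0.01)
  expect_equal(nrow(seln), 0)
  expect_equal(attr(seln, "z_threshold"), Inf)
})

test_that("overlapping selected windows merge into contiguous stranded regions", {
  sc <- tibble::tibble(
    chrom = "chrA",
    start = c(0L, 150L, 300L, 900L, 0L),
    end = c(300L, 450L, 600L, 1200L, 300L),
    strand = c("+", "+", "+", "+", "-"),
    n = 0, m = 0,
    z = c(10, 9, 8, 7, 6), posterior_unbound = 0
  )
  sel <- select_enriched(sc, fdr = 0.1)
  plus <- sel[sel$strand == "+", ]
  expect_equal(nrow(sel), 3)
  expect_equal(sort(plus$start), c(0L, 900L))
  expect_equal(sort(plus$end), c(600L, 1200L))
  expect_equal(sel$n_windows[sel$start == 0 & sel$strand == "+"], 3L)
})

test_that("tidy and glance expose the fitted parameters", {
  set.seed(5)
  fx <- generate_fixture(n_peaks = 0, genome_length = 30000,
                         sigma_shared = 0, seed = 5)
  w <- make_windows(c(chrF = fx$params$genome_length), strands = "+")
  fit <- em_fit(count_windows(w, fx$fg, fx$bg))
  td <- generics::tidy(fit)
  expect_equal(td$term, c("rho", "sigma", "mu", "delta_min", "delta_max"))
  expect_equal(td$estimate[1], fit$rho)
  gl <- generics::glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_windows, fit$n_windows)
})
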