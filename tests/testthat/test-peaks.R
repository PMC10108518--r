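# Coverage profiles and Gaussian-mixture peak deconvolution.

region <- function(start, end, chrom = "chrA", strand = "+") {
  list(chrom = chrom, start = start, end = end, strand = strand)
}

test_that("coverage and read-start profiles count weighted fragments per base", {
  reads <- make_reads("chrA", c(0, 5, 10), c(10, 15, 12),
                      read_start = c(10 - 1, 10, 11))
  # use fragments [0,10), [5,15) for depth checks
  prof <- coverage_profile(region(0, 20), reads[1:2, ])
  expect_equal(prof$depth[prof$position == 7], 2)
  expect_equal(prof$depth[prof$position == 12], 1)
  # read starts {9, 10}: one each
  expect_equal(prof$read_starts[prof$position %in% c(9, 10)], c(1, 1))
  # conservation: total depth equals total overlap length
  expect_equal(sum(prof$depth), sum(pmin(reads$end[1:2], 20) -
                                      pmax(reads$start[1:2], 0)))
  # read-start mass equals weight of records starting inside the region
  prof2 <- coverage_profile(region(0, 20), reads)
  expect_equal(sum(prof2$read_starts), 3)
})

test_that("a single concentrated cluster is recovered as one dominant peak", {
  set.seed(2)
  mids <- rnorm(500, 150, 10)
  fit <- fit_peak_mixture(region(0, 300), mids, fragment_size = 10,
                          restarts = 8, seed = 2)
  expect_equal(fit$K_max, 30)
  top <- fit$peaks[1, ]
  expect_lt(abs(top$center - 150), 2)
  expect_lt(abs(top$width - 10), 3)
  expect_gt(top$n_peak / sum(fit$weights), 0.8)
})

test_that("two well-separated clusters are both recovered", {
  set.seed(3)
  mids <- c(rnorm(300, 80, 8), rnorm(300, 220, 8))
  fit <- fit_peak_mixture(region(0, 300), mids, fragment_size = 30,
                          seed = 3)
  top2 <- sort(fit$peaks$center[1:2])
  expect_lt(abs(top2[1] - 80), 3)
  expect_lt(abs(top2[2] - 220), 3)
})

test_that("K_max is the region length over the fragment size and widths are clamped", {
  fit <- fit_peak_mixture(region(0, 300), c(100, 150, 200),
                          fragment_size = 10, restarts = 2, seed = 1)
  expect_equal(fit$K_max, 30)
  expect_true(all(fit$peaks$width >= 10 / 4 - 1e-9))
  expect_true(all(fit$peaks$width <= 150 + 1e-9))
})

test_that("fewer than two fragments give a single peak of width fragment_size/2", {
  fit <- fit_peak_mixture(region(0, 300), 120, fragment_size = 40)
  expect_equal(nrow(fit$peaks), 1)
  expect_equal(fit$peaks$center, 120)
  expect_equal(fit$peaks$width, 20)
})

test_that("no returned peak pair violates the half-overlap rule", {
  set.seed(9)
  for (rep in 1:5) {
    mids <- c(rnorm(200, 120, 15), rnorm(200, 160, 15), runif(50, 0, 400))
    fit <- fit_peak_mixture(region(0, 400), mids, fragment_size = 50,
                            seed = rep)
    bad <- overlap_violations(fit$peaks$center, fit$peaks$width)
    expect_equal(nrow(bad), 0)
  }
})

test_that("peak fitting is deterministic under a fixed seed", {
  mids <- c(rnorm(150, 100, 12), rnorm(150, 260, 9))
  f1 <- fit_peak_mixture(region(0, 400), mids, fragment_size = 60, seed = 5)
  f2 <- fit_peak_mixture(region(0, 400), mids, fragment_size = 60, seed = 5)
  expect_equal(f1$peaks, f2$peaks)
  expect_equal(f1$loglik, f2$loglik)
})

test_that("peak scoring recomputes z from assigned counts and thresholds them", {
  set.seed(12)
  mids <- rnorm(400, 150, 10)
  fit <- fit_peak_mixture(region(0, 300), mids, fragment_size = 50, seed = 1)
  em <- manual_fit(0.95, sigma = 0.1, mu = 0, delta_min = -0.01,
                   delta_max = 0.05, N = 1e4, M = 1e4, pseudocount = 0.5)
  bg_sparse <- make_reads("chrA", seq(0, 280, by = 40), seq(20, 300, by = 40))
  scored_all <- score_peaks(fit, em, bg_sparse, z_threshold = -Inf)
  expect_true(all(diff(scored_all$z) <= 0))
  # n_peak/N matching m_peak/M * e^mu scores ~0 and is dropped by z > 0
  expect_equal(nrow(score_peaks(fit, em, bg_sparse, z_threshold = 1e9)), 0)
  # lowering the threshold never removes a peak
  hi <- score_peaks(fit, em, bg_sparse, z_threshold = 5)
  lo <- score_peaks(fit, em, bg_sparse, z_threshold = 2)
  expect_true(all(hi$center %in% lo$center))
  # background fragments inside the span are counted with their weights
  expect_true(all(scored_all$m_peak <= sum(bg_sparse$weight)))
})

test_that("tidy/glance summarize a peak fit", {
  fit <- fit_peak_mixture(region(0, 300), rnorm(100, 150, 10),
                          fragment_size = 60, seed = 8)
  td <- generics::tidy(fit)
  expect_true(all(c("chrom", "strand", "center", "width", "n_peak") %in%
                    names(td)))
  gl <- generics::glance(fit)
  expect_equal(gl$K_max, 5)
  expect_equal(gl$n_fragments, 100)
})
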