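# CLIP-experiment simulation and the planted-peak fixture generator.

test_that("with no readthrough every read starts one base past the crosslink", {
  cfg <- sim_config(n_sites = 1, n_molecules_per_site = 300,
                    rho_readthrough = 0, seed = 8)
  sim <- simulate_clip(cfg)
  xl <- sim$sites$crosslink
  expect_true(all(sim$reads$read_start == xl + 1))
  expect_equal(sim$sites$modal_read_start - 1L, xl)
  # conservation: one read per molecule
  expect_equal(nrow(sim$reads), 300)
})

test_that("with full readthrough read starts reproduce the fragment 5' ends", {
  cfg <- sim_config(n_sites = 1, n_molecules_per_site = 2000,
                    rho_readthrough = 1, seed = 9)
  sim <- simulate_clip(cfg)
  # direct draw of the fragment-start distribution with the same geometry
  set.seed(1009)
  mc <- sim$sites$motif_center
  direct <- mc - cfg$protection_halfwidth -
    rgeom(2000, 1 / (1 + cfg$overhang_mean))
  d_stat <- suppressWarnings(
    ks.test(sim$reads$read_start, direct)$statistic
  )
  expect_lt(unname(d_stat), 0.06)
})

test_that("the crosslink beats the coverage center at low readthrough and matches it at high", {
  lo <- distance_summary(simulate_clip(sim_config(rho_readthrough = 0.1,
                                                  seed = 15)))
  hi <- distance_summary(simulate_clip(sim_config(rho_readthrough = 0.9,
                                                  seed = 15)))
  expect_lte(mean(abs(lo$d_crosslink)), mean(abs(lo$d_center)))
  expect_lte(mean(abs(lo$d_crosslink)), mean(abs(hi$d_crosslink)) + 1)
})

test_that("the center-to-crosslink distance shrinks as readthrough grows", {
  mean_dist <- function(rho, seed) {
    s <- simulate_clip(sim_config(n_sites = 3, n_molecules_per_site = 800,
                                  rho_readthrough = rho, seed = seed))
    mean(abs(s$sites$gaussian_center - s$sites$crosslink))
  }
  for (seed in 1:5) {
    d <- vapply(c(0, 0.5, 1), mean_dist, numeric(1), seed = seed)
    expect_true(all(diff(d) <= 0))
  }
})

test_that("upstream and downstream crosslink modes flip the distance sign", {
  up <- distance_summary(simulate_clip(sim_config(
    crosslink_offset_mode = "upstream", rho_readthrough = 0.1, seed = 4
  )))
  dn <- distance_summary(simulate_clip(sim_config(
    crosslink_offset_mode = "downstream", rho_readthrough = 0.1, seed = 4
  )))
  expect_lt(median(up$d_crosslink), 0)
  expect_gt(median(dn$d_crosslink), 0)
})

test_that("simulation output is deterministic under a fixed seed and carries the motif", {
  s1 <- simulate_clip(sim_config(seed = 33, bg_rate = 0.01))
  s2 <- simulate_clip(sim_config(seed = 33, bg_rate = 0.01))
  expect_equal(s1$reads, s2$reads)
  expect_equal(s1$sites, s2$sites)
  for (i in seq_len(nrow(s1$sites))) {
    got <- substr(s1$genome, s1$sites$motif_start[i] + 1,
                  s1$sites$motif_start[i] + 6)
    expect_equal(unname(got), "TGCATG")
  }
  expect_true(all(s1$reads$end <= nchar(s1$genome)))
})

test_that("moment matching recovers center and width of simple profiles", {
  tri <- tibble::tibble(position = 140:160,
                        depth = 10 - abs(140:160 - 150))
  g <- fit_gaussian_to_coverage(tri)
  expect_equal(unname(g["center"]), 150)

  two <- tibble::tibble(position = c(10, 20), depth = c(1, 1))
  g2 <- fit_gaussian_to_coverage(two)
  expect_equal(unname(g2["center"]), 15)
  expect_equal(unname(g2["width"]), 5)

  shifted <- dplyr::mutate(tri, position = position + 7)
  expect_equal(unname(fit_gaussian_to_coverage(shifted)["center"]), 157)

  expect_error(fit_gaussian_to_coverage(
    tibble::tibble(position = 1:3, depth = 0)
  ), "all-zero")
})

test_that("fixtures are reproducible and geometrically valid", {
  f1 <- generate_fixture(n_peaks = 3, genome_length = 15000, seed = 19)
  f2 <- generate_fixture(n_peaks = 3, genome_length = 15000, seed = 19)
  expect_equal(f1$fg, f2$fg)
  expect_equal(f1$truth, f2$truth)
  expect_equal(nrow(f1$truth), 3)
  expect_true(all(f1$fg$end <= f1$params$genome_length))
  expect_true(all(f1$fg$start >= 0))
  expect_equal(unname(f1$totals["N"]),
               f1$params$fg_depth * f1$params$genome_length)
  # planted positions sit at distinct block centers
  expect_equal(anyDuplicated(f1$truth$position %/% 300), 0)
})

test_that("the fixture's window counts recover the planted depletion offset", {
  fx <- generate_fixture(n_peaks = 0, genome_length = 300000,
                         mu_offset = -0.25, sigma_noise = 0.15, seed = 27)
  w <- make_windows(c(chrF = fx$params$genome_length), 300, 300,
                    strands = "+")
  cc <- count_windows(w, fx$fg, fx$bg, totals = fx$totals)
  fit <- em_fit(cc)
  expect_lt(abs(fit$mu - (-0.25)), 0.05)
  expect_lt(abs(fit$sigma - 0.15), 0.05)
})
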