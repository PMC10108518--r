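# PWM handling, posterior scanning, enrichment, trimming, similarity.

test_that("information content covers the uniform, deterministic and half-half cases", {
  expect_equal(information_content(c(0.25, 0.25, 0.25, 0.25)), 0)
  expect_equal(information_content(c(1, 0, 0, 0)), 2)
  expect_equal(information_content(c(0.5, 0.5, 0, 0)), 1)
  m <- pwm(cbind(c(1, 0, 0, 0), c(0.25, 0.25, 0.25, 0.25)))
  expect_equal(information_content(m), c(2, 0))
})

test_that("trimming removes low-information boundaries only", {
  lowc <- c(0.3, 0.3, 0.2, 0.2)   # ~0.03 bits
  hic <- c(0.9, 0.05, 0.03, 0.02) # ~1.4 bits
  m <- pwm(cbind(lowc, hic, hic, lowc))
  tr <- trim_pwm(m)
  expect_equal(ncol(tr), 2)
  expect_true(all(information_content(tr) >= 0.5))

  # already-informative motifs are untouched
  m2 <- pwm(cbind(hic, hic, hic))
  expect_equal(ncol(trim_pwm(m2)), 3)

  # an interior low-information column is never removed
  m3 <- pwm(cbind(hic, lowc, hic))
  expect_equal(ncol(trim_pwm(m3)), 3)

  # all-low motifs collapse to the single best column, with a warning
  m4 <- pwm(cbind(lowc, lowc))
  expect_warning(tr4 <- trim_pwm(m4), "threshold")
  expect_equal(ncol(tr4), 1)
})

test_that("posterior scanning reproduces the mixture arithmetic", {
  uni <- pwm(matrix(0.25, 4, 3))
  hits <- scan_posteriors("ACGTACG", uni, prior = 0.3)
  expect_equal(nrow(hits), 5)
  expect_equal(hits$posterior, rep(0.3, 5)) # likelihood ratio 1 everywhere

  # single-column A motif on "A": the 1e-3 floor gives L_w = 1/1.003
  a_only <- pwm(matrix(c(1, 0, 0, 0), 4, 1,
                       dimnames = list(c("A", "C", "G", "T"), NULL)))
  post <- scan_posteriors("A", a_only, prior = 0.5)$posterior
  lw <- 1 / 1.003
  expect_equal(post, 0.5 * lw / (0.5 * lw + 0.5 * 0.25))
  expect_equal(post, 0.7996, tolerance = 2e-4)

  # posterior is strictly increasing in the prior
  p_lo <- scan_posteriors("ACGTA", uni, prior = 0.2)$posterior
  p_hi <- scan_posteriors("ACGTA", uni, prior = 0.4)$posterior
  expect_true(all(p_hi > p_lo))

  # U equals T, N contributes a factor of one to both likelihoods
  t_only <- pwm(matrix(c(0, 0, 0, 1), 4, 1,
                       dimnames = list(c("A", "C", "G", "T"), NULL)))
  expect_equal(scan_posteriors("U", t_only, 0.5)$posterior,
               scan_posteriors("T", t_only, 0.5)$posterior)
  expect_equal(scan_posteriors("N", t_only, 0.5)$posterior, 0.5)
  expect_error(scan_posteriors("AXG", t_only, 0.5), "non-ACGTUN")
})

test_that("posterior calibration: mean posterior tracks the planted prior", {
  set.seed(6)
  m <- consensus_pwm("TGCATG", major = 0.85)
  prior <- 0.2
  seqs <- vapply(1:800, function(i) {
    if (runif(1) < prior) {
      paste(vapply(1:6, function(j) {
        sample(BASES, 1, prob = unclass(m)[, j])
      }, character(1)), collapse = "")
    } else paste(sample(BASES, 6, TRUE), collapse = "")
  }, character(1))
  posts <- vapply(seqs, function(s) {
    scan_posteriors(s, m, prior = prior)$posterior[1]
  }, numeric(1))
  expect_lt(abs(mean(posts) - prior), 0.05)
})

test_that("motif similarity has exact boundary values and matches the worked example", {
  m2col <- pwm(cbind(c(1, 0, 0, 0), c(0, 1, 0, 0)))
  expect_identical(motif_similarity(m2col, m2col), 1)
  a1 <- pwm(matrix(c(1, 0, 0, 0), 4))
  c1 <- pwm(matrix(c(0, 1, 0, 0), 4))
  expect_identical(motif_similarity(a1, c1), 0)
  # m1 = [A, C], m2 = [C]: S12 = 1 (offset aligning the C columns),
  # S11 = 2, S22 = 1 -> M = 2/3
  expect_equal(motif_similarity(m2col, c1), 2 / 3)
  expect_equal(motif_similarity(c1, m2col), 2 / 3)
})

test_that("similarity is symmetric, bounded, and agrees with the brute-force oracle", {
  set.seed(17)
  for (i in 1:30) {
    m1 <- random_pwm(sample(1:8, 1))
    m2 <- random_pwm(sample(1:8, 1))
    s12 <- motif_similarity(m1, m2)
    expect_equal(s12, motif_similarity(m2, m1))
    expect_gte(s12, 0)
    expect_lte(s12, 1)
    expect_equal(s12, oracle_motif_similarity(m1, m2), tolerance = 1e-12)
  }
})

test_that("cross-validated enrichment is ~1 on null data and high with planted sites", {
  set.seed(23)
  fg0 <- random_seqs(120, 41)
  bg0 <- random_seqs(240, 41)
  weak <- consensus_pwm("TGCATG", major = 0.55)
  null_e <- motif_enrichment(fg0, bg0, weak, seed = 23)
  expect_equal(null_e$runs, 5L) # default
  expect_gt(null_e$mean_enrichment, 0.7)
  expect_lt(null_e$mean_enrichment, 1.4)

  sharp <- consensus_pwm("TGCATG", major = 0.85)
  fg1 <- plant_consensus(random_seqs(120, 41), "TGCATG")
  planted <- motif_enrichment(fg1, bg0, sharp, seed = 23)
  expect_gt(planted$mean_enrichment, 2)
  expect_gte(planted$sd_enrichment, 0)
})

test_that("background sequences come from the lowest-z windows", {
  genome <- setNames(paste(rep("ACGT", 500), collapse = ""), "chrA")
  sc <- tibble::tibble(
    chrom = "chrA", start = seq(0L, 1800L, by = 200L),
    end = seq(200L, 2000L, by = 200L), strand = "+",
    z = seq(-3, 6, length.out = 10)
  )
  bgs <- background_sequences(sc, genome, n_fg_sites = 5, n_per_site = 4,
                              size = 40, pool_frac = 0.2, seed = 3)
  expect_length(bgs, 20)
  expect_true(all(nchar(bgs) == 40))
})

test_that("PWMs round-trip through TRANSFAC-style text", {
  m1 <- consensus_pwm("TGCA", major = 0.7, name = "mA")
  m2 <- random_pwm(3)
  path <- withr::local_tempfile(fileext = ".mat")
  write_pwms(list(m1, m2), path)
  back <- read_pwms(path)
  expect_length(back, 2)
  expect_equal(unclass(back[["mA"]]), unclass(m1), tolerance = 1e-5)
  expect_equal(attr(back[[1]], "name"), "mA")
  # count matrices are normalized on read
  counts <- withr::local_tempfile(fileext = ".mat")
  writeLines(c("NA cnt", "PO A C G T", "01 8 1 1 0", "02 0 0 0 10", "//"),
             counts)
  pc <- read_pwms(counts)[[1]]
  expect_equal(unname(colSums(unclass(pc))), c(1, 1))
  expect_equal(unname(unclass(pc)[1, 1]), 0.8)
})
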