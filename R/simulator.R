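# Simulation of a CLIP experiment: an RBP binds its cognate motif,
# crosslinks to a nearby nucleotide, protects a region from RNase
# digestion, and the reverse transcriptase either truncates at the
# crosslink (producing read 5' ends piling up one base downstream of it)
# or reads through to the fragment end. Also provides the planted-peak
# fixture generator used to test the inference modules end to end.

#' Simulation configuration
#'
#' Defaults describe a generic eCLIP-like experiment: a 30-nt protected
#' footprint (`protection_halfwidth` 15), RNase digestion leaving
#' geometric overhangs of mean 15 nt beyond the protected region (fragments
#' mostly 30-90 nt), reads long enough to span the cDNA, and a deterministic
#' crosslink site whose placement relative to the motif is set by
#' `crosslink_offset_mode`: 3 nt before the motif start (`upstream`), the
#' motif center (`within`), or 3 nt past the motif end (`downstream`).
#' `crosslink_offset_sd` adds optional spread.
#'
#' @param genome_length Simulated chromosome length (nt).
#' @param motif_consensus Planted motif (ACGT string).
#' @param n_sites Number of binding sites.
#' @param n_molecules_per_site Crosslinked molecules per site.
#' @param crosslink_offset_mode `"upstream"`, `"within"`, or
#'   `"downstream"`.
#' @param crosslink_offset_sd SD of the crosslink position around its modal
#'   nucleotide (default 0: a single crosslinked nucleotide).
#' @param protection_halfwidth Protected half-width around the motif center
#'   (nt).
#' @param overhang_mean Mean of the geometric digestion overhang beyond the
#'   protected region (nt).
#' @param rho_readthrough Probability the reverse transcriptase reads
#'   through the crosslink instead of truncating.
#' @param bg_rate Background fragments per nucleotide (default 0).
#' @param read_length Maximum read length (nt).
#' @param seed Seed for full reproducibility.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 20000L,
                       motif_consensus = "TGCATG",
                       n_sites = 5L,
                       n_molecules_per_site = 2000L,
                       crosslink_offset_mode = c("within", "upstream",
                                                 "downstream"),
                       crosslink_offset_sd = 0,
                       protection_halfwidth = 15L,
                       overhang_mean = 15,
                       rho_readthrough = 0.1,
                       bg_rate = 0,
                       read_length = 100L,
                       seed = 1L) {
  crosslink_offset_mode <- match.arg(crosslink_offset_mode)
  stopifnot(
    rho_readthrough >= 0, rho_readthrough <= 1,
    genome_length > nchar(motif_consensus),
    n_sites >= 1, n_molecules_per_site >= 1, protection_halfwidth >= 1,
    overhang_mean > 0, bg_rate >= 0, read_length >= 1
  )
  structure(
    list(
      genome_length = as.integer(genome_length),
      motif_consensus = toupper(chartr("U", "T", motif_consensus)),
      n_sites = as.integer(n_sites),
      n_molecules_per_site = as.integer(n_molecules_per_site),
      crosslink_offset_mode = crosslink_offset_mode,
      crosslink_offset_sd = crosslink_offset_sd,
      protection_halfwidth = as.integer(protection_halfwidth),
      overhang_mean = overhang_mean,
      rho_readthrough = rho_readthrough,
      bg_rate = bg_rate,
      read_length = as.integer(read_length),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Modal crosslink position for a site, relative to the motif.
crosslink_anchor <- function(cfg, motif_start) {
  len <- nchar(cfg$motif_consensus)
  switch(cfg$crosslink_offset_mode,
    upstream = motif_start - 3L,
    within = motif_start + len %/% 2L,
    downstream = motif_start + len + 2L
  )
}

#' Simulate a CLIP experiment
#'
#' Binding sites carrying the motif consensus are planted at regular
#' intervals on a random plus-strand chromosome. Per molecule, the
#' crosslink position is drawn around the mode set by the offset
#' configuration; the protected fragment spans the motif center +/-
#' `protection_halfwidth` extended by geometric digestion overhangs and
#' clipped to contain the crosslink. With probability `1 - rho_readthrough`
#' the cDNA is truncated so the read 5' end sits one base downstream of the
#' crosslinked nucleotide; otherwise the read starts at the fragment 5'
#' end. Per site, the modal read start and a moment-matched Gaussian center
#' of the read coverage are recorded.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `clip_sim`: `reads` (fragment-table tibble,
#'   background included), `sites` (per-site truth: motif and crosslink
#'   positions, `modal_read_start`, `gaussian_center`, `gaussian_width`),
#'   `genome` (named character), `config`.
#' @export
simulate_clip <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$genome_length
  motif_len <- nchar(cfg$motif_consensus)
  margin <- cfg$protection_halfwidth + ceiling(10 * cfg$overhang_mean) +
    cfg$read_length
  if (L < 2 * margin + cfg$n_sites * motif_len) {
    abort("genome too short for the requested sites and fragment geometry")
  }
  motif_starts <- as.integer(round(seq(margin, L - margin,
                                       length.out = cfg$n_sites)))
  genome_chars <- sample(PWM_BASES, L, replace = TRUE)
  for (s in motif_starts) {
    genome_chars[(s + 1):(s + motif_len)] <-
      strsplit(cfg$motif_consensus, "")[[1]]
  }
  genome <- setNames(paste(genome_chars, collapse = ""), "chrS")

  p_geom <- 1 / (1 + cfg$overhang_mean)
  site_reads <- purrr::map(seq_len(cfg$n_sites), function(i) {
    mc <- motif_starts[i] + motif_len %/% 2L
    n_mol <- cfg$n_molecules_per_site
    xl_mode <- crosslink_anchor(cfg, motif_starts[i])
    xl <- if (cfg$crosslink_offset_sd > 0) {
      as.integer(round(rnorm(n_mol, xl_mode, cfg$crosslink_offset_sd)))
    } else rep(xl_mode, n_mol)
    u <- rgeom(n_mol, p_geom)
    v <- rgeom(n_mol, p_geom)
    frag_start <- pmin(mc - cfg$protection_halfwidth - u, xl)
    frag_end <- pmax(mc + cfg$protection_halfwidth + v + 1L, xl + 2L)
    frag_start <- pmax(frag_start, 0L)
    frag_end <- pmin(frag_end, L)
    if (any(xl < 0 | xl + 1L >= L)) {
      abort("crosslink position falls outside the genome; enlarge it")
    }
    readthrough <- runif(n_mol) < cfg$rho_readthrough
    cdna_start <- ifelse(readthrough, frag_start, xl + 1L)
    cdna_end <- pmin(frag_end, cdna_start + cfg$read_length)
    tibble(
      chrom = "chrS",
      start = as.integer(cdna_start),
      end = as.integer(cdna_end),
      strand = "+",
      read_start = as.integer(cdna_start),
      weight = 1,
      name = sprintf("site%d_mol%d", i, seq_len(n_mol)),
      site = i,
      crosslink = xl
    )
  })
  reads <- purrr::list_rbind(site_reads)

  n_bg <- rpois(1, cfg$bg_rate * L)
  if (n_bg > 0) {
    u <- rgeom(n_bg, p_geom)
    v <- rgeom(n_bg, p_geom)
    flen <- 2L * cfg$protection_halfwidth + u + v + 1L
    bstart <- floor(runif(n_bg, 0, pmax(1, L - flen)))
    bg_reads <- tibble(
      chrom = "chrS",
      start = as.integer(bstart),
      end = as.integer(pmin(bstart + flen, L)),
      strand = "+",
      read_start = as.integer(bstart),
      weight = 1,
      name = sprintf("bg_mol%d", seq_len(n_bg)),
      site = NA_integer_,
      crosslink = NA_integer_
    )
    reads <- bind_rows(reads, bg_reads)
  }

  sites <- purrr::map(seq_len(cfg$n_sites), function(i) {
    rr <- site_reads[[i]]
    prof <- coverage_profile(
      list(chrom = "chrS", start = min(rr$start), end = max(rr$end),
           strand = "+"),
      rr[, READ_COLS]
    )
    gfit <- fit_gaussian_to_coverage(prof)
    start_counts <- table(rr$read_start)
    modal <- as.integer(names(start_counts)[which.max(start_counts)])
    tibble(
      site = i,
      motif_start = motif_starts[i],
      motif_center = motif_starts[i] + motif_len %/% 2L,
      crosslink = crosslink_anchor(cfg, motif_starts[i]),
      modal_read_start = modal,
      gaussian_center = gfit[["center"]],
      gaussian_width = gfit[["width"]]
    )
  }) |> purrr::list_rbind()

  structure(
    list(reads = reads, sites = sites, genome = genome, config = cfg),
    class = "clip_sim"
  )
}

#' @export
print.clip_sim <- function(x, ...) {
  cat(sprintf(
    "CLIP simulation: %d site(s) x %d molecules, rho_readthrough = %.2f (%s crosslink)\n",
    x$config$n_sites, x$config$n_molecules_per_site,
    x$config$rho_readthrough, x$config$crosslink_offset_mode
  ))
  print(x$sites)
  invisible(x)
}

#' Moment-matched Gaussian fit to a coverage profile
#'
#' Center = coverage-weighted mean position, width = coverage-weighted
#' standard deviation.
#'
#' @param profile A `clip_coverage` (or any data frame with `position` and
#'   `depth`).
#' @return Named numeric vector `c(center =, width =)`.
#' @export
fit_gaussian_to_coverage <- function(profile) {
  w <- profile$depth
  if (sum(w) <= 0) abort("all-zero coverage profile")
  center <- sum(w * profile$position) / sum(w)
  width <- sqrt(sum(w * (profile$position - center)^2) / sum(w))
  c(center = center, width = width)
}

#' Per-site distances of crosslink and coverage-center estimates from the
#' motif
#'
#' For each simulated site, `d_crosslink` is the modal read start minus the
#' motif center and `d_center` the Gaussian coverage center minus the motif
#' center. Histogram these over sites to see which anchor localizes the
#' motif.
#'
#' @param result A `clip_sim`.
#' @return A tibble with `site`, `d_crosslink`, `d_center`.
#' @export
distance_summary <- function(result) {
  stopifnot(inherits(result, "clip_sim"))
  result$sites |>
    transmute(
      site,
      d_crosslink = modal_read_start - motif_center,
      d_center = gaussian_center - motif_center
    )
}

#' Generate a planted-peak fixture for the enrichment pipeline
#'
#' Emulates the data structure the window model assumes. The chromosome is
#' divided into `block_size`-nt expression blocks; each block's base rate
#' carries a log-normal expression factor shared between foreground and
#' background (`sigma_shared`, cancels in the frequency ratio) and
#' independent per-sample multiplicative noise `exp(N(0, sigma_noise))`
#' (the model's sigma). Foreground block rates are additionally depleted by
#' `exp(mu_offset)` relative to the nominal library sizes reported in
#' `totals` (`fg_depth * genome_length`, `bg_depth * genome_length`).
#' Foreground-only fragment clusters of `peak_reads` fragments with
#' `Normal(position, peak_sd)` midpoints are planted at `n_peaks` random
#' block centers.
#'
#' @param n_peaks Number of planted peaks.
#' @param genome_length Chromosome length (nt).
#' @param fg_depth,bg_depth Background fragment rates per nucleotide in
#'   each sample.
#' @param peak_sd Positional spread (sd, nt) of planted peak fragments.
#' @param sigma_noise Per-sample multiplicative noise scale.
#' @param mu_offset Systematic log depletion of unbound foreground windows.
#' @param sigma_shared Shared expression-heterogeneity scale (default 0.5).
#' @param peak_reads Fragments per planted peak (default 400).
#' @param fragment_length Fragment length (nt, default 60).
#' @param block_size Expression-block / window size (default 300).
#' @param seed Seed.
#' @return A list of class `clip_fixture`: `fg`, `bg` (read tibbles),
#'   `truth` (planted positions), `totals` (nominal `N`, `M`), `params`.
#' @export
generate_fixture <- function(n_peaks = 5L,
                             genome_length = 30000L,
                             fg_depth = 0.2,
                             bg_depth = 0.2,
                             peak_sd = 10,
                             sigma_noise = 0.1,
                             mu_offset = -0.1,
                             sigma_shared = 0.5,
                             peak_reads = 400L,
                             fragment_length = 60L,
                             block_size = 300L,
                             seed = 1L) {
  stopifnot(n_peaks >= 0, genome_length >= 2 * block_size,
            fg_depth > 0, bg_depth > 0, peak_sd > 0, fragment_length >= 2)
  set.seed(seed)
  L <- as.integer(genome_length)
  n_blocks <- L %/% block_size
  L <- n_blocks * as.integer(block_size) # trim to whole blocks

  shared <- exp(rnorm(n_blocks, 0, sigma_shared))
  eps_fg <- exp(rnorm(n_blocks, 0, sigma_noise))
  eps_bg <- exp(rnorm(n_blocks, 0, sigma_noise))
  lam_fg <- fg_depth * block_size * shared * eps_fg * exp(mu_offset)
  lam_bg <- bg_depth * block_size * shared * eps_bg

  scatter <- function(lambda, prefix) {
    counts <- rpois(n_blocks, lambda)
    block <- rep.int(seq_len(n_blocks) - 1L, counts)
    mids <- block * block_size + floor(runif(sum(counts), 0, block_size))
    half <- fragment_length %/% 2L
    start <- pmax(0L, as.integer(mids - half))
    end <- pmin(L, as.integer(mids + half))
    tibble(
      chrom = "chrF", start = start, end = end, strand = "+",
      read_start = start, weight = 1,
      name = sprintf("%s_%d", prefix, seq_along(start))
    )
  }
  fg <- scatter(lam_fg, "fgb")
  bg <- scatter(lam_bg, "bg")

  truth <- tibble(peak = integer(0), position = integer(0))
  if (n_peaks > 0) {
    usable <- seq_len(n_blocks)
    if (n_peaks > length(usable)) abort("more peaks than blocks")
    blocks <- sort(sample(usable, n_peaks))
    positions <- as.integer((blocks - 1L) * block_size + block_size %/% 2L)
    half <- fragment_length %/% 2L
    peak_rows <- purrr::map(seq_len(n_peaks), function(i) {
      mids <- as.integer(round(rnorm(peak_reads, positions[i], peak_sd)))
      start <- pmax(0L, mids - half)
      end <- pmin(L, mids + half)
      ok <- end - start >= 2L
      tibble(
        chrom = "chrF", start = start[ok], end = end[ok], strand = "+",
        read_start = start[ok], weight = 1,
        name = sprintf("fgp%d_%d", i, seq_len(sum(ok)))
      )
    })
    fg <- bind_rows(fg, purrr::list_rbind(peak_rows))
    truth <- tibble(peak = seq_len(n_peaks), position = positions)
  }

  structure(
    list(
      fg = fg, bg = bg, truth = truth,
      totals = c(N = fg_depth * L, M = bg_depth * L),
      params = list(
        n_peaks = n_peaks, genome_length = L, fg_depth = fg_depth,
        bg_depth = bg_depth, peak_sd = peak_sd, sigma_noise = sigma_noise,
        mu_offset = mu_offset, sigma_shared = sigma_shared,
        peak_reads = peak_reads, fragment_length = fragment_length,
        block_size = as.integer(block_size), seed = seed
      )
    ),
    class = "clip_fixture"
  )
}

#' @export
print.clip_fixture <- function(x, ...) {
  cat(sprintf(
    "Planted-peak fixture: %d peak(s) on %d nt, %d fg / %d bg fragments\n",
    x$params$n_peaks, x$params$genome_length, nrow(x$fg), nrow(x$bg)
  ))
  invisible(x)
}
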