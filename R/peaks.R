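# Peak deconvolution: within each enriched region, a mixture of K Gaussians
# plus a uniform noise component is fitted to the weighted foreground
# fragment midpoints by EM. Peaks whose spans (center +/- 2 sd) overlap by
# more than half of the smaller span are pruned (least significant first)
# and EM continues; the best-likelihood configuration over 2*K_max random
# restarts is kept.

#' Per-nucleotide coverage and read-start profile of a region
#'
#' `depth[i]` is the summed weight of same-strand fragments covering
#' nucleotide `i`; `read_starts[i]` the summed weight of records whose
#' `read_start` equals `i`. Used for display, crosslink anchoring, and
#' peak-fit initialization.
#'
#' @param region A one-row data frame (or list) with `chrom`, `start`,
#'   `end`, `strand`.
#' @param reads Read-record tibble (one sample).
#' @return A tibble with `position`, `depth`, `read_starts`; class
#'   `clip_coverage`, with the region stored in attributes.
#' @export
coverage_profile <- function(region, reads) {
  validate_reads(reads)
  len <- region$end - region$start
  stopifnot(len > 0)
  rr <- filter(reads, chrom == region$chrom, strand == region$strand,
               end > region$start, start < region$end)
  depth <- numeric(len + 1)
  if (nrow(rr) > 0) {
    s <- pmax(rr$start, region$start) - region$start + 1L
    e <- pmin(rr$end, region$end) - region$start
    for (i in seq_len(nrow(rr))) {
      depth[s[i]] <- depth[s[i]] + rr$weight[i]
      depth[e[i] + 1L] <- depth[e[i] + 1L] - rr$weight[i]
    }
    depth <- cumsum(depth)
  }
  starts <- numeric(len)
  in_region <- rr$read_start >= region$start & rr$read_start < region$end
  if (any(in_region)) {
    sums <- rowsum(rr$weight[in_region],
                   rr$read_start[in_region] - region$start + 1L)
    starts[as.integer(rownames(sums))] <- sums[, 1]
  }
  out <- tibble(
    position = seq.int(region$start, region$end - 1L),
    depth = depth[seq_len(len)],
    read_starts = starts
  )
  attr(out, "region") <- as.list(region)[c("chrom", "start", "end", "strand")]
  class(out) <- c("clip_coverage", class(out))
  out
}

#' Fit a Gaussian mixture of binding peaks to fragment midpoints
#'
#' The maximum number of peaks in a region is the region length divided by
#' the fragment size (`K_max`). Each restart initializes `K_max` components
#' (the first at the highest local maxima of the 5-nt-smoothed midpoint
#' histogram, later ones at randomly sampled midpoints), runs EM to
#' convergence, then repeatedly applies the overlap rule: if two peak spans
#' (center +/- 2 sd) overlap by more than half of the smaller span, the peak
#' with less assigned fragment mass is removed and EM continues. The
#' configuration with the maximum likelihood over `2 * K_max` restarts is
#' returned. Widths are clamped to `[fragment_size/4, region_length/2]`.
#'
#' @param region One-row data frame/list with `chrom`, `start`, `end`,
#'   `strand`.
#' @param midpoints Fragment midpoint positions (genomic coordinates).
#' @param weights Fragment weights (recycled; default 1).
#' @param fragment_size Expected fragment size in nucleotides.
#' @param restarts Number of EM restarts (default `2 * K_max`).
#' @param noise_weight Initial weight of the uniform noise component
#'   (default 0.1).
#' @param tol,max_iter EM convergence controls.
#' @param seed Optional seed for restart initialization.
#' @return A `clip_peak_fit`: peaks tibble (`center`, `width`, `weight`,
#'   `n_peak`) ordered by decreasing fragment mass, plus `noise_weight`,
#'   `loglik`, `K_max`.
#' @export
fit_peak_mixture <- function(region, midpoints, weights = 1, fragment_size,
                             restarts = NULL, noise_weight = 0.1,
                             tol = 1e-6, max_iter = 100L, seed = NULL) {
  stopifnot(fragment_size >= 1, length(midpoints) >= 1)
  len <- region$end - region$start
  weights <- rep_len(weights, length(midpoints))
  k_max <- max(1L, floor(len / fragment_size))
  restarts <- restarts %||% (2L * k_max)

  if (length(midpoints) < 2) {
    peaks <- tibble(
      peak_id = 1L, center = as.numeric(midpoints[1]),
      width = fragment_size / 2, weight = 1, n_peak = sum(weights)
    )
    return(new_peak_fit(peaks, 0, NA_real_, k_max, region, midpoints,
                        weights, fragment_size))
  }

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }

  width_lo <- fragment_size / 4
  width_hi <- len / 2
  hist_centers <- smoothed_maxima(midpoints, weights, region, k_max)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- if (r == 1) hist_centers else
      sample(midpoints, k_max, replace = TRUE, prob = weights) +
        runif(k_max, -fragment_size / 2, fragment_size / 2)
    cfg <- list(
      centers = as.numeric(centers),
      widths = rep(fragment_size, length(centers)),
      pi = rep((1 - noise_weight) / length(centers), length(centers)),
      pi_noise = noise_weight
    )
    cfg <- run_em_with_pruning(cfg, midpoints, weights, region,
                               width_lo, width_hi, tol, max_iter)
    if (is.null(best) || cfg$loglik > best$loglik) best <- cfg
  }

  w_total <- sum(weights)
  resp <- component_responsibilities(best, midpoints, region)
  n_peak <- as.numeric(weights %*% resp$gauss)
  ord <- order(n_peak, decreasing = TRUE)
  peaks <- tibble(
    peak_id = seq_along(ord),
    center = best$centers[ord],
    width = best$widths[ord],
    weight = best$pi[ord],
    n_peak = n_peak[ord]
  )
  new_peak_fit(peaks, best$pi_noise, best$loglik, k_max, region,
               midpoints, weights, fragment_size)
}

new_peak_fit <- function(peaks, noise_weight, loglik, k_max, region,
                         midpoints, weights, fragment_size) {
  structure(
    list(
      peaks = peaks, noise_weight = noise_weight, loglik = loglik,
      K_max = k_max,
      region = as.list(region)[c("chrom", "start", "end", "strand")],
      midpoints = midpoints, weights = weights,
      fragment_size = fragment_size
    ),
    class = "clip_peak_fit"
  )
}

#' @export
print.clip_peak_fit <- function(x, ...) {
  cat(sprintf("Peak mixture fit: %s:%d-%d(%s), %d peak(s), K_max = %d\n",
              x$region$chrom, x$region$start, x$region$end, x$region$strand,
              nrow(x$peaks), x$K_max))
  print(x$peaks)
  invisible(x)
}

smoothed_maxima <- function(midpoints, weights, region, k) {
  len <- region$end - region$start
  counts <- numeric(len)
  idx <- pmin(pmax(round(midpoints) - region$start + 1L, 1L), len)
  sums <- rowsum(rep_len(weights, length(idx)), idx)
  counts[as.integer(rownames(sums))] <- sums[, 1]
  sm <- as.numeric(stats::filter(counts, rep(1 / 5, 5), sides = 2))
  sm[is.na(sm)] <- 0
  is_max <- sm >= dplyr::lag(sm, default = -Inf) &
    sm >= dplyr::lead(sm, default = -Inf) & sm > 0
  cand <- which(is_max)
  cand <- cand[order(sm[cand], decreasing = TRUE)]
  centers <- (cand[seq_len(min(k, length(cand)))] - 1L) + region$start
  if (length(centers) < k) {
    extra <- sample(midpoints, k - length(centers), replace = TRUE)
    centers <- c(centers, extra)
  }
  as.numeric(centers)
}

# E-step densities for the current configuration.
component_densities <- function(cfg, midpoints, region) {
  len <- region$end - region$start
  k <- length(cfg$centers)
  dens <- matrix(0, length(midpoints), k)
  for (j in seq_len(k)) {
    dens[, j] <- dnorm(midpoints, cfg$centers[j], cfg$widths[j])
  }
  list(gauss = dens, noise = rep(1 / len, length(midpoints)))
}

component_responsibilities <- function(cfg, midpoints, region) {
  d <- component_densities(cfg, midpoints, region)
  num <- sweep(d$gauss, 2, cfg$pi, `*`)
  noise <- cfg$pi_noise * d$noise
  tot <- rowSums(num) + noise
  tot[tot <= 0] <- .Machine$double.xmin
  list(gauss = num / tot, noise = noise / tot, mix = tot)
}

run_em_once <- function(cfg, midpoints, weights, region,
                        width_lo, width_hi, tol, max_iter) {
  w_total <- sum(weights)
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    r <- component_responsibilities(cfg, midpoints, region)
    ll <- sum(weights * base::log(r$mix))
    wr <- r$gauss * weights
    mass <- colSums(wr)
    # drop numerically dead components
    alive <- mass > 1e-9 * w_total
    if (!all(alive)) {
      cfg$centers <- cfg$centers[alive]
      cfg$widths <- cfg$widths[alive]
      cfg$pi <- cfg$pi[alive]
      if (length(cfg$centers) == 0) break
      renorm <- sum(cfg$pi) + cfg$pi_noise
      cfg$pi <- cfg$pi / renorm
      cfg$pi_noise <- cfg$pi_noise / renorm
      next
    }
    cfg$centers <- colSums(wr * midpoints) / mass
    cfg$widths <- pmin(pmax(sqrt(
      colSums(wr * outer(midpoints, cfg$centers, `-`)^2) / mass
    ), width_lo), width_hi)
    cfg$pi <- mass / w_total
    cfg$pi_noise <- sum(weights * r$noise) / w_total
    if (abs(ll - ll_prev) < tol) break
    ll_prev <- ll
  }
  r <- component_responsibilities(cfg, midpoints, region)
  cfg$loglik <- sum(weights * base::log(r$mix))
  cfg$mass <- colSums(r$gauss * weights)
  cfg
}

# Half-overlap rule on spans center +/- 2*width: returns index pairs that
# overlap by more than half of the smaller span.
overlap_violations <- function(centers, widths) {
  k <- length(centers)
  if (k < 2) return(matrix(integer(0), ncol = 2))
  lo <- centers - 2 * widths
  hi <- centers + 2 * widths
  out <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      ov <- min(hi[i], hi[j]) - max(lo[i], lo[j])
      if (ov > 0.5 * min(hi[i] - lo[i], hi[j] - lo[j])) {
        out[[length(out) + 1]] <- c(i, j)
      }
    }
  }
  do.call(rbind, out) %||% matrix(integer(0), ncol = 2)
}

run_em_with_pruning <- function(cfg, midpoints, weights, region,
                                width_lo, width_hi, tol, max_iter) {
  repeat {
    cfg <- run_em_once(cfg, midpoints, weights, region,
                       width_lo, width_hi, tol, max_iter)
    if (length(cfg$centers) == 0) {
      cfg$loglik <- -Inf
      return(cfg)
    }
    bad <- overlap_violations(cfg$centers, cfg$widths)
    if (nrow(bad) == 0) return(cfg)
    involved <- unique(as.integer(bad))
    drop <- involved[which.min(cfg$mass[involved])]
    keep <- setdiff(seq_along(cfg$centers), drop)
    cfg$centers <- cfg$centers[keep]
    cfg$widths <- cfg$widths[keep]
    cfg$pi <- cfg$pi[keep]
    renorm <- sum(cfg$pi) + cfg$pi_noise
    cfg$pi <- cfg$pi / renorm
    cfg$pi_noise <- cfg$pi_noise / renorm
    if (length(cfg$centers) == 0) {
      cfg$loglik <- -Inf
      return(cfg)
    }
  }
}

#' Recalculate peak z-scores and keep significant peaks
#'
#' Each peak's foreground count `n_peak` is the responsibility-weighted
#' fragment mass assigned to its Gaussian component; the background count
#' `m_peak` is the weighted background fragment mass with midpoint inside
#' the peak span (center +/- 2 sd). The window-level z formula is then
#' applied to `(n_peak, N, m_peak, M)` with the fitted `mu` and `sigma`,
#' and peaks with `z >= z_threshold` are kept.
#'
#' @param peak_fit A `clip_peak_fit`.
#' @param em A `clip_em_fit` (provides `mu`, `sigma`, pseudocount and
#'   default totals).
#' @param bg Background read-record tibble (the whole sample or the
#'   region's slice; same-strand records with midpoints in each span are
#'   counted).
#' @param z_threshold Minimum z (use the FDR-derived threshold from
#'   [select_enriched()]).
#' @param totals Optional `c(N =, M =)` override.
#' @return Peaks tibble with `m_peak` and `z` columns, significant peaks
#'   only, ordered by decreasing z.
#' @export
score_peaks <- function(peak_fit, em, bg, z_threshold, totals = NULL) {
  stopifnot(inherits(peak_fit, "clip_peak_fit"), inherits(em, "clip_em_fit"))
  validate_reads(bg, "bg")
  totals <- totals %||% c(N = em$N, M = em$M)
  region <- peak_fit$region
  bg_rr <- filter(bg, chrom == region$chrom, strand == region$strand)
  bg_mid <- fragment_midpoint(bg_rr$start, bg_rr$end)
  peaks <- peak_fit$peaks
  if (nrow(peaks) == 0) return(mutate(peaks, m_peak = double(), z = double()))
  peaks$m_peak <- purrr::map_dbl(seq_len(nrow(peaks)), function(i) {
    lo <- peaks$center[i] - 2 * peaks$width[i]
    hi <- peaks$center[i] + 2 * peaks$width[i]
    sum(bg_rr$weight[bg_mid >= lo & bg_mid <= hi])
  })
  pc <- em$pseudocount
  np <- peaks$n_peak + pc
  mp <- peaks$m_peak + pc
  v <- 2 * em$sigma^2 + 1 / np + 1 / mp
  x <- base::log(np / totals[["N"]]) - base::log(mp / totals[["M"]])
  peaks$z <- (x - em$mu) / sqrt(v)
  peaks |>
    filter(z >= z_threshold) |>
    arrange(desc(z)) |>
    mutate(peak_id = dplyr::row_number())
}

#' Call peaks across all enriched regions
#'
#' Convenience wrapper running [fit_peak_mixture()] and [score_peaks()] for
#' every region from [select_enriched()].
#'
#' @param regions Region tibble from [select_enriched()] (its
#'   `z_threshold` attribute is used unless overridden).
#' @param fg,bg Read-record tibbles.
#' @param em A `clip_em_fit`.
#' @param fragment_size Expected fragment size (nt).
#' @param z_threshold Override of the FDR-derived threshold.
#' @param seed Optional seed (each region derives its own sub-seed).
#' @return A tibble of significant peaks with region coordinates attached,
#'   ordered by decreasing z.
#' @export
call_peaks <- function(regions, fg, bg, em, fragment_size,
                       z_threshold = NULL, seed = NULL) {
  z_threshold <- z_threshold %||% attr(regions, "z_threshold") %||% 2
  if (nrow(regions) == 0) {
    return(tibble(
      chrom = character(), strand = character(), region_id = integer(),
      peak_id = integer(), center = double(), width = double(),
      weight = double(), n_peak = double(), m_peak = double(), z = double()
    ))
  }
  validate_reads(fg, "fg")
  out <- purrr::map(seq_len(nrow(regions)), function(i) {
    region <- regions[i, ]
    rr <- filter(fg, chrom == region$chrom, strand == region$strand,
                 end > region$start, start < region$end)
    mids <- fragment_midpoint(rr$start, rr$end)
    inside <- mids >= region$start & mids < region$end
    if (!any(inside)) return(NULL)
    fit <- fit_peak_mixture(
      region, mids[inside], rr$weight[inside], fragment_size,
      seed = if (!is.null(seed)) derive_seed(seed, i) else NULL
    )
    scored <- score_peaks(fit, em, bg, z_threshold)
    if (nrow(scored) == 0) return(NULL)
    mutate(scored,
           chrom = region$chrom, strand = region$strand,
           region_id = region$region_id, .before = 1)
  })
  peaks <- purrr::list_rbind(purrr::compact(out))
  if (nrow(peaks) > 0) peaks <- arrange(peaks, desc(z))
  peaks
}
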