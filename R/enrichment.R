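# Window-level enrichment: a two-component mixture over window read counts.
#
# Unbound windows: the foreground read frequency n/N tracks the background
# frequency m/M up to multiplicative sample-preparation noise (variance
# 2*sigma^2 on the log scale), Poisson sampling noise (variances 1/n and
# 1/m), and a systematic depletion offset mu of unbound regions in the IP.
# Bound windows: a uniform density over the observed range of the frequency
# difference delta = n/N - m/M. The mixture weight rho of the unbound
# component, sigma and mu are fitted by expectation-maximization.
#
# The two component formulas are densities over different variables (the
# log ratio x and the frequency difference delta); to mix them they are
# both expressed as densities over the observed count n via the Jacobians
# dx/dn = 1/n and ddelta/dn = 1/N. The E-step therefore weighs
# rho * P_u(x)/n against (1 - rho) * P_b/N; without these factors the
# uniform component dominates every window whenever read frequencies are
# small and the fit degenerates.

#' Unbound-window density
#'
#' Density of the log frequency ratio for a window without protein binding:
#' a Gaussian in `log(n/N) - log(m/M)` with mean `mu` and variance
#' `2*sigma^2 + 1/n + 1/m` (multiplicative noise in the two samples plus
#' Poisson terms). Natural logarithms throughout. Counts must be positive;
#' the fitting routines apply a half-unit pseudocount before calling this.
#'
#' @param n,m Weighted window counts in foreground and background
#'   (vectorized, must be positive).
#' @param N,M Total weighted reads in each sample.
#' @param sigma Multiplicative-noise scale (>= 0).
#' @param mu Systematic foreground-depletion offset (log scale).
#' @param log Return log densities?
#' @return Density values, one per window.
#' @export
prob_unbound <- function(n, m, N, M, sigma, mu, log = FALSE) {
  if (any(n <= 0) || any(m <= 0)) {
    abort("prob_unbound requires positive counts (apply a pseudocount first)")
  }
  stopifnot(N > 0, M > 0, sigma >= 0)
  v <- 2 * sigma^2 + 1 / n + 1 / m
  x <- base::log(n / N) - base::log(m / M)
  dnorm(x, mean = mu, sd = sqrt(v), log = log)
}

#' Bound-window density
#'
#' Uniform density over the observed range of the read-frequency difference
#' `delta = n/N - m/M` across all windows: `1 / (delta_max - delta_min)`,
#' independent of the individual window.
#'
#' @param delta_min,delta_max Range of `delta` over all windows.
#' @return A single density value.
#' @export
prob_bound <- function(delta_min, delta_max) {
  if (!(delta_max > delta_min)) {
    abort("degenerate delta range: delta_max must exceed delta_min")
  }
  1 / (delta_max - delta_min)
}

#' Fit the enrichment mixture by expectation-maximization
#'
#' The E-step computes, per window, the posterior probability of the unbound
#' component; the M-step sets `rho` to the mean posterior and maximizes the
#' posterior-weighted Gaussian log-likelihood over `(mu, sigma)` numerically
#' (no closed form, because the variance depends on `sigma`). Iteration
#' stops when the total data log-likelihood changes by less than `tol`.
#'
#' @param counts Window-count tibble from [count_windows()] (columns `n`,
#'   `m`; totals in attributes or via `totals`).
#' @param totals Optional `c(N = , M = )` override.
#' @param init Optional `c(rho = , sigma = , mu = )` starting point; by
#'   default `rho = 0.9`, `mu` the median log ratio, `sigma` the MAD of the
#'   log ratios.
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_iter Maximum EM iterations (default 200).
#' @param pseudocount Added to `n` and `m` before any log or variance term
#'   (default 0.5, a half-integer continuity correction applied identically
#'   to both samples).
#' @return An object of class `clip_em_fit` with elements `rho`, `sigma`,
#'   `mu`, `delta_min`, `delta_max`, `loglik`, `loglik_trace`, `converged`.
#'   [generics::tidy()] and [generics::glance()] methods are provided.
#' @export
em_fit <- function(counts, totals = NULL, init = NULL, tol = 1e-6,
                   max_iter = 200L, pseudocount = 0.5) {
  d <- window_model_data(counts, totals, pseudocount)
  if (length(d$x) < 10) {
    abort("em_fit needs at least 10 windows with counts")
  }
  p_b <- prob_bound(d$delta_min, d$delta_max)

  rho <- unname(init["rho"] %|na|% 0.9)
  mu <- unname(init["mu"] %|na|% median(d$x))
  sigma <- unname(init["sigma"] %|na|% min(mad(d$x), 10))

  weighted_nll <- function(par, post) {
    v <- 2 * par[2]^2 + d$v_base
    -sum(post * dnorm(d$x, par[1], sqrt(v), log = TRUE))
  }

  # count-space (log) densities: Jacobians 1/n for the Gaussian component,
  # 1/N for the uniform component (see header comment)
  log_pb_n <- base::log(p_b) - base::log(d$N)

  trace <- numeric(0)
  converged <- FALSE
  ll_prev <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E-step
    log_pu_n <- dnorm(d$x, mu, sqrt(2 * sigma^2 + d$v_base), log = TRUE) -
      base::log(d$np)
    hi <- pmax(log_pu_n + base::log(rho), log_pb_n + base::log(1 - rho))
    ll_i <- hi + base::log(
      exp(log_pu_n + base::log(rho) - hi) +
        exp(log_pb_n + base::log(1 - rho) - hi)
    )
    ll <- sum(ll_i)
    trace <- c(trace, ll)
    post <- exp(log_pu_n + base::log(rho) - ll_i)
    if (abs(ll - ll_prev) < tol || iter >= max_iter) {
      converged <- abs(ll - ll_prev) < tol
      break
    }
    ll_prev <- ll
    # M-step
    rho <- min(max(mean(post), 1e-9), 1 - 1e-9)
    opt <- optim(
      c(mu, sigma), weighted_nll, post = post,
      method = "L-BFGS-B", lower = c(-Inf, 0), upper = c(Inf, 10)
    )
    if (opt$value <= weighted_nll(c(mu, sigma), post)) {
      mu <- opt$par[1]
      sigma <- opt$par[2]
    }
  }
  if (!converged) {
    warn(sprintf("EM did not converge within %d iterations", max_iter))
  }

  structure(
    list(
      rho = rho, sigma = sigma, mu = mu,
      delta_min = d$delta_min, delta_max = d$delta_max,
      N = d$N, M = d$M, pseudocount = pseudocount,
      loglik = trace[length(trace)], loglik_trace = trace,
      iterations = iter, converged = converged, n_windows = length(d$x)
    ),
    class = "clip_em_fit"
  )
}

`%|na|%` <- function(x, default) {
  if (is.null(x) || length(x) == 0 || is.na(x)) default else x
}

window_model_data <- function(counts, totals = NULL, pseudocount = 0.5) {
  if (!all(c("n", "m") %in% names(counts))) {
    abort("`counts` must have columns `n` and `m` (see count_windows())")
  }
  N <- if (!is.null(totals)) unname(totals["N"]) else attr(counts, "N")
  M <- if (!is.null(totals)) unname(totals["M"]) else attr(counts, "M")
  if (is.null(N) || is.null(M)) {
    abort("totals N and M not found; pass `totals = c(N =, M =)`")
  }
  np <- counts$n + pseudocount
  mp <- counts$m + pseudocount
  delta <- np / N - mp / M
  list(
    x = base::log(np / N) - base::log(mp / M),
    v_base = 1 / np + 1 / mp,
    np = np,
    delta_min = min(delta), delta_max = max(delta),
    N = N, M = M
  )
}

#' @export
print.clip_em_fit <- function(x, ...) {
  cat("Enrichment mixture fit (EM)\n")
  cat(sprintf("  windows: %d   log-likelihood: %.3f   %s in %d iterations\n",
              x$n_windows, x$loglik,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat(sprintf("  rho = %.4f   sigma = %.4f   mu = %.4f\n",
              x$rho, x$sigma, x$mu))
  cat(sprintf("  delta range: [%.3g, %.3g]\n", x$delta_min, x$delta_max))
  invisible(x)
}

#' Score windows with enrichment z-scores and posteriors
#'
#' The z-score standardizes the exponent of the unbound density:
#' `z = (log(n/N) - log(m/M) - mu) / sqrt(2*sigma^2 + 1/n + 1/m)`, with the
#' same pseudocount as the fit. The posterior probability of the unbound
#' component is the E-step value at the fitted parameters.
#'
#' @param counts Window-count tibble.
#' @param fit A `clip_em_fit`.
#' @param totals Optional totals override (defaults to those of the fit).
#' @return `counts` with columns `z` and `posterior_unbound` added.
#' @export
window_zscores <- function(counts, fit, totals = NULL) {
  stopifnot(inherits(fit, "clip_em_fit"))
  totals <- totals %||% c(N = fit$N, M = fit$M)
  d <- window_model_data(counts, totals, fit$pseudocount)
  v <- 2 * fit$sigma^2 + d$v_base
  # count-space densities, as in the E-step of em_fit
  log_pu_n <- dnorm(d$x, fit$mu, sqrt(v), log = TRUE) - base::log(d$np)
  log_pb_n <- base::log(prob_bound(fit$delta_min, fit$delta_max)) -
    base::log(d$N)
  odds <- base::log(fit$rho) + log_pu_n -
    base::log(1 - fit$rho) - log_pb_n
  counts |>
    mutate(
      z = (d$x - fit$mu) / sqrt(v),
      posterior_unbound = 1 / (1 + exp(-odds))
    )
}

#' Select significantly enriched windows and merge them into regions
#'
#' Windows are ranked by decreasing z-score; the false discovery rate of the
#' top-k set is the mean posterior probability of the unbound component
#' among those k windows. The z-threshold is the z of the largest k whose
#' FDR stays at or below `fdr`; selected windows must additionally exceed
#' `z_min` (default 2). Overlapping selected windows on the same strand are
#' merged into maximal contiguous regions for peak fitting.
#'
#' @param scores Output of [window_zscores()].
#' @param fdr Target false discovery rate (default 0.1).
#' @param z_min Hard z-score floor (default 2).
#' @return A tibble of merged regions (`chrom`, `start`, `end`, `strand`,
#'   `region_id`, `n_windows`, `max_z`) with attributes `z_threshold` and
#'   `windows` (the selected windows). Empty when nothing passes.
#' @export
select_enriched <- function(scores, fdr = 0.1, z_min = 2) {
  stopifnot(fdr > 0, fdr < 1 || fdr == 1)
  if (!all(c("z", "posterior_unbound") %in% names(scores))) {
    abort("`scores` must come from window_zscores()")
  }
  ranked <- arrange(scores, desc(z))
  cum_fdr <- cumsum(ranked$posterior_unbound) / seq_len(nrow(ranked))
  passing <- which(cum_fdr <= fdr)
  empty <- tibble(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), region_id = integer(),
    n_windows = integer(), max_z = double()
  )
  if (length(passing) == 0) {
    attr(empty, "z_threshold") <- Inf
    attr(empty, "windows") <- ranked[0, ]
    return(empty)
  }
  k <- max(passing)
  z_threshold <- ranked$z[k]
  selected <- filter(ranked, z >= z_threshold, z > z_min)
  if (nrow(selected) == 0) {
    attr(empty, "z_threshold") <- z_threshold
    attr(empty, "windows") <- selected
    return(empty)
  }
  gr <- intervals_to_granges(selected)
  merged <- GenomicRanges::reduce(gr, ignore.strand = FALSE)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  per_region <- tibble(
    region = S4Vectors::subjectHits(hits),
    z = selected$z[S4Vectors::queryHits(hits)]
  ) |>
    group_by(.data$region) |>
    summarise(n_windows = dplyr::n(), max_z = max(z))
  regions <- granges_to_intervals(merged) |>
    mutate(
      region_id = dplyr::row_number(),
      n_windows = per_region$n_windows[match(region_id, per_region$region)],
      max_z = per_region$max_z[match(region_id, per_region$region)]
    ) |>
    arrange(desc(max_z))
  attr(regions, "z_threshold") <- z_threshold
  attr(regions, "windows") <- selected
  regions
}
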