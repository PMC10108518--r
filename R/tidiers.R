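# broom-style accessors for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the enrichment mixture fit
#'
#' @param x A `clip_em_fit`.
#' @param ... Unused.
#' @return One row per parameter (`term`, `estimate`).
#' @export
tidy.clip_em_fit <- function(x, ...) {
  tibble(
    term = c("rho", "sigma", "mu", "delta_min", "delta_max"),
    estimate = c(x$rho, x$sigma, x$mu, x$delta_min, x$delta_max)
  )
}

#' @rdname tidy.clip_em_fit
#' @export
glance.clip_em_fit <- function(x, ...) {
  tibble(
    logLik = x$loglik, n_windows = x$n_windows,
    iterations = x$iterations, converged = x$converged,
    N = x$N, M = x$M
  )
}

#' Tidy a per-region peak mixture fit
#'
#' @param x A `clip_peak_fit`.
#' @param ... Unused.
#' @return The peaks tibble with region coordinates attached.
#' @export
tidy.clip_peak_fit <- function(x, ...) {
  x$peaks |>
    mutate(chrom = x$region$chrom, strand = x$region$strand, .before = 1)
}

#' @rdname tidy.clip_peak_fit
#' @export
glance.clip_peak_fit <- function(x, ...) {
  tibble(
    logLik = x$loglik, n_peaks = nrow(x$peaks), K_max = x$K_max,
    noise_weight = x$noise_weight, n_fragments = length(x$midpoints)
  )
}

#' Tidy a CLIP simulation
#'
#' @param x A `clip_sim`.
#' @param ... Unused.
#' @return The per-site truth/estimate tibble joined with the distance
#'   summary.
#' @export
tidy.clip_sim <- function(x, ...) {
  left_join(x$sites, distance_summary(x), by = "site")
}
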