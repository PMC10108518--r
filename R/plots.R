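# ggplot2 visualisations of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a coverage profile
#'
#' Fragment coverage as an area, read-start frequency as a line: read
#' starts piling up against one flank of a coverage peak are the signature
#' of reverse-transcriptase truncation at the crosslink.
#'
#' @param object A `clip_coverage`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clip_coverage <- function(object, ...) {
  region <- attr(object, "region")
  ggplot2::ggplot(object, ggplot2::aes(x = position)) +
    ggplot2::geom_area(ggplot2::aes(y = depth), fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = read_starts), colour = "steelblue") +
    ggplot2::labs(
      x = sprintf("%s position (%s)", region$chrom, region$strand),
      y = "weighted coverage (grey) / read starts (blue)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a simulated CLIP experiment relative to the motif
#'
#' Pooled read coverage (solid), its moment-matched Gaussian (dashed) and
#' the read-start frequency (blue), all centered on the motif (position 0).
#'
#' @param object A `clip_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clip_sim <- function(object, ...) {
  sites <- object$sites
  reads <- object$reads |> filter(!is.na(.data$site))
  rel <- reads |>
    left_join(sites[, c("site", "motif_center")], by = "site") |>
    mutate(rs = read_start - .data$motif_center,
           s0 = start - .data$motif_center,
           e0 = end - .data$motif_center)
  span <- range(c(rel$s0, rel$e0))
  pos <- seq(span[1], span[2])
  cov <- numeric(length(pos))
  for (i in seq_len(nrow(rel))) {
    idx <- seq.int(rel$s0[i] - span[1] + 1L, rel$e0[i] - span[1])
    cov[idx] <- cov[idx] + rel$weight[i]
  }
  prof <- tibble(position = pos, depth = cov)
  g <- fit_gaussian_to_coverage(prof)
  gauss <- tibble(
    position = pos,
    depth = dnorm(pos, g[["center"]], g[["width"]]) * sum(cov)
  )
  starts <- rel |> count(rs, wt = weight)
  ggplot2::ggplot(prof, ggplot2::aes(position, depth)) +
    ggplot2::geom_line(colour = "red") +
    ggplot2::geom_line(data = gauss, colour = "red", linetype = "dashed") +
    ggplot2::geom_col(data = starts,
                      ggplot2::aes(rs, .data$n), fill = "steelblue",
                      width = 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(
      x = "position relative to motif center",
      y = "read coverage / read-start frequency",
      title = sprintf("readthrough probability %.2f",
                      object$config$rho_readthrough)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fitted peak mixture over the fragment midpoints
#'
#' @param object A `clip_peak_fit`.
#' @param binwidth Histogram bin width (default 5 nt).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clip_peak_fit <- function(object, binwidth = 5, ...) {
  df <- tibble(midpoint = object$midpoints, weight = object$weights)
  total <- sum(object$weights)
  curves <- purrr::map(seq_len(nrow(object$peaks)), function(i) {
    pk <- object$peaks[i, ]
    xs <- seq(object$region$start, object$region$end, length.out = 200)
    tibble(
      peak_id = pk$peak_id, position = xs,
      density = dnorm(xs, pk$center, pk$width) * pk$weight * total * binwidth
    )
  }) |> purrr::list_rbind()
  ggplot2::ggplot(df, ggplot2::aes(midpoint)) +
    ggplot2::geom_histogram(ggplot2::aes(weight = weight),
                            binwidth = binwidth, fill = "grey80") +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(position, .data$density, group = peak_id),
      colour = "red"
    ) +
    ggplot2::labs(x = "fragment midpoint", y = "weighted fragments") +
    ggplot2::theme_minimal()
}

#' Foreground-background window scatter
#'
#' Log read frequencies of every window in the two samples, colored by the
#' posterior probability of enrichment (1 - posterior of the unbound
#' component).
#'
#' @param scores Output of [window_zscores()].
#' @param fit The `clip_em_fit` used to score (provides totals).
#' @return A ggplot.
#' @export
plot_window_scatter <- function(scores, fit) {
  pc <- fit$pseudocount
  df <- scores |>
    mutate(
      fg_freq = log2((n + pc) / fit$N),
      bg_freq = log2((m + pc) / fit$M),
      p_bound = 1 - posterior_unbound
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$bg_freq, .data$fg_freq,
                                   colour = .data$p_bound)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = fit$mu / log(2),
                         linetype = "dashed") +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "log2 background read frequency",
                  y = "log2 foreground read frequency",
                  colour = "P(bound)") +
    ggplot2::theme_minimal()
}

#' Information-content logo of a PWM
#'
#' Stacked per-base bars scaled by column information content (bits).
#'
#' @param x A `pwm`.
#' @return A ggplot.
#' @export
plot_pwm <- function(x) {
  stopifnot(inherits(x, "pwm"))
  ic <- information_content(x)
  df <- as_tibble(unclass(x), rownames = "base") |>
    tidyr::pivot_longer(-base, names_to = "pos", values_to = "freq") |>
    mutate(pos = as.integer(gsub("\\D", "", pos)),
           height = freq * ic[pos])
  ggplot2::ggplot(df, ggplot2::aes(pos, .data$height, fill = base)) +
    ggplot2::geom_col(colour = "white", linewidth = 0.2) +
    ggplot2::scale_fill_manual(
      values = c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839")
    ) +
    ggplot2::labs(x = "motif position", y = "information (bits)",
                  title = attr(x, "name")) +
    ggplot2::theme_minimal()
}
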