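# Sliding-window tiling of the reference and weighted fragment counting.

#' Tile chromosomes into overlapping sliding windows
#'
#' Windows of `window_size` nucleotides are laid out every `step` nucleotides
#' from position 0, per chromosome and per strand; the terminal window is
#' truncated at the chromosome end. With the defaults (300 nt windows sliding
#' by 150 nt) every position is covered by two windows.
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param window_size Window length in nucleotides (default 300).
#' @param step Offset between consecutive window starts (default 150).
#' @param strands Strands to tile (default both).
#' @return A tibble with `chrom`, `start`, `end`, `strand`.
#' @export
make_windows <- function(chrom_lengths, window_size = 300L, step = 150L,
                         strands = STRANDS) {
  stopifnot(window_size >= step, step >= 1)
  if (length(chrom_lengths) == 0) {
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), strand = character()))
  }
  if (is.null(names(chrom_lengths))) {
    abort("`chrom_lengths` must be a named vector")
  }
  per_chrom <- purrr::imap(chrom_lengths, function(len, chrom) {
    starts <- seq.int(0L, len - 1L, by = step)
    starts <- starts[starts < len]
    tibble(
      chrom = chrom,
      start = as.integer(starts),
      end = as.integer(pmin(starts + window_size, len))
    )
  })
  purrr::list_rbind(per_chrom) |>
    tidyr::expand_grid(strand = strands) |>
    arrange(chrom, strand, start)
}

#' Count weighted fragments per window in foreground and background
#'
#' Each fragment contributes its weight to every same-strand window that
#' contains its midpoint, so within one phase of the tiling a fragment is
#' counted exactly once and totals are conserved. The totals `N` (foreground)
#' and `M` (background) default to the total weighted record count of each
#' sample and normalize the counts in the enrichment model.
#'
#' @param windows Window tibble from [make_windows()].
#' @param fg,bg Read-record tibbles for the foreground (IP) and background
#'   (SMI or RNA-seq) samples.
#' @param totals Optional `c(N = , M = )` override of the library-size
#'   normalizers, e.g. when the counted region is a slice of a larger
#'   library.
#' @param drop_empty Drop windows with zero counts in both samples (default
#'   `TRUE`; they carry no information for the model).
#' @return A tibble with the window coordinates, weighted counts `n` and
#'   `m`, and attributes `N` and `M`.
#' @export
count_windows <- function(windows, fg, bg, totals = NULL, drop_empty = TRUE) {
  validate_reads(fg, "fg")
  validate_reads(bg, "bg")
  validate_intervals(windows, "windows")
  if (nrow(fg) == 0 || sum(fg$weight) <= 0) {
    abort("foreground sample has zero total weighted reads; model undefined")
  }
  if (nrow(bg) == 0 || sum(bg$weight) <= 0) {
    abort("background sample has zero total weighted reads; model undefined")
  }
  N <- if (!is.null(totals)) unname(totals["N"]) else sum(fg$weight)
  M <- if (!is.null(totals)) unname(totals["M"]) else sum(bg$weight)

  counts <- windows |>
    mutate(window_id = dplyr::row_number()) |>
    mutate(
      n = window_weight_sums(windows, fg),
      m = window_weight_sums(windows, bg)
    ) |>
    select(-window_id)
  if (drop_empty) counts <- filter(counts, n > 0 | m > 0)
  attr(counts, "N") <- N
  attr(counts, "M") <- M
  counts
}

# Sum of fragment weights whose midpoint lies in each window (same strand).
window_weight_sums <- function(windows, reads) {
  out <- numeric(nrow(windows))
  if (nrow(reads) == 0) return(out)
  mids <- fragment_midpoint(reads$start, reads$end)
  key_w <- paste(windows$chrom, windows$strand, windows$start, sep = "\r")
  # windows are on the regular grid start = 0, step, 2*step, ...; find, for
  # each fragment, the window starts whose span contains its midpoint
  step <- infer_step(windows)
  size <- max(windows$end - windows$start)
  n_phase <- ceiling(size / step)
  acc <- new.env(parent = emptyenv())
  for (j in seq_len(n_phase) - 1L) {
    cand <- (mids %/% step - j) * step
    ok <- cand >= 0 & mids < cand + size
    if (!any(ok)) next
    keys <- paste(reads$chrom[ok], reads$strand[ok], cand[ok], sep = "\r")
    sums <- rowsum(reads$weight[ok], keys)
    idx <- match(rownames(sums), key_w)
    hit <- !is.na(idx)
    out[idx[hit]] <- out[idx[hit]] + sums[hit, 1]
  }
  out
}

infer_step <- function(windows) {
  starts <- sort(unique(windows$start))
  if (length(starts) < 2) return(max(windows$end - windows$start))
  min(diff(starts))
}
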