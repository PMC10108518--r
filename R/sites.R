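# Binding-site extraction: fixed-width sequences (anchor +/- 20 nt) around
# coverage-peak centers or modal read-start (crosslink) positions, merged
# to non-redundancy so motifs are not double-counted.

#' Modal read-start (crosslink) position of a peak
#'
#' Reverse-transcriptase truncation makes read 5' ends pile up next to the
#' crosslinked nucleotide, so the position with most read starts inside the
#' peak span (center +/- 2 sd) estimates the crosslink. Ties are broken by
#' proximity to the peak center, then leftmost. With no read starts in the
#' span the rounded peak center is returned with a message.
#'
#' @param peak One row of a peaks tibble (needs `center`, `width`).
#' @param profile A `clip_coverage` of the enclosing region (foreground).
#' @return Integer position.
#' @export
crosslink_position <- function(peak, profile) {
  stopifnot(inherits(profile, "clip_coverage"))
  lo <- peak$center - 2 * peak$width
  hi <- peak$center + 2 * peak$width
  span <- filter(profile, position >= lo, position <= hi)
  if (nrow(span) == 0 || sum(span$read_starts) == 0) {
    inform("no read starts in peak span; falling back to the peak center")
    return(as.integer(round(peak$center)))
  }
  top <- filter(span, read_starts == max(read_starts))
  top <- arrange(top, abs(position - peak$center), position)
  as.integer(top$position[1])
}

#' Extract fixed-width binding-site sequences around peak anchors
#'
#' Each significant peak yields a site spanning `flank` nucleotides on both
#' sides of its anchor (41 nt with the default flank of 20), clipped at
#' chromosome edges. The anchor is either the rounded coverage-peak center
#' (`"peak_center"`) or the modal read-start position (`"crosslink"`).
#' Sites are sorted by decreasing z and made non-redundant greedily: among
#' overlapping same-strand sites only the highest-z one is kept. Minus
#' strand sequences are reverse-complemented.
#'
#' @param peaks Peaks tibble from [call_peaks()] (needs `chrom`, `strand`,
#'   `center`, `width`, `z`).
#' @param fg Foreground read records (used to locate read starts for
#'   crosslink anchoring).
#' @param genome A named character vector of sequences, a
#'   [Biostrings::DNAStringSet], or a FASTA path.
#' @param anchor_kind `"peak_center"` or `"crosslink"`.
#' @param flank Nucleotides on each side of the anchor (default 20).
#' @return A tibble of sites: coordinates, `anchor`, `z`, uppercase
#'   `sequence`.
#' @export
extract_sites <- function(peaks, fg, genome,
                          anchor_kind = c("peak_center", "crosslink"),
                          flank = 20L) {
  anchor_kind <- match.arg(anchor_kind)
  genome <- as_genome(genome)
  if (nrow(peaks) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), anchor = integer(), anchor_kind = character(),
      z = double(), sequence = character()
    ))
  }
  chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
  missing_chroms <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing_chroms) > 0) {
    abort(sprintf("genome lacks sequences: %s",
                  paste(missing_chroms, collapse = ", ")))
  }

  anchors <- purrr::map_int(seq_len(nrow(peaks)), function(i) {
    pk <- peaks[i, ]
    if (anchor_kind == "peak_center") return(as.integer(round(pk$center)))
    lo <- max(0, floor(pk$center - 2 * pk$width))
    hi <- min(chrom_lengths[[pk$chrom]], ceiling(pk$center + 2 * pk$width) + 1)
    prof <- coverage_profile(
      list(chrom = pk$chrom, start = as.integer(lo), end = as.integer(hi),
           strand = pk$strand),
      fg
    )
    crosslink_position(pk, prof)
  })

  sites <- peaks |>
    mutate(
      anchor = anchors,
      start = pmax(0L, anchor - as.integer(flank)),
      end = pmin(unname(chrom_lengths[chrom]),
                 anchor + as.integer(flank) + 1L),
      anchor_kind = anchor_kind
    ) |>
    arrange(desc(z))

  keep <- greedy_nonoverlap(sites)
  sites <- sites[keep, ]
  seqs <- Biostrings::subseq(
    genome[sites$chrom], start = sites$start + 1L, end = sites$end
  )
  neg <- sites$strand == "-"
  seqs <- unname(as.character(seqs))
  if (any(neg)) seqs[neg] <- reverse_complement(seqs[neg])
  sites |>
    mutate(sequence = toupper(seqs), site_id = dplyr::row_number()) |>
    select(site_id, chrom, start, end, strand, anchor, anchor_kind, z,
           sequence)
}

# Greedy keep-best: scan sites (already sorted by decreasing z), keep a
# site iff it overlaps no previously kept same-strand site.
greedy_nonoverlap <- function(sites) {
  keep <- logical(nrow(sites))
  kept <- list()
  for (i in seq_len(nrow(sites))) {
    key <- paste(sites$chrom[i], sites$strand[i])
    prev <- kept[[key]]
    ok <- TRUE
    if (!is.null(prev)) {
      ok <- all(sites$start[i] >= prev$end | sites$end[i] <= prev$start)
    }
    if (ok) {
      keep[i] <- TRUE
      kept[[key]] <- rbind(
        prev, data.frame(start = sites$start[i], end = sites$end[i])
      )
    }
  }
  keep
}

as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    return(Biostrings::readDNAStringSet(genome))
  }
  if (is.character(genome) && !is.null(names(genome))) {
    return(Biostrings::DNAStringSet(genome))
  }
  abort("`genome` must be a FASTA path, DNAStringSet, or named character vector")
}

#' Write sites as FASTA
#'
#' Headers are `chrom:start-end(strand)` with the z-score in the
#' description.
#'
#' @param sites Sites tibble from [extract_sites()].
#' @param path Output file.
#' @export
write_sites_fasta <- function(sites, path) {
  ids <- sprintf("%s:%d-%d(%s) z=%.3f",
                 sites$chrom, sites$start, sites$end, sites$strand, sites$z)
  xs <- Biostrings::DNAStringSet(sites$sequence)
  names(xs) <- ids
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}
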