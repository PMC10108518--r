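# Internal helpers shared across modules.
#
# Coordinate convention: 0-based, half-open [start, end), strand in {"+","-"}.
# BED files use the same convention on disk; SAM/BAM input (1-based, closed)
# is converted at the reader boundary.

STRANDS <- c("+", "-")

#' Columns of a read-record tibble
#'
#' Every alignment reader and the simulator emit this schema: one row per
#' reported alignment, `fragment = [start, end)` (mate-pair outer span for
#' paired-end data), `read_start` the 5' end of the cDNA in transcript
#' orientation (rightmost genomic coordinate on the minus strand), `weight`
#' the fractional count in (0, 1] used everywhere downstream, and `name`
#' the read identifier.
#' @keywords internal
READ_COLS <- c("chrom", "start", "end", "strand", "read_start", "weight", "name")

validate_reads <- function(reads, arg = "reads") {
  if (!is.data.frame(reads)) {
    abort(sprintf("`%s` must be a data frame of read records", arg))
  }
  missing_cols <- setdiff(READ_COLS, names(reads))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "`%s` is missing read-record columns: %s",
      arg, paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(reads) > 0) {
    if (any(reads$end <= reads$start)) {
      abort(sprintf("`%s` contains empty or inverted fragments", arg))
    }
    if (!all(reads$strand %in% STRANDS)) {
      abort(sprintf("`%s` has strands outside {+,-}", arg))
    }
    if (any(reads$weight <= 0 | reads$weight > 1)) {
      abort(sprintf("`%s` has weights outside (0, 1]", arg))
    }
    bad <- reads$read_start < reads$start | reads$read_start >= reads$end
    if (any(bad)) {
      abort(sprintf(
        "`%s`: %d read_start positions fall outside their fragment",
        arg, sum(bad)
      ))
    }
  }
  invisible(reads)
}

validate_intervals <- function(x, arg = "intervals") {
  if (!is.data.frame(x)) abort(sprintf("`%s` must be a data frame", arg))
  need <- c("chrom", "start", "end")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "`%s` is missing columns: %s", arg, paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(x) > 0 && any(x$end <= x$start)) {
    abort(sprintf("`%s` contains empty or inverted intervals", arg))
  }
  invisible(x)
}

# Fragment midpoint under the half-open convention: [100, 120) -> 110.
fragment_midpoint <- function(start, end) {
  (start + end) %/% 2L
}

# Intervals tibble -> GRanges (0-based half-open -> 1-based closed).
intervals_to_granges <- function(x, ignore_strand = FALSE) {
  strand <- if (ignore_strand || is.null(x$strand)) "*" else x$strand
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

granges_to_intervals <- function(gr) {
  tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# Seed helper: deterministic derivation of sub-seeds below 2^31.
derive_seed <- function(seed, k) {
  (as.integer(seed) + 104729L * as.integer(k)) %% 2147483647L
}
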