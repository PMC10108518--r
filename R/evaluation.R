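# Nucleotide-level agreement between peak/site collections.

#' Nucleotide-level Jaccard agreement of two peak sets
#'
#' Both inputs are expanded to their sets of covered (chrom, strand,
#' position) triples; the agreement is `|A intersect B| / (|A| + |B| -
#' |A intersect B|)`. A plus- and a minus-strand position never intersect.
#'
#' @param a,b Data frames with `chrom`, `start`, `end` (0-based half-open)
#'   and optionally `strand` (assumed `+` when absent), or paths to BED
#'   files.
#' @return A one-row tibble with `jaccard`, `intersection`, `union`,
#'   `n_a`, `n_b` (nucleotide counts).
#' @export
jaccard_nt <- function(a, b) {
  a <- as_peak_intervals(a)
  b <- as_peak_intervals(b)
  if (nrow(a) == 0 && nrow(b) == 0) {
    abort("both peak sets are empty; the agreement is undefined")
  }
  gr_a <- GenomicRanges::reduce(intervals_to_granges(a))
  gr_b <- GenomicRanges::reduce(intervals_to_granges(b))
  shared <- union(GenomeInfoDb::seqlevels(gr_a), GenomeInfoDb::seqlevels(gr_b))
  GenomeInfoDb::seqlevels(gr_a) <- shared
  GenomeInfoDb::seqlevels(gr_b) <- shared
  n_a <- sum(GenomicRanges::width(gr_a))
  n_b <- sum(GenomicRanges::width(gr_b))
  inter <- sum(GenomicRanges::width(
    GenomicRanges::intersect(gr_a, gr_b, ignore.strand = FALSE)
  ))
  tibble(
    jaccard = inter / (n_a + n_b - inter),
    intersection = inter,
    union = n_a + n_b - inter,
    n_a = n_a,
    n_b = n_b
  )
}

as_peak_intervals <- function(x) {
  if (is.character(x) && length(x) == 1) {
    gr <- rtracklayer::import(x, format = "BED")
    return(granges_to_intervals(gr) |>
             mutate(strand = ifelse(strand == "*", "+", strand)))
  }
  validate_intervals(x)
  x <- as_tibble(x)
  if (is.null(x$strand)) x$strand <- "+"
  x
}
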