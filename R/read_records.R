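# Reading aligned, deduplicated CLIP reads into the weighted fragment
# representation used by all downstream modules.

#' Read a plain-text fragment table
#'
#' The tab-separated fragment table is the tool-free interchange format for
#' read records (columns `chrom`, `start`, `end`, `strand`, `read_start`,
#' `weight`, `name`; 0-based half-open coordinates). The simulator writes
#' this format, so the full pipeline can be exercised without any aligner.
#'
#' @param path Path to a tab-separated file with a header line.
#' @return A tibble of read records.
#' @export
read_fragment_table <- function(path) {
  reads <- readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      strand = readr::col_character(),
      read_start = readr::col_integer(),
      weight = readr::col_double(),
      name = readr::col_character()
    )
  )
  validate_reads(reads, arg = path)
  reads
}

#' @rdname read_fragment_table
#' @param reads A read-record tibble.
#' @export
write_fragment_table <- function(reads, path) {
  validate_reads(reads)
  readr::write_tsv(reads[, READ_COLS], path)
  invisible(path)
}

#' Load alignments into weighted read records
#'
#' Converts a coordinate-sorted, indexed BAM (or SAM, converted on the fly),
#' or a plain fragment table, into one record per reported alignment. For
#' paired-end libraries only proper pairs are used; the fragment is the outer
#' span of the two mates and `read_start` is the 5' end of mate 2 (the
#' reverse-transcriptase truncation position in eCLIP), which on the minus
#' strand is the rightmost genomic coordinate of that read. Reads reported at
#' more loci than `max_multimappers` are dropped entirely; each retained
#' read's alignments carry weight 1/(number of its reported alignments), so
#' per-read weight always sums to one.
#'
#' @param path BAM/SAM file, or a tab-separated fragment table
#'   (`.tsv`/`.tab`/`.txt`).
#' @param library_layout `"paired"` or `"single"`.
#' @param max_multimappers Maximum number of reported alignments for a read
#'   to be retained (default 1: unique mappers only).
#' @param sense_strand Which alignment strand carries the transcript sense:
#'   for paired data the default is mate 2 (eCLIP); `"flip"` reverses the
#'   inferred strand for protocols sequencing the antisense.
#' @return A tibble of read records (see [read_fragment_table()] for the
#'   schema).
#' @export
load_alignments <- function(path,
                            library_layout = c("paired", "single"),
                            max_multimappers = 1L,
                            sense_strand = c("as_aligned", "flip")) {
  library_layout <- match.arg(library_layout)
  sense_strand <- match.arg(sense_strand)
  stopifnot(max_multimappers >= 1)
  if (!file.exists(path)) abort(sprintf("alignment file not found: %s", path))

  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "tab", "txt")) {
    reads <- read_fragment_table(path)
  } else {
    reads <- load_alignments_bam(path, library_layout)
  }
  if (sense_strand == "flip" && nrow(reads) > 0) {
    reads$strand <- ifelse(reads$strand == "+", "-", "+")
  }
  apply_multimapper_weights(reads, max_multimappers)
}

load_alignments_bam <- function(path, library_layout) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "sam") {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = TRUE)
  } else if (!file.exists(paste0(path, ".bai")) &&
             !file.exists(sub("\\.bam$", ".bai", path))) {
    abort(sprintf(
      "BAM file %s has no index; coordinate-sort and index it first", path
    ))
  }

  if (library_layout == "paired") {
    n_records <- Rsamtools::countBam(path)$records
    pairs <- GenomicAlignments::readGAlignmentPairs(
      path,
      use.names = TRUE,
      param = Rsamtools::ScanBamParam(
        flag = Rsamtools::scanBamFlag(isProperPair = TRUE)
      )
    )
    n_skipped <- n_records - 2L * length(pairs)
    if (n_skipped > 0) {
      inform(sprintf(
        "%s: %d records were not part of a proper pair and were skipped",
        path, n_skipped
      ))
    }
    if (length(pairs) == 0) {
      return(tibble(
        chrom = character(), start = integer(), end = integer(),
        strand = character(), read_start = integer(),
        weight = double(), name = character()
      ))
    }
    mate2 <- GenomicAlignments::last(pairs)
    span <- GenomicRanges::granges(pairs) # outer span of the pair
    m2_strand <- as.character(GenomicAlignments::strand(mate2))
    tibble(
      chrom = as.character(GenomeInfoDb::seqnames(span)),
      start = GenomicRanges::start(span) - 1L,
      end = GenomicRanges::end(span),
      strand = m2_strand,
      read_start = ifelse(
        m2_strand == "+",
        GenomicAlignments::start(mate2) - 1L,
        GenomicAlignments::end(mate2) - 1L
      ),
      weight = 1,
      name = names(pairs)
    )
  } else {
    aln <- GenomicAlignments::readGAlignments(path, use.names = TRUE)
    if (length(aln) == 0) {
      return(tibble(
        chrom = character(), start = integer(), end = integer(),
        strand = character(), read_start = integer(),
        weight = double(), name = character()
      ))
    }
    aln_strand <- as.character(GenomicAlignments::strand(aln))
    tibble(
      chrom = as.character(GenomeInfoDb::seqnames(aln)),
      start = GenomicAlignments::start(aln) - 1L,
      end = GenomicAlignments::end(aln),
      strand = aln_strand,
      read_start = ifelse(
        aln_strand == "+",
        GenomicAlignments::start(aln) - 1L,
        GenomicAlignments::end(aln) - 1L
      ),
      weight = 1,
      name = names(aln)
    )
  }
}

# Weight = 1/(reported alignments of the read); reads above the cap dropped.
apply_multimapper_weights <- function(reads, max_multimappers) {
  validate_reads(reads)
  if (nrow(reads) == 0) return(reads)
  reads |>
    group_by(name) |>
    mutate(weight = 1 / n()) |>
    filter(n() <= max_multimappers) |>
    ungroup()
}

#' Remove reads overlapping abundant non-coding RNAs
#'
#' Reads from abundant ncRNAs (rRNA, tRNA, snRNA, ...) are common CLIP
#' contaminants. Any read whose fragment shares at least one nucleotide with
#' an ncRNA interval (same chromosome, strand-agnostic) is removed, and the
#' removal applies to every alignment of that read name, mirroring removal
#' by read-name list.
#'
#' @param reads Read-record tibble.
#' @param ncrna A data frame with `chrom`/`start`/`end` columns (0-based
#'   half-open), a `GRanges`, or a path to a BED/GFF3 file.
#' @return The filtered read-record tibble.
#' @export
filter_ncrna <- function(reads, ncrna) {
  validate_reads(reads)
  gr <- ncrna_granges(ncrna)
  if (length(gr) == 0 || nrow(reads) == 0) return(reads)
  hits <- GenomicRanges::findOverlaps(
    intervals_to_granges(reads, ignore_strand = TRUE),
    gr, ignore.strand = TRUE
  )
  dropped_names <- unique(reads$name[S4Vectors::queryHits(hits)])
  filter(reads, !name %in% dropped_names)
}

ncrna_granges <- function(ncrna) {
  if (is.null(ncrna)) return(GenomicRanges::GRanges())
  if (methods::is(ncrna, "GRanges")) return(ncrna)
  if (is.character(ncrna) && length(ncrna) == 1) {
    return(rtracklayer::import(ncrna))
  }
  validate_intervals(ncrna, "ncrna")
  if (nrow(ncrna) == 0) return(GenomicRanges::GRanges())
  intervals_to_granges(ncrna, ignore_strand = TRUE)
}

#' Choose between transcriptome and genome alignments of a read
#'
#' When reads are aligned both to a representative transcriptome and to the
#' genome, the transcriptome alignment is preferred unless the genome
#' alignment scores more than 3 points higher: the transcriptome is chosen
#' iff `score_transcriptome > score_genome - 3`. If only one score is
#' present the corresponding side is returned.
#'
#' @param score_transcriptome,score_genome Integer alignment scores (`AS`
#'   tags); `NA` when the read did not align on that side. Vectorized.
#' @return Character vector of `"transcriptome"` or `"genome"`.
#' @export
assign_read_locus <- function(score_transcriptome, score_genome) {
  if (length(score_transcriptome) != length(score_genome)) {
    abort("score vectors must have equal length")
  }
  both_missing <- is.na(score_transcriptome) & is.na(score_genome)
  if (any(both_missing)) {
    abort("both alignment scores are missing for at least one read")
  }
  dplyr::case_when(
    is.na(score_genome) ~ "transcriptome",
    is.na(score_transcriptome) ~ "genome",
    score_transcriptome > score_genome - 3 ~ "transcriptome",
    .default = "genome"
  )
}
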