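# Shared fixture builders and independent brute-force oracles. The oracles
# deliberately use naive loops/set expansion so they share no code with the
# package implementations they check.

BASES <- c("A", "C", "G", "T")

random_seqs <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

# PWM with `major` probability on the consensus base at each position.
consensus_pwm <- function(consensus, major = 0.85, name = consensus) {
  chars <- strsplit(consensus, "")[[1]]
  m <- matrix((1 - major) / 3, 4, length(chars),
              dimnames = list(BASES, NULL))
  for (j in seq_along(chars)) m[chars[j], j] <- major
  pwm(m, name = name)
}

random_pwm <- function(len) {
  m <- matrix(rexp(4 * len), 4, len, dimnames = list(BASES, NULL))
  pwm(sweep(m, 2, colSums(m), `/`), name = "random")
}

# Plant one consensus occurrence at a random offset of each sequence.
plant_consensus <- function(seqs, consensus) {
  w <- nchar(consensus)
  vapply(seqs, function(s) {
    pos <- sample(nchar(s) - w + 1, 1)
    paste0(substr(s, 1, pos - 1), consensus, substr(s, pos + w, nchar(s)))
  }, character(1), USE.NAMES = FALSE)
}

make_reads <- function(chrom, start, end, strand = "+", read_start = start,
                       weight = 1, name = NULL) {
  k <- max(lengths(list(start, end, strand, read_start, weight)))
  tibble::tibble(
    chrom = rep_len(chrom, k), start = as.integer(rep_len(start, k)),
    end = as.integer(rep_len(end, k)), strand = rep_len(strand, k),
    read_start = as.integer(rep_len(read_start, k)),
    weight = rep_len(weight, k),
    name = name %||% sprintf("r%d", seq_len(k))
  )
}

`%||%` <- rlang::`%||%`

# Hand-built clip_em_fit for testing the scoring formulas in isolation.
manual_fit <- function(rho, sigma, mu, delta_min, delta_max, N, M,
                       pseudocount = 0) {
  structure(
    list(rho = rho, sigma = sigma, mu = mu, delta_min = delta_min,
         delta_max = delta_max, N = N, M = M, pseudocount = pseudocount,
         loglik = NA_real_, loglik_trace = numeric(0), iterations = 0L,
         converged = TRUE, n_windows = 0L),
    class = "clip_em_fit"
  )
}

# --- independent oracles -------------------------------------------------

# Unbound density straight from the printed formula.
oracle_prob_unbound <- function(n, m, N, M, sigma, mu) {
  v <- 2 * sigma^2 + 1 / n + 1 / m
  (1 / sqrt(2 * pi * v)) *
    exp(-(log(n / N) - log(m / M) - mu)^2 / (2 * v))
}

oracle_zscore <- function(n, m, N, M, sigma, mu) {
  (log(n / N) - log(m / M) - mu) / sqrt(2 * sigma^2 + 1 / n + 1 / m)
}

# Nucleotide-set Jaccard by explicit position expansion.
oracle_jaccard <- function(a, b) {
  expand <- function(x) {
    unlist(purrr::pmap(x, function(chrom, start, end, strand, ...) {
      paste(chrom, strand, seq.int(start, end - 1L))
    }))
  }
  sa <- unique(expand(a))
  sb <- unique(expand(b))
  inter <- length(intersect(sa, sb))
  inter / (length(sa) + length(sb) - inter)
}

oracle_information <- function(col) {
  tot <- 2
  for (f in col) if (f > 0) tot <- tot + f * log(f) / log(2)
  tot
}

# Motif similarity with explicit offset/position/base loops.
oracle_motif_similarity <- function(m1, m2) {
  s_of <- function(a, b) {
    l1 <- ncol(a); l2 <- ncol(b)
    best <- -Inf
    for (d in -(l2 - 1):(l1 - 1)) {
      tot <- 0
      any_overlap <- FALSE
      for (i in 1:l1) {
        j <- i - d
        if (j >= 1 && j <= l2) {
          any_overlap <- TRUE
          for (b_ in 1:4) tot <- tot + a[b_, i] * b[b_, j]
        }
      }
      if (any_overlap && tot > best) best <- tot
    }
    best
  }
  a <- unname(unclass(m1)); b <- unname(unclass(m2))
  2 * s_of(a, b) / (s_of(a, a) + s_of(b, b))
}

# Sliding-window tiling by direct enumeration.
oracle_windows <- function(len, size, step) {
  out <- list()
  s <- 0
  while (s < len) {
    out[[length(out) + 1]] <- c(s, min(s + size, len))
    s <- s + step
  }
  do.call(rbind, out)
}

# Minimal coordinate-sorted SAM for the BAM reader tests.
write_test_sam <- function(path, records,
                           sq = "@SQ\tSN:chr1\tLN:10000") {
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", sq, records), path)
  path
}
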