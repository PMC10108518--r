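# Position weight matrices: representation, information content and
# boundary trimming, posterior-based occupancy scanning, cross-validated
# motif enrichment of foreground sites versus weakly enriched background
# sequences, and the offset-maximized motif-similarity measure.

PWM_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' A PWM is stored as a 4 x L column-stochastic matrix (rows A, C, G, T; U
#' is treated as T). Count matrices are normalized. Raw frequencies are
#' kept as given (so orthogonal columns stay orthogonal for the similarity
#' measure); likelihood-based scanning applies its own floor, see
#' [scan_posteriors()].
#'
#' @param x A 4 x L or L x 4 numeric matrix of frequencies or counts, with
#'   base names on the 4-dimension (`U` accepted for `T`).
#' @param name Motif identifier.
#' @return An object of class `pwm`.
#' @export
pwm <- function(x, name = "motif") {
  x <- as.matrix(x)
  if (nrow(x) != 4 && ncol(x) == 4) x <- t(x)
  if (nrow(x) != 4) abort("a PWM needs 4 base rows (A, C, G, T/U)")
  rn <- rownames(x) %||% PWM_BASES
  rn[rn == "U"] <- "T"
  if (!setequal(rn, PWM_BASES)) abort("PWM rows must be named A, C, G, T/U")
  rownames(x) <- rn
  x <- x[PWM_BASES, , drop = FALSE]
  if (any(x < 0) || any(colSums(x) <= 0)) {
    abort("PWM entries must be non-negative with positive column sums")
  }
  x <- sweep(x, 2, colSums(x), `/`)
  structure(x, name = name, class = c("pwm", "matrix", "array"))
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s' (%d positions)\n", attr(x, "name"), ncol(x)))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

# Floor entries at 1e-3 and renormalize: used wherever zero frequencies
# would null a likelihood product.
pwm_pseudo <- function(x, floor = 1e-3) {
  y <- pmax(unclass(x), floor)
  sweep(y, 2, colSums(y), `/`)
}

#' Information content of PWM columns
#'
#' `2 + sum_b f_b log2 f_b` bits per column (0 log 0 taken as 0): 0 for a
#' uniform column, 2 for a deterministic base.
#'
#' @param x A `pwm` or a single base-frequency 4-vector.
#' @return Bits, one value per column.
#' @export
information_content <- function(x) {
  m <- if (is.matrix(x)) unclass(x) else matrix(x, ncol = 1)
  apply(m, 2, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
}

#' Trim uninformative PWM boundaries
#'
#' Repeatedly removes the first or last column while its information
#' content is below `min_bits`; interior columns are never removed. If
#' every column is below the threshold the single most informative column
#' is retained with a warning.
#'
#' @param x A `pwm`.
#' @param min_bits Information threshold in bits (default 0.5).
#' @return The trimmed `pwm`.
#' @export
trim_pwm <- function(x, min_bits = 0.5) {
  stopifnot(inherits(x, "pwm"))
  ic <- information_content(x)
  lo <- 1L
  hi <- ncol(x)
  while (lo < hi && ic[lo] < min_bits) lo <- lo + 1L
  while (hi > lo && ic[hi] < min_bits) hi <- hi - 1L
  if (lo == hi && ic[lo] < min_bits) {
    warn("all PWM columns fall below the information threshold; keeping the best one")
    lo <- hi <- which.max(ic)
  }
  pwm(unclass(x)[, lo:hi, drop = FALSE], name = attr(x, "name"))
}

# Encode a sequence as row indices into the PWM (NA for N).
encode_seq <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  chars[chars == "U"] <- "T"
  idx <- match(chars, PWM_BASES)
  if (any(is.na(idx) & chars != "N")) {
    abort(sprintf("sequence contains non-ACGTUN characters: %s",
                  paste(unique(chars[is.na(idx) & chars != "N"]), collapse = "")))
  }
  idx
}

#' Posterior motif occupancy along a sequence
#'
#' For each offset the motif likelihood is the product of the (floored,
#' renormalized) PWM frequencies of the observed bases, the background
#' likelihood the product of `bg_freqs`; `N` positions contribute a factor
#' of 1 to both. The posterior that the offset is a motif site is
#' `prior * L_w / (prior * L_w + (1 - prior) * L_b)`.
#'
#' @param seq A nucleotide string (ACGTUN; at least as long as the motif).
#' @param x A `pwm`.
#' @param prior Prior probability of a site at an offset, in (0, 1).
#' @param bg_freqs Background base frequencies (A, C, G, T); default
#'   uniform.
#' @return A tibble with `offset` (0-based) and `posterior`.
#' @export
scan_posteriors <- function(seq, x, prior, bg_freqs = rep(0.25, 4)) {
  stopifnot(inherits(x, "pwm"), prior > 0, prior < 1)
  lik <- offset_likelihoods(seq, x, bg_freqs)
  tibble(
    offset = seq_along(lik$lw) - 1L,
    posterior = prior * lik$lw / (prior * lik$lw + (1 - prior) * lik$lb)
  )
}

offset_likelihoods <- function(seq, x, bg_freqs) {
  w <- ncol(x)
  idx <- encode_seq(seq)
  if (length(idx) < w) {
    abort("sequence shorter than the motif")
  }
  mat <- base::log(pwm_pseudo(x))
  bg <- base::log(pmax(bg_freqs, 1e-12))
  n_off <- length(idx) - w + 1L
  lw <- numeric(n_off)
  lb <- numeric(n_off)
  for (j in seq_len(w)) {
    b <- idx[j:(j + n_off - 1L)]
    known <- !is.na(b)
    contrib_w <- numeric(n_off)
    contrib_b <- numeric(n_off)
    contrib_w[known] <- mat[cbind(b[known], j)]
    contrib_b[known] <- bg[b[known]]
    lw <- lw + contrib_w
    lb <- lb + contrib_b
  }
  list(lw = exp(lw), lb = exp(lb))
}

# Prior of site occurrence per scanned offset, trained by maximizing the
# independent-offset mixture likelihood over the training sequences:
# every offset is a site with probability p (motif likelihood L_w) or
# background with probability 1 - p.
train_prior <- function(seqs, x, bg_freqs) {
  liks <- purrr::map(seqs, offset_likelihoods, x = x, bg_freqs = bg_freqs)
  lr <- unlist(purrr::map(liks, ~ .x$lw / .x$lb))
  obj <- function(p) sum(base::log(p * lr + (1 - p)))
  optimize(obj, c(1e-6, 1 - 1e-6), maximum = TRUE)$maximum
}

#' Cross-validated motif enrichment of foreground sites
#'
#' Per run, the foreground sequences are split into a training part, used
#' only to fit the prior probability of non-specific occurrence, and a test
#' part. The enrichment is the mean posterior per scanned offset in the
#' test foreground divided by the same density in the background
#' sequences, both under the trained prior. The mean and standard
#' deviation over `runs` repeats (default 5) are reported.
#'
#' @param fg_sites,bg_sites Character vectors of sequences (background at
#'   least as many as foreground, comparable lengths).
#' @param x A `pwm`.
#' @param runs Number of train/test repeats (default 5).
#' @param train_frac Fraction of foreground used for prior training
#'   (default 0.5).
#' @param bg_freqs Background base frequencies; estimated from the pooled
#'   background sequences by default.
#' @param seed Optional seed; each run derives its own sub-seed.
#' @return A one-row tibble: `motif`, `mean_enrichment`, `sd_enrichment`,
#'   `runs`, `mean_prior`.
#' @export
motif_enrichment <- function(fg_sites, bg_sites, x, runs = 5L,
                             train_frac = 0.5, bg_freqs = NULL,
                             seed = NULL) {
  stopifnot(inherits(x, "pwm"), length(fg_sites) >= 2)
  if (length(bg_sites) < length(fg_sites)) {
    warn("fewer background than foreground sequences")
  }
  bg_freqs <- bg_freqs %||% base_frequencies(bg_sites)
  bg_liks <- purrr::map(bg_sites, offset_likelihoods, x = x,
                        bg_freqs = bg_freqs)
  fg_liks <- purrr::map(fg_sites, offset_likelihoods, x = x,
                        bg_freqs = bg_freqs)
  n_fg <- length(fg_sites)
  n_train <- max(1L, min(n_fg - 1L, round(train_frac * n_fg)))

  run_once <- function(r) {
    if (!is.null(seed)) set.seed(derive_seed(seed, r))
    train_idx <- sample(n_fg, n_train)
    test_idx <- setdiff(seq_len(n_fg), train_idx)
    if (length(test_idx) == 0) abort("empty test split")
    prior <- train_prior(fg_sites[train_idx], x, bg_freqs)
    fg_density <- posterior_density(fg_liks[test_idx], prior)
    bg_density <- posterior_density(bg_liks, prior)
    if (bg_density == 0) {
      warn("background posterior density is zero; enrichment is infinite")
      return(c(enrichment = Inf, prior = prior))
    }
    c(enrichment = fg_density / bg_density, prior = prior)
  }
  res <- purrr::map(seq_len(runs), run_once)
  enr <- purrr::map_dbl(res, "enrichment")
  tibble(
    motif = attr(x, "name"),
    mean_enrichment = mean(enr),
    sd_enrichment = if (runs > 1) sd(enr) else 0,
    runs = as.integer(runs),
    mean_prior = mean(purrr::map_dbl(res, "prior"))
  )
}

posterior_density <- function(liks, prior) {
  post <- purrr::map_dbl(liks, function(l) {
    sum(prior * l$lw / (prior * l$lw + (1 - prior) * l$lb))
  })
  n_off <- purrr::map_int(liks, ~ length(.x$lw))
  sum(post) / sum(n_off)
}

base_frequencies <- function(seqs) {
  idx <- unlist(purrr::map(seqs, encode_seq))
  idx <- idx[!is.na(idx)]
  counts <- tabulate(idx, nbins = 4) + 1
  counts / sum(counts)
}

#' Sample background sequences from the least enriched windows
#'
#' Emulates drawing unbound sequences from the genomic regions most
#' depleted of IP reads: windows are ranked by ascending z-score, the
#' lowest `pool_frac` fraction forms the pool, and `n_per_site` random
#' subsequences of `size` nucleotides are drawn per foreground site.
#'
#' @param scores Window scores from [window_zscores()].
#' @param genome Genome (path, DNAStringSet, or named character).
#' @param n_fg_sites Number of foreground sites.
#' @param n_per_site Background sequences per foreground site (default 20).
#' @param size Background sequence length (default 40).
#' @param pool_frac Fraction of lowest-z windows used (default 0.25).
#' @param seed Optional seed.
#' @return Character vector of `n_fg_sites * n_per_site` sequences.
#' @export
background_sequences <- function(scores, genome, n_fg_sites,
                                 n_per_site = 20L, size = 40L,
                                 pool_frac = 0.25, seed = NULL) {
  genome <- as_genome(genome)
  pool <- scores |>
    arrange(z) |>
    head(max(1L, floor(nrow(scores) * pool_frac))) |>
    filter(end - start >= size)
  if (nrow(pool) == 0) abort("no windows long enough for background sampling")
  if (!is.null(seed)) set.seed(seed)
  n_total <- n_fg_sites * n_per_site
  rows <- sample(nrow(pool), n_total, replace = TRUE)
  offsets <- floor(runif(n_total) *
                     (pool$end[rows] - pool$start[rows] - size + 1))
  starts <- pool$start[rows] + offsets
  seqs <- as.character(Biostrings::subseq(
    genome[pool$chrom[rows]], start = starts + 1L, end = starts + size
  ))
  neg <- pool$strand[rows] == "-"
  if (any(neg)) seqs[neg] <- reverse_complement(seqs[neg])
  toupper(seqs)
}

#' Motif similarity
#'
#' `I(m1, m2, d)` is the sum over overlapping positions of the inner
#' products of the base-frequency columns with the second motif at offset
#' `d`; `S` is the maximum of `I` over all offsets with at least one
#' overlapping column, and `M(m1, m2) = 2 S(m1, m2) / (S(m1, m1) +
#' S(m2, m2))`. The measure is symmetric, handles motifs of different
#' lengths, and ranges from 0 (orthogonal base-frequency vectors) to 1
#' (identical motifs).
#'
#' @param m1,m2 `pwm` objects.
#' @return Similarity in `[0, 1]`.
#' @export
motif_similarity <- function(m1, m2) {
  stopifnot(inherits(m1, "pwm"), inherits(m2, "pwm"))
  2 * max_inner_product(m1, m2) /
    (max_inner_product(m1, m1) + max_inner_product(m2, m2))
}

max_inner_product <- function(m1, m2) {
  a <- unclass(m1)
  b <- unclass(m2)
  l1 <- ncol(a)
  l2 <- ncol(b)
  best <- -Inf
  for (d in seq.int(-(l2 - 1L), l1 - 1L)) {
    i <- seq_len(l1)
    j <- i - d
    ok <- j >= 1 & j <= l2
    s <- sum(a[, i[ok], drop = FALSE] * b[, j[ok], drop = FALSE])
    if (s > best) best <- s
  }
  best
}

#' Read and write PWMs in TRANSFAC-style matrix text
#'
#' A file holds one or more records: `NA <name>`, a `PO A C G T` header,
#' numbered count/frequency rows, and a `//` terminator.
#'
#' @param path File path.
#' @return `read_pwms()`: a named list of `pwm` objects.
#' @export
read_pwms <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != ""]
  out <- list()
  name <- NULL
  rows <- list()
  bases <- PWM_BASES
  flush <- function() {
    if (length(rows) > 0) {
      m <- t(do.call(rbind, rows)) # rows are positions -> 4 x L
      rownames(m) <- bases
      colnames(m) <- NULL
      out[[name %||% sprintf("motif_%d", length(out) + 1)]] <<-
        pwm(m, name = name %||% "motif")
    }
    rows <<- list()
  }
  for (ln in lines) {
    if (startsWith(ln, "NA")) {
      name <- trimws(sub("^NA\\s*", "", ln))
    } else if (startsWith(ln, "PO") || startsWith(ln, "P0")) {
      bases <- strsplit(ln, "\\s+")[[1]][-1]
    } else if (startsWith(ln, "//")) {
      flush()
      name <- NULL
      bases <- PWM_BASES
    } else if (grepl("^[0-9]", ln)) {
      vals <- as.numeric(strsplit(ln, "\\s+")[[1]][-1])
      rows[[length(rows) + 1]] <- vals
    }
  }
  flush()
  out
}

#' @rdname read_pwms
#' @param x A `pwm` or list of `pwm`s.
#' @export
write_pwms <- function(x, path) {
  if (inherits(x, "pwm")) x <- list(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in x) {
    writeLines(sprintf("NA %s", attr(m, "name")), con)
    writeLines("PO A C G T", con)
    mm <- t(unclass(m))
    for (i in seq_len(nrow(mm))) {
      writeLines(sprintf("%02d %.6f %.6f %.6f %.6f",
                         i, mm[i, 1], mm[i, 2], mm[i, 3], mm[i, 4]), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}
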