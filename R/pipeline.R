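# End-to-end pipeline: load -> filter -> windows -> mixture fit -> region
# selection -> peak fitting/scoring -> site extraction -> motif enrichment,
# with tabular/BED/FASTA outputs and a machine-readable run manifest.

#' Assemble a pipeline configuration
#'
#' Either pass a flat key-value YAML file or named arguments; arguments
#' override file values. Required: `fg`, `bg` (BAM/SAM or fragment-table
#' paths) and `out_dir`. Optional: `genome` (FASTA; required for site
#' sequences and motifs), `ncrna` (BED/GFF3), `pwms` (TRANSFAC-style file).
#'
#' @param path Optional YAML file of keys.
#' @param ... Overrides (see Details in [run_pipeline()]).
#' @return A list of class `clip_config`.
#' @export
run_config <- function(path = NULL, ...) {
  defaults <- list(
    fg = NULL, bg = NULL, genome = NULL, ncrna = NULL, pwms = NULL,
    out_dir = NULL,
    library_layout = "single", max_multimappers = 1L,
    window_size = 300L, step = 150L, fragment_size = 60L,
    fdr = 0.1, z_enrich = 2, anchor_kind = "crosslink", flank = 20L,
    runs = 5L, train_frac = 0.5, bg_per_site = 20L, seed = 1L
  )
  from_file <- if (!is.null(path)) yaml::read_yaml(path) else list()
  overrides <- list(...)
  cfg <- utils::modifyList(utils::modifyList(defaults, from_file), overrides)
  for (k in c("fg", "bg", "out_dir")) {
    if (is.null(cfg[[k]])) abort(sprintf("config key '%s' is required", k))
  }
  for (k in c("fg", "bg", "genome", "ncrna", "pwms")) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]])) {
      abort(sprintf("config path '%s' does not exist: %s", k, cfg[[k]]))
    }
  }
  structure(cfg, class = "clip_config")
}

#' Run the full peak-calling pipeline
#'
#' Executes the two-stage analysis (window enrichment model, then per-region
#' peak deconvolution), extracts binding sites, and, when a genome and PWM
#' file are configured, computes known-motif enrichments. All outputs are
#' written under `out_dir`: `windows.tsv`, `regions.bed`/`regions.tsv`,
#' `peaks.bed`/`peaks.tsv`, `sites.bed`/`sites.fa`/`sites.tsv`,
#' `motif_enrichment.tsv`, and `manifest.json` (parameters, fitted model,
#' stage counts). A run that finds no significant peaks is a success with
#' empty outputs.
#'
#' @param config A `clip_config` from [run_config()] (or a YAML path).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- run_config(config)
  stopifnot(inherits(config, "clip_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(parameters = unclass(config), stages = list(),
                   partial = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  fg <- stage("load_foreground", load_alignments(
    config$fg, config$library_layout, config$max_multimappers
  ))
  bg <- stage("load_background", load_alignments(
    config$bg, config$library_layout, config$max_multimappers
  ))
  if (!is.null(config$ncrna)) {
    fg <- stage("filter_ncrna", filter_ncrna(fg, config$ncrna))
    bg <- stage("filter_ncrna", filter_ncrna(bg, config$ncrna))
  }
  manifest$stages$reads <- list(fg = nrow(fg), bg = nrow(bg),
                                fg_weight = sum(fg$weight),
                                bg_weight = sum(bg$weight))

  genome <- if (!is.null(config$genome)) as_genome(config$genome) else NULL
  chrom_lengths <- if (!is.null(genome)) {
    setNames(Biostrings::width(genome), names(genome))
  } else {
    tapply(c(fg$end, bg$end), c(fg$chrom, bg$chrom), max)
  }

  windows <- stage("windows", make_windows(
    chrom_lengths, config$window_size, config$step
  ))
  counts <- stage("counting", count_windows(windows, fg, bg))
  fit <- stage("em_fit", em_fit(counts))
  scores <- stage("zscores", window_zscores(counts, fit))
  regions <- stage("select_enriched", select_enriched(
    scores, fdr = config$fdr, z_min = config$z_enrich
  ))
  z_threshold <- attr(regions, "z_threshold")
  manifest$stages$windows <- list(
    counted = nrow(counts), enriched = nrow(attr(regions, "windows")),
    regions = nrow(regions), z_threshold = z_threshold
  )
  manifest$model <- list(
    rho = fit$rho, sigma = fit$sigma, mu = fit$mu,
    delta_min = fit$delta_min, delta_max = fit$delta_max,
    loglik = fit$loglik, converged = fit$converged
  )

  peaks <- stage("peaks", call_peaks(
    regions, fg, bg, fit, config$fragment_size, seed = config$seed
  ))
  manifest$stages$peaks <- list(significant = nrow(peaks))

  readr::write_tsv(scores, file.path(config$out_dir, "windows.tsv"))
  readr::write_tsv(regions, file.path(config$out_dir, "regions.tsv"))
  write_bed(regions |> mutate(name = paste0("region_", region_id),
                              score = max_z),
            file.path(config$out_dir, "regions.bed"))
  peaks_bed <- peaks
  if (nrow(peaks_bed) > 0) {
    peaks_bed <- peaks_bed |>
      mutate(
        start = as.integer(pmax(0, floor(center - 2 * width))),
        end = as.integer(ceiling(center + 2 * width)),
        name = sprintf("peak_%d_%d", region_id, peak_id),
        score = z
      )
  }
  readr::write_tsv(peaks, file.path(config$out_dir, "peaks.tsv"))
  write_bed(peaks_bed, file.path(config$out_dir, "peaks.bed"))

  sites <- NULL
  if (!is.null(genome) && nrow(peaks) > 0) {
    sites <- stage("sites", extract_sites(
      peaks, fg, genome, anchor_kind = config$anchor_kind,
      flank = config$flank
    ))
    readr::write_tsv(sites, file.path(config$out_dir, "sites.tsv"))
    write_bed(sites |> mutate(name = sprintf("site_%d", site_id), score = z),
              file.path(config$out_dir, "sites.bed"))
    write_sites_fasta(sites, file.path(config$out_dir, "sites.fa"))
    manifest$stages$sites <- list(n = nrow(sites),
                                  anchor_kind = config$anchor_kind)
  }

  if (!is.null(config$pwms) && !is.null(sites) && nrow(sites) >= 2) {
    motifs <- stage("motifs", read_pwms(config$pwms))
    bg_seqs <- stage("background_sequences", background_sequences(
      scores, genome, n_fg_sites = nrow(sites),
      n_per_site = config$bg_per_site, size = 2L * config$flank,
      seed = config$seed
    ))
    enr <- purrr::list_rbind(purrr::map(motifs, function(m) {
      motif_enrichment(sites$sequence, bg_seqs, m, runs = config$runs,
                       train_frac = config$train_frac, seed = config$seed)
    }))
    readr::write_tsv(enr, file.path(config$out_dir, "motif_enrichment.tsv"))
    manifest$stages$motifs <- list(n_motifs = nrow(enr))
  }

  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(
    manifest, file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(manifest)
}

# BED6 with the score column scaled/clamped to 0-1000 (z * 100); the
# full-precision values live in the side tables.
write_bed <- function(x, path) {
  if (nrow(x) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed <- tibble(
    chrom = x$chrom,
    start = as.integer(x$start),
    end = as.integer(x$end),
    name = if (!is.null(x$name)) x$name else ".",
    score = as.integer(pmin(pmax(round((x$score %||% 0) * 100), 0), 1000)),
    strand = x$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
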