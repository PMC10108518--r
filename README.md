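# clipem

Peak calling and motif analysis for CLIP-seq data with an
enrichment-mixture model.

CLIP (crosslinking and immunoprecipitation) experiments sequence the RNA
fragments bound by a specific RNA-binding protein (RBP). The sequenced
immunoprecipitation (IP) library mixes true binding signal with abundant
non-specific background, so binding sites must be called **relative to a
background library** — a size-matched input (SMI) as in eCLIP, or RNA-seq.
`clipem` is for computational biologists analyzing such paired
foreground/background CLIP libraries who want an end-to-end, scriptable R
workflow: from aligned reads to enriched regions, individual binding
peaks, fixed-width binding-site sequences, and known-motif enrichment —
plus a generative simulator of the experiment that explains when crosslink
positions (read-start pile-ups) localize binding motifs better than
coverage-peak centers.

## The model

**Stage 1 — enriched regions.** The genome is tiled with sliding windows
(300 nt, step 150 nt, stranded) and weighted fragment counts are tabulated
per window in the foreground (n of N total) and background (m of M). For
unbound windows the log frequency ratio x = log(n/N) − log(m/M) follows

    P_u(n | N, m, M, σ, μ) = Normal(x; μ, 2σ² + 1/n + 1/m)

— multiplicative library noise (2σ²), Poisson counting noise (1/n + 1/m),
and a systematic IP depletion offset μ. Bound windows follow a uniform
density over the observed range of δ = n/N − m/M. The mixture weight ρ of
the unbound component and (σ, μ) are fitted by expectation–maximization,
windows are scored with z = (x − μ)/√(2σ² + 1/n + 1/m), and windows are
selected at a posterior-based FDR (≤ 0.1) with z > 2, then merged into
regions.

**Stage 2 — peaks.** Within each region, fragment midpoints are fitted
with a mixture of up to K_max = ⌊region length / fragment size⌋ Gaussians
plus uniform noise; peak pairs overlapping by more than half of the
smaller span lose their weaker member and EM continues; the best of
2·K_max restarts is kept. Peak z-scores are recomputed from the fragments
assigned to each peak.

**Sites and motifs.** Each significant peak yields a 41-nt site centered
on the coverage-peak center or on the *crosslink* (modal read start —
reverse transcriptase truncates at the crosslinked nucleotide, so read 5'
ends pile up next to it). Known motifs (PWMs) are scored by a
posterior-based enrichment of foreground sites versus sequences from the
least-enriched windows, with the site prior trained on a held-out split.
Peak sets are compared with a nucleotide-level Jaccard index; PWMs with
the offset-maximized similarity M(m1,m2) = 2S12/(S11+S22).

## Worked example

Everything runs tool-free from simulated data. `generate_fixture()`
plants 5 foreground-only peak clusters on a 30 kb chromosome over a
realistic noisy background shared with the background sample:

```r
library(clipem)

fx      <- generate_fixture(n_peaks = 5, genome_length = 30000, seed = 7)
windows <- make_windows(c(chrF = 30000))
counts  <- count_windows(windows, fx$fg, fx$bg)
fit     <- em_fit(counts)
fit
#> Enrichment mixture fit (EM)
#>   windows: 200   log-likelihood: -885.245   converged in 7 iterations
#>   rho = 0.9102   sigma = 0.0850   mu = -0.2648
#>   delta range: [-0.0135, 0.0466]
```

About 91% of windows are unbound (`rho`), the foreground is globally
depleted by e^−0.26 in unbound windows (`mu`), and the multiplicative
noise scale is ~0.09 (`sigma`). Calling peaks:

```r
scores  <- window_zscores(counts, fit)
regions <- select_enriched(scores, fdr = 0.1)
peaks   <- call_peaks(regions, fx$fg, fx$bg, fit, fragment_size = 60, seed = 7)
peaks
#> # A tibble: 6 × 10
#>   chrom strand region_id peak_id center width weight n_peak m_peak     z
#> 1 chrF  +              4       1 17550.    15  0.800  413.      16 11.8
#> 2 chrF  +              2       1  3149.    15  0.608  408.      16 11.8
#> 3 chrF  +              6       1 29550.    15  0.860  411.       8 10.8
#> 4 chrF  +              3       1 12451.    15  0.752  406.       6 10.2
#> 5 chrF  +              1       1   750.    15  0.865  407.       5  9.83
#> 6 chrF  +              5       1 21634.    15  0.235   12.9      1  2.61
```

The five planted positions (750, 3150, 12450, 17550, 29550) are each
recovered within ~1 nt; `n_peak`/`m_peak` are the weighted foreground and
background fragment counts behind each recomputed z. Fitted objects have
broom-style accessors (`tidy(fit)`, `glance(fit)`) and every result type
has an `autoplot()`/`plot_*()` method.

The simulator reproduces the anchoring contrast — at a readthrough
probability of 0.1, the modal read start sits 1 nt from the motif while
the fitted coverage center is ~15 nt downstream:

```r
sim <- simulate_clip(sim_config(rho_readthrough = 0.1, seed = 1))
dplyr::summarise(distance_summary(sim),
                 crosslink = mean(abs(d_crosslink)),
                 center    = mean(abs(d_center)))
#> # A tibble: 1 × 2
#>   crosslink center
#> 1         1   15.5
```

`run_pipeline(run_config(...))` chains all stages from files (BAM/SAM or
fragment tables) to BED/FASTA/TSV outputs and a JSON run manifest; a thin
command-line wrapper lives at `inst/scripts/clipem` (subcommands `run`,
`simulate`, `fixture`, `jaccard`, `motif-sim`, `motif-enrich`).

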