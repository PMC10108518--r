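---
title: "Peak calling for CLIP-seq with an enrichment mixture model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak calling for CLIP-seq with an enrichment mixture model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipem)
```

## The problem

Crosslinking and immunoprecipitation (CLIP) experiments map where an
RNA-binding protein (RBP) touches the transcriptome: UV light covalently
links the protein to RNA, unprotected RNA is digested, the protein is
purified with its bound fragments, and the fragments are reverse-transcribed
and sequenced. Read coverage in the immunoprecipitated (IP, "foreground")
library mixes true binding signal with abundant non-specific background, so
a matched background library — a size-matched input (SMI) in eCLIP, or
RNA-seq — is needed to tell them apart. `clipem` implements the full
inference chain from aligned reads to binding sites and motif enrichments,
plus a generative simulator of the experiment itself.

## Stage 1: window-level enrichment model

The genome is tiled with sliding windows (default 300 nt, step 150 nt, per
strand). Each fragment contributes its weight to every same-strand window
containing its midpoint, so one fragment is counted exactly once per tiling
phase and totals are conserved; multi-mapping reads carry weight
1/(number of reported alignments), so a read always contributes unit mass in
total. Windows with zero counts in both samples are dropped (they carry no
information and the log terms below are undefined there).

For a window with foreground count $n$ (sample total $N$) and background
count $m$ (total $M$), the unbound model says the log frequency ratio
$x = \log(n/N) - \log(m/M)$ is Gaussian:

$$P_u(n \mid N, m, M, \sigma, \mu) =
  \frac{1}{\sqrt{2\pi v}}
  \exp\!\left(-\frac{(x - \mu)^2}{2v}\right),
  \qquad v = 2\sigma^2 + \frac1n + \frac1m ,$$

where $2\sigma^2$ is multiplicative sample-preparation noise (each library
contributes $\sigma^2$ on the log scale), $1/n + 1/m$ approximates the
Poisson counting noise, and $\mu < 0$ captures the systematic depletion of
unbound windows in the IP (bound regions absorb read mass, so unbound
frequencies fall below their background values). Bound windows are modeled
as uniform over the observed range of the frequency difference
$\delta = n/N - m/M$:

$$P_b = \frac{1}{\delta_{\max} - \delta_{\min}} .$$

A pseudocount of 0.5 is added to $n$ and $m$ before any log or variance
term, identically in both samples — the standard half-integer continuity
correction; without it the model is undefined at zero counts.

**Mixing the two components.** $P_u$ is a density over the log ratio $x$
while $P_b$ is a density over $\delta$; mixing the printed formulas
directly compares densities on different measurement scales, and because
read frequencies are small numbers the uniform term then dominates every
window. Both formulas become a single consistent mixture once each is
expressed as a density over the observed count $n$, using the Jacobians
$\mathrm{d}x/\mathrm{d}n = 1/n$ and
$\mathrm{d}\delta/\mathrm{d}n = 1/N$:

$$P(n) = \rho\,\frac{P_u(x)}{n} + (1-\rho)\,\frac{P_b}{N} .$$

`em_fit()` fits $(\rho, \sigma, \mu)$ by EM: the E-step computes the
posterior probability that each window is unbound; the M-step sets $\rho$
to the mean posterior and maximizes the posterior-weighted Gaussian
log-likelihood over $(\mu, \sigma)$ numerically (no closed form exists
because $v$ depends on $\sigma$), with $\sigma \in [0, 10]$, convergence
tolerance $10^{-6}$ on the log-likelihood, at most 200 iterations, and
initialization $\rho = 0.9$, $\mu = \mathrm{median}(x)$,
$\sigma = \mathrm{MAD}(x)$. The total log-likelihood is non-decreasing
across iterations, which the tests assert on every fitted trace.

One behavior of this mixture is worth knowing: on data with *no* bound
windows at all, the $\delta$ range is set by the most extreme null windows
themselves, so the uniform component softly absorbs the tail order
statistics and $\hat\rho$ converges near (typically 0.96–0.99), not
exactly at, one. As soon as genuinely enriched windows exist, they dominate
the $\delta$ range, the uniform flattens by orders of magnitude, and this
absorption disappears — which is why parameter recovery on planted-peak
data is accurate.

### Scores, FDR, regions

Windows are scored with

$$z = \frac{\log(n/N) - \log(m/M) - \mu}{\sqrt{2\sigma^2 + 1/n + 1/m}},$$

the natural standardization of the $P_u$ exponent (natural logarithms
throughout; $\sigma$ and $\mu$ are scale-consistent under this choice).
Ranking windows by decreasing $z$, the false discovery rate of the top-$k$
set is estimated as the mean posterior probability of the unbound component
among those $k$ (a Bayesian local-FDR aggregate). The $z$ threshold is the
$z$ of the largest $k$ with FDR at or below the target (default 0.1);
selected windows must additionally satisfy $z > 2$. Overlapping selected
windows on one strand merge into maximal contiguous regions.

## Stage 2: peak deconvolution within regions

Within each enriched region, the weighted foreground fragment *midpoints*
are modeled as a mixture of $K$ Gaussians (one per binding event) plus a
uniform noise component over the region. Fragment midpoints give a proper
i.i.d. likelihood; per-nucleotide coverage, which smears each fragment over
its length, is kept for display and crosslink anchoring. The maximum number
of peaks is the region length divided by the expected fragment size,
$K_{\max} = \lfloor L / f \rfloor$. After each EM convergence the overlap
rule is enforced: when two peak spans (center $\pm 2$ sd) overlap by more
than half of the smaller span, the peak with less assigned fragment mass is
removed and EM continues from the pruned configuration. The procedure is
restarted $2 K_{\max}$ times (the first initialization places centers at
the highest local maxima of the 5-nt-smoothed midpoint histogram; later
restarts sample centers from the weighted midpoints) and the configuration
with maximum likelihood is kept. Widths are clamped to
$[f/4,\ L/2]$ to exclude single-point spikes and region-wide flats.
"Least significant" during pruning is judged by assigned fragment mass
rather than the final $z$, which is only computable after background
counting; $z$ is monotone in the assigned mass at fixed local background,
so the two orderings agree where the rule bites.

Each surviving peak is then re-scored: $n_{\text{peak}}$ is the
responsibility-weighted fragment mass of its component,
$m_{\text{peak}}$ the weighted background fragment mass with midpoint
inside the span, and the stage-1 $z$ formula is applied to
$(n_{\text{peak}}, N, m_{\text{peak}}, M)$ with the fitted $\mu, \sigma$.
Peaks at or above the FDR-derived threshold are reported.

## Binding sites and motifs

Sites span 20 nt on each side of an anchor (41 nt, clipped at contig
edges): either the rounded coverage-peak center, or the *crosslink* — the
modal read-start position within the peak span, because reverse
transcriptase frequently aborts at the crosslinked nucleotide so cDNA 5'
ends pile up one base downstream of it. Ties go to the position closest to
the peak center, then leftmost; the crosslink search is restricted to the
peak span so neighboring peaks cannot capture each other's read starts.
Overlapping same-strand sites are merged greedily from the top of the
$z$-ranking, keeping the best site verbatim (important for motif analysis).
Minus-strand sequences are reverse-complemented.

Motif occupancy uses a single-site, independent-offset posterior: at each
offset the motif likelihood is the product of PWM frequencies (floored at
$10^{-3}$ and renormalized, so zeros never null a product) and the
background likelihood the product of background base frequencies (estimated
from the pooled background sequences by default);
$P(\text{site}) = p L_w / (p L_w + (1-p) L_b)$. The prior $p$ is trained by
maximizing the independent-offset mixture likelihood on a held-out training
split of the foreground sites — training and evaluation never share
sequences. Enrichment is the mean posterior per scanned offset in the test
foreground divided by the same density in background sequences sampled from
the least-enriched windows (20 sequences of 40 nt per site by default),
repeated 5 times with fresh splits; the mean and sd over runs are reported.
Enrichment estimates from a few hundred sequences are stable for motifs of
moderate information content; for near-deterministic PWMs the density
ratio hinges on a handful of exact matches and is correspondingly noisy.

PWM utilities follow the field's conventions: per-column information
content $2 + \sum_b f_b \log_2 f_b$ bits, boundary-only trimming at 0.5
bits (the threshold unit is taken as bits), and the similarity
$M(m_1, m_2) = 2S_{12}/(S_{11} + S_{22})$ with
$S = \max_d \sum_i m_1(i) \cdot m_2(i-d)$, which is 1 for identical motifs
and 0 for orthogonal columns. The container keeps raw frequencies — the
$10^{-3}$ floor applies only inside likelihood scanning — so these boundary
values are attained exactly.

## The simulator

`simulate_clip()` generates the experiment forward: an RBP binds planted
motif instances, crosslinks at a nucleotide positioned upstream of, within,
or downstream of the motif, protects `protection_halfwidth` (default 15 nt,
a ~30 nt footprint) around the motif center, and RNase digestion leaves
geometric overhangs (mean 15 nt) beyond the protection, giving fragments
mostly 30–90 nt — typical of CLIP libraries. With probability
$1 - \rho_{\text{readthrough}}$ the reverse transcriptase truncates and the
read's 5' end sits one base downstream (in genome coordinates) of the
crosslinked nucleotide; otherwise the read starts at the fragment 5' end.
Only the plus strand is simulated; the analysis is strand-symmetric.

These defaults were chosen from the qualitative physics of the experiment,
not calibrated to any output: the truncation pile-up must compete with the
mode of the fragment-start distribution, and with a geometric overhang of
mean 15 even a 10% truncation fraction wins, which is what makes the modal
read start a robust crosslink estimator across the readthrough range. At
low readthrough the coverage is one-sided (reads run from the crosslink
downstream), so the Gaussian coverage center sits ~half a fragment
downstream of the motif while the modal read start stays within a base of
it; at high readthrough coverage becomes symmetric around the motif and
both anchors agree — the package's tests reproduce exactly this contrast.

`generate_fixture()` emulates the *data structure the window model
assumes*: per-block expression heterogeneity shared between samples
(log-normal, `sigma_shared`, cancels in the frequency ratio), independent
per-sample multiplicative noise (`sigma_noise` — the model's $\sigma$),
Poisson fragment counts, a global depletion `mu_offset` of unbound
foreground windows relative to nominal library sizes, and foreground-only
Gaussian fragment clusters at planted positions. Because a global scaling
of all foreground rates cancels when normalizing by the realized total, the
fixture reports nominal totals ($\text{depth} \times L$) in `totals`;
parameter-recovery analyses use those, while end-to-end peak recovery uses
realized totals (it does not depend on $\mu$). What the fixture does *not*
emulate: spliced or multi-mapping alignment ambiguity, sequence
composition bias, PCR duplication, overdispersion beyond log-normal
rates, and strandedness errors — so passing tests demonstrate correct
inference under the model's own assumptions, not robustness to every
artifact of real libraries.

## Numerical and design choices

- Coordinates are 0-based half-open everywhere internally; BED on disk;
  1-based SAM/BAM converted at the reader boundary. On the minus strand
  the read start is the alignment's rightmost coordinate (5' in transcript
  orientation).
- Multi-mapper weight is 1/(alignments of that read), so per-read weight
  sums to one regardless of the configured cap.
- ncRNA overlap filtering is strand-agnostic (contaminant fragments from
  abundant ncRNAs are frequently antisense-mapped) and removes every
  alignment of an overlapping read name.
- Transcriptome-vs-genome assignment: transcriptome wins iff its alignment
  score exceeds the genome score minus 3, preferring spliced isoforms on
  near-ties.
- EM for the window model and the peak mixtures both assert monotone
  likelihood; the peak EM drops components whose mass falls below
  $10^{-9}$ of the total.
- Degenerate inputs: fewer than two fragments in a region yield a single
  peak of width $f/2$ at the midpoint; an all-below-threshold PWM trims to
  its single most informative column with a warning; a window sample with
  zero total weight is an error naming the stage.
- Test problem sizes: parameter recovery uses 2,500 non-overlapping
  windows per fit (750 kb at 300 nt) at three parameter settings times
  three seeds — overlapping windows share reads, so the recovery
  assessment uses the non-overlapping phase where the model's independence
  assumption holds exactly; end-to-end recovery uses 30 kb fixtures with
  five planted peaks; the simulator contrast uses 2,000 molecules per
  site.

## Known limitations

- The FDR estimate is model-based (mean unbound posterior); on a pure null
  the single most extreme window can pass the filter because it defines
  the $\delta$ range itself. Downstream peak re-scoring usually removes
  it; the null-calibration test allows at most that one window.
- Replicate combination and IDR-style reproducibility scoring are out of
  scope; replicates are analyzed separately and compared with
  `jaccard_nt()`.
- De novo motif discovery is not included; supplied PWMs are scored.
  Crosslink-induced mutations (PAR-CLIP style) are not modeled.
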