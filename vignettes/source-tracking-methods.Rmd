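---
title: "Bayesian source tracking for degraded 16S communities: model and methods"
author: "sourcemixr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian source tracking: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sourcemixr)
```

## The problem

A degraded faecal or environmental sample (the *sink*) yields a 16S
amplicon community of uncertain provenance: some fraction derives from
the original gut community, the rest from soil, handling, laboratory
reagents, or environments nobody has characterized. `sourcemixr`
estimates, for each sink, the mixing proportions over a set of
well-characterized *source* environments plus an explicit *Unknown*
environment that absorbs taxa no source explains. The approach is the
Bayesian source-tracking mixture model with collapsed Gibbs sampling,
wrapped in the supporting pipeline a degraded-sample study needs: read
QC, OTU assignment, taxonomy collapsing, table merging, rarefaction,
hyperparameter calibration, confidence flags and contamination checks.

## The mixture model

Each of the sink's $N$ reads carries a latent environment assignment
$z_i \in \{1, \dots, V, \mathrm{Unknown}\}$. Integrating out the
mixing proportions (symmetric Dirichlet prior with pseudocount
$\beta$) and each environment's taxon distribution (Dirichlet with
pseudocount $\alpha_1$ for known sources, $\alpha_2$ for Unknown), the
collapsed full conditional for read $i$ of taxon $t$ is

$$
p(z_i = v \mid \cdot) \;\propto\;
\frac{m_{vt} + n^{-i}_{vt} + \alpha_1}
     {m_{v\cdot} + n^{-i}_{v\cdot} + T\alpha_1}
\,\bigl(n^{-i}_{v} + \beta\bigr),
$$

where $m_{vt}$ are the source's pooled training counts and
$n^{-i}_{vt}$ the sink reads currently assigned to $v$ (excluding read
$i$). The Unknown environment uses the same form with $m \equiv 0$ and
$\alpha_2$ in place of $\alpha_1$: it has no training data and builds
its emission distribution entirely from the sink reads it claims, so
it self-reinforces once it captures a coherent block of otherwise
unexplained taxa.

Including the currently assigned sink counts in the known-source
emission term is the collapsed-sampler convention; setting
`trainingOnly = TRUE` in `gibbsConfig()` switches to fixed,
training-only emissions so the assumption stays auditable.

### Fitting schedule and confidence

`fitMixture()` runs 25 independent restarts by default. Each restart
initializes assignments i.i.d. uniformly over the $V+1$ environments,
performs 1,000 full sweeps of the conditional in fixed read order
("burn-in"), and records a single draw: the fraction of reads assigned
to each environment. We report the across-restart mean and standard
deviation; if any environment's SD exceeds `sdThreshold` (default
0.15) the estimate is flagged low-confidence. This flag captures the
multimodality that matters in practice — for example a sink that is
"all Unknown" in most restarts but "mostly compost" in a few is
genuinely ambiguous, and the draw matrix (reordered by
nearest-neighbour chaining in `summarizeRestarts()`) shows it
directly.

We chose the empirical assignment fraction $n_v/N$ rather than the
smoothed posterior mean $(n_v+\beta)/(N+(V{+}1)\beta)$ as the
per-restart draw; with $N$ in the hundreds-to-thousands the difference
is negligible and the empirical fraction keeps draws interpretable as
read allocations.

Whether "burn-in iterations" means full sweeps or single-read updates
is ambiguous in most descriptions of this sampler family; we implement
full sweeps, the stricter reading.

### Seeding

Every stochastic routine takes one master seed and derives child seeds
with a single documented splitter (`set.seed(master)` followed by
`sample.int`): one child per restart, per pipeline stage, per sink.
Fixing the master seed fixes every output byte for byte.

### Hyperparameters

* `alpha1` (default 0.001): smoothing of known-source emissions.
  Training totals are typically $10^3$–$10^5$ reads, so this only
  matters for taxa a source has never exhibited.
* `alpha2` (default 0.00415): the Unknown environment's pseudocount
  per taxon, its only prior mass. Larger values raise the floor
  probability with which Unknown claims taxa it has not yet absorbed,
  making it more absorbent; too large and it steals mass that a
  genuine source explains. Because the right value is data-dependent,
  `calibrateAlpha2()` exists (below); the default sits in the range
  such screens select in practice.
* `beta` (default 10): Dirichlet pseudocount on mixing proportions;
  weakly informative at typical sink depths.

## Calibrating alpha2 by leave-one-source-out

An Unknown environment is only useful if it, not a sibling source,
absorbs mass that belongs to no training source. The identifiability
screen in `calibrateAlpha2()` therefore refits each calibration sink
with each source environment removed from the training data, at each
candidate $\alpha_2$, reusing identical seeds so differences reflect
$\alpha_2$ alone. Removing a source must not cause any *remaining*
source's mean proportion to rise by more than `epsilon` (default
0.05) plus one across-restart SD — removed mass should flow to
Unknown. The chosen value is the **largest** candidate passing for
every removed source and sink, keeping Unknown maximally absorbent
without source confusion. Raw zero-increase would be unattainable
under Monte-Carlo noise, hence the tolerance; the SD term absorbs
restart variability at small sink depths.

The default grid spans $10^{-4}$ to $10^{-1}$ in 7 log-spaced steps
and includes 0.00415 and 0.01. Which sinks to calibrate on is the
caller's choice (default: all supplied sinks jointly).

## The supporting pipeline

**Read QC** (`runReadQC()`): inclusion requires an *exact* barcode
match (reads with any barcode mismatch are unassigned), an *exact*
forward-primer match, mean per-read Phred strictly over 25, and a
post-trim length of at least 130 bases. The quality rule is applied to
the mean (a per-read statistic typical of pyrosequencing-era
pipelines; `qualityStat = "min"` is available since the historical
record rarely says which was used), and "over" is honored strictly: a
read at mean 25.0 exactly is dropped. Length is measured after barcode
and primer removal. The reverse primer is trimmed when present at the
3' end but its absence alone does not reject, because
single-direction reads often terminate before the distal primer.

**OTU assignment**: `clusterOTUsDeNovo()` is a deterministic greedy
centroid clusterer (decreasing abundance, ties by label, first
centroid at or above the identity threshold wins; default 0.99) —
a documented stand-in for heavier external clusterers, sufficient for
and faithful to the pipeline's contract. `assignClosedReference()`
maps queries to the best reference at $\ge$ 0.97 identity, inclusive
at the boundary, ties to the earlier reference. Identity is matches /
aligned columns under global alignment with free end gaps (match +1,
mismatch −1, gap −2) — the natural choice for short homologous
amplicons, and configurable.

**Taxonomy collapsing and merging**: `collapseTaxonomy()` sums counts
within lineages truncated at the requested rank; features missing from
the taxonomy map collapse into a reserved `Unassigned` bin rather than
being dropped, so per-sample totals are conserved exactly — the
property every downstream proportion depends on. `mergeTables()`
unions taxon indices and concatenates samples; species-level
collapsing before merging is what lets data sequenced over different
16S regions share one table.

**Rarefaction**: `rarefyTable()` subsamples without replacement
to a fixed depth, 10,000 by default in the
tracking pipeline; samples below the target are kept at full depth and
flagged, rather than dropped. `richnessCurve()` gives Monte-Carlo
rarefaction curves whose expectation has the hypergeometric closed
form $\sum_t \bigl[1 - \binom{N-N_t}{d}/\binom{N}{d}\bigr]$, exposed
as `expectedRichness()`. `depthRobustness()` refits the mixture at
depths 500–5,000 to confirm conclusions are depth-insensitive.

**Community description**: `phylumProfiles()` computes per-sample
relative abundances with a 5% display floor — masking, not
renormalizing, so conservation stays testable; `clusterProfiles()`
performs hierarchical clustering (Euclidean, complete linkage by
default, both configurable) on the *full* unmasked vectors;
`otuSharing()` reports exact presence/absence intersection
cardinalities, the quantities a Venn–Euler display encodes (the
geometric layout is out of scope).

## The synthetic test bed

`simConfig()` and its generators define the closed-loop validation
conditions. Source profiles are symmetric-Dirichlet draws
(concentration 0.5, giving the skewed few-dominant-taxa shape typical
of 16S surveys) over per-source preferred taxon blocks, mixed with a
shared background at weight $1 - \mathrm{separation}$: one knob runs
from fully confusable (0) to disjoint-support (1) sources. Sinks are
built read by read — a multinomial draw over the true mixing
proportions assigns each read to a component, then its taxon is drawn
from that component's profile — and the recorded ground truth is the
*realized* allocation, the achievable target for recovery tests. The
out-of-training "unknown" component is simply one more generated
profile that never enters training. Defaults (200 taxa, 5 sources, 5
training samples per source, depths 500–10,000) bracket the scale of
a merged multi-study 16S table.

The generator does **not** simulate chimeras, homopolymer or
ancient-DNA damage patterns, read-length variation, or compositional
correlations between sources beyond the shared background. Passing
tests therefore demonstrate correctness of the estimator and pipeline
under the stated generative model, not robustness to every artifact of
real degraded samples.

## Numerical and design choices

* The Gibbs inner loop is implemented in C++ (Rcpp) and consumes R's
  RNG stream, so results are reproducible through `set.seed()` alone.
* `exactPosterior()` enumerates all $(V{+}1)^N$ assignments with
  sequential Dirichlet-multinomial predictive weights (exchangeable,
  hence order-invariant) and is the sampler's independent oracle for
  $N \le 8$, $V \le 3$.
* Draw-matrix reordering minimizes adjacent-row Euclidean distance by
  greedy nearest-neighbour chaining over all starting rows, never
  returning an ordering longer than the input's; ties break to the
  lowest index.
* Degenerate inputs are rejected with named-parameter messages (empty
  sinks, zero-total samples in profiles, depth 0, duplicate barcodes
  or sample ids, removal of the last source).
* Validation problem sizes: the test suite checks sampler/oracle
  agreement on instances up to $N = 6$ reads, recovery on 20 sinks per
  depth × separation scenario at the default 1,000-sweep, 25-restart
  schedule, and calibration on a planted twin pair (0.85 similarity);
  `scripts/acceptance.R` re-runs the same checks at 10 sinks per
  scenario.

## Known limitations

* The greedy OTU clusterer is quadratic in sequence count and meant
  for the package's pipeline contract, not for millions of raw reads.
* Proportion estimates are per-sink; per-taxon source attribution is
  deliberately not produced.
* The calibration screen shares seeds across candidates but is still
  Monte-Carlo: near the pass/fail boundary the chosen alpha2 can move
  between adjacent grid points across master seeds.
* With strongly overlapping sources (separation well below 0.9) the
  mixture is weakly identified; the restart-SD flag reports this
  rather than hiding it.
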