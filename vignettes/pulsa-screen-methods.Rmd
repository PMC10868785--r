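---
title: "Simulating and scoring pulse-shape FACS CRISPR screens"
author: "pulsaScreen maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scoring pulse-shape FACS CRISPR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsaScreen)
```

# The screen this package models

Pooled CRISPR knockout screens read out a phenotype by sorting a
guide-carrying cell population into phenotypic bins and sequencing the sgRNA
cassettes of each bin. Here the phenotype is the formation of a protein
inclusion reported by a fluorescent aggregation reporter, and the sorter
distinguishes inclusion-bearing from diffuse cells by Pulse Shape Analysis
(PulSA): at equal total fluorescence, a cell whose reporter is concentrated
in a punctum produces a taller and narrower fluorescence pulse (height
FITC-H, width FITC-W) than a cell with diffuse signal. Sorting the extreme
tails of the pulse-shape distribution yields an aggregate-positive and an
aggregate-negative pool; a guide whose knockout promotes inclusion
formation is enriched in the positive pool.

`pulsaScreen` provides the full loop as testable code: a generative model
of the screen (library, planted gene effects, single-guide cells, optics,
gates, sequencing), and the scoring algorithm that turns sgRNA counts into
per-gene phenotypes, permutation p-values and hit calls. Because no raw
sequencing data are public for the screen this models, the package's
validation is property-based: a fully null screen must produce uniform
p-values, planted regulators must be recovered, and every numerical core is
held against an independent oracle.

# Generative model

## Library and cell population

`generateLibrary()` builds a Brunello-like library: a chosen number of
genes at 4 guides per gene plus 1000 non-targeting controls (NTCs), each
with a unique random 20-nt spacer. `assignEffects()` plants positive and
negative regulators: gene effects are additive shifts on the log-odds that
a cell forms an inclusion; the NTC sentinel is exactly 0. Each guide gets a
knockout efficacy — the probability that an infected cell actually loses
gene function — which collapses editing efficiency and selection time into
a single number (no temporal dynamics are modelled).

`simulatePopulation()` draws one guide per cell (low multiplicity of
infection is assumed to hold exactly; the screen titered virus to ~30%
survival precisely to approximate this), with per-guide abundances
log-normally dispersed (sigma 0.5 by default) to emulate library skew.
A cell aggregates with probability

$$P(\text{aggregated}) = \operatorname{logit}^{-1}(\beta_0 + e_g \cdot K),$$

where $\beta_0$ is the baseline log-odds, $e_g$ the planted effect of the
cell's gene and $K \in \{0,1\}$ the knockout outcome. Reporter expression
is log-normal. Aggregated cells draw a latent *punctate fraction* $f$ — the
share of reporter fluorescence concentrated in the inclusion — from a
Beta(5, 2) scaled into [0.3, 0.95]; diffuse cells have $f = 0$. The Beta
parameters are a synthetic choice giving a clearly separable pulse-shape
signal, not a measured quantity.

The baseline inclusion probability is not reported for the real reporter
line, so it is a free parameter; the default is 0.25, a realistic value
for an overexpressed aggregation-prone reporter. A practical side effect of
a moderate baseline is that planted effects change a guide's pool
representation by at most $1/0.25 = 4$-fold, so hit guides do not all pile
into the extreme of the abundance ranking used by the local-Z correction
(see below).

## Pulse model

`acquirePopulation()` treats the cytometer explicitly, since the real
instrument is a black box: a cell crosses a Gaussian interrogation beam
(sigma $\sigma_b$, default 2 µm) at constant speed. Diffuse fluorophores
have spatial sigma $\sigma_c = 0.3 \times \text{diameter}$ (diameters
log-normal around 15 µm); an inclusion is a near-point source
($\sigma_p = 0.5$ µm). The noiseless pulse is the two-component Gaussian
mixture

$$s(t) = (1-f)\,F\,\phi(t; \sigma_1) + f\,F\,\phi(t; \sigma_2),
\qquad \sigma_i^2 = \sigma_b^2 + \sigma_{c,p}^2,$$

with $F$ total fluorescence and $\phi$ a normalized Gaussian density in
transit time. Consequences used by the tests: the **area** equals $F$
exactly (linearity), the **height** is $\sum_i w_i F /(\sqrt{2\pi}\sigma_i)$
— for beam sigma 1, diffuse sigma 2 and a point-source inclusion the
punctate/diffuse height ratio is exactly $\sqrt{5}$ — and the **width**,
defined as the time the signal exceeds an absolute trigger threshold, is
found by vectorized bisection (64 iterations; the mixture is unimodal).
Width is deliberately *not* full-width-at-half-maximum: FWHM is invariant
to $F$ and would erase the height-versus-width contrast the gate exploits.
Gaussian noise (sd 1 signal unit) is added to the height only; a pulse that
never crosses the trigger reports width 0 and is flagged, not dropped with
an error.

## Gating and sequencing

`gateExpression()` keeps cells inside a closed quantile interval of pulse
area (default [0.25, 0.75]), mirroring sorting within a narrow window of
transgene expression to decouple expression level from aggregation; the
order-statistic convention (lower bound `max(1, ceiling(q_lo n))`-th
smallest, upper `ceiling(q_hi n)`-th) is normative and tested.
`calibratePulsaGates()` gates on the 1-D discriminant $r = h/w$: the real
sorter used a hand-drawn two-dimensional region whose geometry is not
published, so a ratio-quantile gate is a stated substitute that reproduces
"about 5% per tail" determinately. Boundary records belong to the gate.
Each sorted pool is split into technical replicates (the screen split each
collected pool in two before DNA extraction), and sequencing is modelled
either as multinomial read sampling of the pool tallies
(`sequencing$mode = "counts"`) or as full FASTQ synthesis with per-base
substitution errors and flank-anchored spacer extraction
(`mode = "reads"`; `synthesizeReads()`, `extractSpacers()`,
`countSpacers()`). The two modes are statistically identical at error rate
0, which the round-trip tests verify; counts mode is the default because
string synthesis adds cost without adding information for scoring studies.
Spacer matching is deterministic (exact, or unique Hamming-distance-1
assignment with ambiguous reads dropped, never split) rather than
delegating to an external aligner, since mapping here only counts 20-mers.

# Scoring algorithm

Given a count matrix with an aggregate-positive and aggregate-negative
sample per replicate, `scoreScreen()` composes:

1. **Normalization** (`normalizeCounts()`): per sample,
   `counts / mean(counts) * 1e6 + 1`. "Sample mean" is read literally as
   the mean count per guide; since any per-sample rescaling cancels in the
   fold change, the distinction from total-count scaling is cosmetic, but
   the choice is fixed and tested. The pseudocount is added *after*
   scaling, per the stated order of operations.
2. **Fold change** (`guideLfc()`): $\log_2$ of the normalized
   positive/negative ratio. Base 2 matches an LFC hit threshold of 1.
3. **Local Z** (`localZ()`): guides are ranked by the mean of their two
   normalized abundances; each guide's LFC is standardized against the
   mean and sample SD of the 2000-guide window centred on it. This removes
   the strong abundance dependence of fold-change variance (low-count
   guides are noisier). Numerical conventions, all tested: windows are
   shifted inward at the edges so they always contain exactly 2000 guides
   (a shrinking window would re-introduce variance differences); the focal
   guide is included in its own window (a flag exposes the alternative,
   which changes z by O(1/window)); ranking ties break by guide id; a
   zero-SD window yields z = 0; the implementation uses centred cumulative
   sums and is required to agree with a naive double loop to 1e-10.
4. **Replicate aggregation** (`aggregateReplicates()`): the unweighted mean
   of per-replicate LFC and local Z per guide. The source analysis says
   only that replicates were "aggregated"; the mean is the simplest
   faithful reading, and pooling counts or Stouffer-combining z are easy
   to add behind the same interface.
5. **Phenotype** (`genePhenotype()`): the mean signed local Z of the two
   guides with the largest |local Z| (ties by guide order); single-guide
   genes pass through flagged.
6. **Permutation p-value** (`genePvalue()`): the observed statistic is the
   mean local Z over all of a gene's guides; the null is the distribution
   of means of equally many z-values drawn without replacement from the
   pool of targeting-guide z-values — i.e. permuting guide-to-gene
   assignments. One null of `n_perm` draws (default 100,000; the
   sampling loop is compiled C++ using R's RNG) is shared per gene-size
   class, which is statistically identical to per-gene nulls and ~100x
   cheaper. P-values are two-sided on |mean z| with add-one smoothing, so
   the smallest attainable value is $1/(n_{perm}+1)$; when
   $\binom{N}{s}$ is small (cap 5000) all subsets are enumerated and the
   exact tail fraction is returned. Two-sidedness reflects that hits are
   reported in both directions; NTC guides are kept in the abundance
   ranking (they behave like any other cassette on the sequencer) but
   excluded from the permutation pool by default — both choices are config
   flags, since the source analysis specifies neither.
7. **Hit calling** (`callHits()`): p < 0.005 and |phenotype| > 1, with the
   sign of the phenotype separating more-aggregation from less-aggregation
   hits. Raw p-values are thresholded, matching the source analysis; no
   multiple-testing correction is applied by default.
8. **NTC calibration** (`ntcPseudogenes()`): consecutive groups of 4 NTC
   guides are scored exactly like genes; in a well-calibrated screen their
   p-values are uniform and essentially none pass the hit thresholds.

# Study conditions used by the tests

The default configuration is the package's statement of the screen's
conditions: 4 guides per gene, 1000 NTCs, 20-nt spacers, 1000x cell
coverage of the library, ~5% collected per sort tail, a [0.25, 0.75]
expression gate, two technical replicates, 500 reads per guide, a
2000-guide window and 100,000 permutations (the acceptance analyses reduce
`n_perm` to 20,000, which bounds attainable p-values at 5e-5, ample for a
0.005 threshold). The synthetic screens use 2000 genes — large enough for
stable calibration statistics, small enough for desk-scale runs; the
recovery study plants 25 positive and 25 negative regulators.

Planted magnitudes are calibrated to the local-SD scale of the scoring
statistic itself: effects of 4 log-odds units at full efficacy shift guide
LFCs by well over 3 window-SD units (the separable regime — every planted
gene must be recovered at p < 0.005 with |phenotype| > 1 and rank above
every null gene), while 1.4 log-odds units at 50% efficacy realize shifts
of about 1.5 window-SDs (the noisy regime, where rank-based recovery above
AUROC 0.95 is the requirement). A reduced smoke configuration (200 genes,
window 200, 1000 permutations, ~100,000 reads per sample, full FASTQ
mode) exercises the whole pipeline, including byte-identical
reproducibility of every artifact under a fixed seed.

# What the generator does and does not emulate

Emulated: library skew, low-MOI single-guide infection, incomplete
knockout, expression spread and expression gating, the height/width
contrast between punctate and diffuse cells, finite sort yield per tail,
technical-replicate splitting of sorted pools, multinomial sequencing and
substitution errors in reads.

Not emulated: fitness effects and guide dropout over the selection window
(the screen sorts a single timepoint), cell-cycle or growth heterogeneity,
doublets and sorter impurities beyond the pulse model, optical
compensation/spillover, the autofluorescence channel, indel spectra or
quality-score structure in reads, and real sorter gate geometry (a 2-D
polygon is replaced by the r = h/w quantile gate). Passing the recovery
tests therefore shows that the scoring algorithm is correct and calibrated
under the stated generative assumptions — not that any particular
biological screen was free of these unmodelled effects.

# Numerical and degenerate-input conventions

* Zero fluorescence yields the pulse (0, 0, 0); a trigger threshold above
  the pulse peak yields width 0, flagged in QC and excluded from gate
  calibration.
* An all-zero count sample is an error (normalization is undefined); a
  zero count in a positive sample normalizes to exactly the pseudocount.
* `localZ` clamps a window larger than the number of guides to n with a
  warning; fewer than 2 guides is an error.
* Empty expression-gate input returns empty output; a tail fraction whose
  record count rounds to zero returns empty (infinite-threshold) gates.
* Extraction failures are data (`flank_not_found`, `truncated`,
  `right_flank_mismatch`), and the counting QC categories partition reads
  by construction.
* All stochastic stages draw from streams derived from one master seed via
  `stageSeed()`, so stages can be rerun independently and whole runs are
  bit-reproducible; permutation draws use R's RNG from compiled code.

# Limitations

The pulse model is a deliberate idealization (Gaussian beam, at most one
effective punctum, no saturation); it is meant to give the gate a
physically sensible, analytically checkable contrast, not to emulate a
specific instrument. The hit thresholds are the source analysis's
conventions, not estimates; with 2000 genes a p < 0.005 cutoff implies ~10
null genes passing the p criterion alone, which is why the phenotype
threshold and the NTC pseudo-gene calibration matter. Single-guide genes
are scored but flagged; their phenotype rests on one measurement.
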