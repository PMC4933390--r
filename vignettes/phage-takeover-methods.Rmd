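---
title: "Models and methods: dissecting a lytic phage infection from kinetics, dual RNA-seq and metabolomics"
author: "phageTakeover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phageTakeover)
```

# Scope

A virulent bacteriophage infecting a bacterial host rewires the cell in
minutes: virions adsorb, intracellular progeny assemble (eclipse), the
cell lyses (latency), and in parallel the phage replaces the host's
mRNA pool with its own transcripts while redirecting metabolism.
phageTakeover implements the full quantitative workflow for such an
experiment — growth-curve kinetics, dual-genome differential
expression, coverage-based RNA-feature discovery, k-mer target
scanning, and time-course metabolomics — together with seeded
simulators that generate every input with a ground-truth record, so
each stage's recovery behaviour is testable end to end.

# Growth kinetics

## The logistic model

One-step growth titers are modelled as

$$f(x) = b + \frac{a}{1 + e^{-k (x - x_c)}}$$

with asymptote $a$ (pfu/mL), inflection abscissa $x_c$ (minutes, the
mean infection-cycle duration for the curve of released phage), slope
$k$ (1/min) and a fixed floor $b$. Eclipse and latency are the first
times each arm's logistic component exceeds 5% of its asymptote,
available in closed form as $x_c - \ln(1/0.05 - 1)/k$
(`thresholdCrossingTime()`): the +CHCl3 arm (chloroform lyses infected
cells and releases assembled virions) yields the eclipse, the -CHCl3
arm (spontaneous release) the latency.

Because titers span orders of magnitude, the least-squares fit is run
on log10 titers (`fitLogistic()`), with multi-start initialisation:
$a_0$ from the maximum titer, $x_{c,0}$ at the steepest log-titer
increase, and a grid of slope starts augmented by a slope estimate read
off the exponential phase. Fits are bounded ($k > 0$, $x_c$ within the
observed range extended by 50%) and the best residual norm wins;
standard errors come from the fit covariance (delta method for $a$).

The fixed floor $b$ deserves a note. Measured one-step curves do not
start at zero: the -CHCl3 arm sits on the infective-centre plateau
(~1e6 pfu/mL here) and the +CHCl3 arm on residual free phage. A pure
three-parameter logistic fitted on the log scale is badly distorted by
that plateau, while on a linear scale the plateau is simply invisible
(2% of the asymptote). Fitting $b$ + logistic with $b$ fixed at the
estimated pre-rise plateau (`baseline = "auto"`, used by
`summarizeGrowth()`) keeps the log-scale fit and reduces exactly to the
plain logistic when $b = 0$, which is what all exact-recovery tests
use.

Burst size is deliberately not taken from the fits: it is the raw
arithmetic `mean(final titers) / (initial -CHCl3 titer - initial
+CHCl3 titer)` (`burstSize()`) — released progeny per infective
centre — and is scale-invariant in the titers. Degenerate inputs are
first-class: flat series return a flagged non-converged fit, titers at
or below detection are dropped with a warning rather than imputed, and
growth parameters are estimated per replicate and summarised as
mean ± SD.

Adsorption assays are an exponential free-phage decay
$p(t) = p_0 e^{-\lambda t}$ fitted by linear regression on log titers
(`fitAdsorption()`); the second-order adsorption rate constant is
$k_a = \lambda / \text{cell density}$ (mL/min) and the 90%-adsorption
time is $\ln(10)/\lambda$, so their product is $\ln 10$ by
construction — one of the invariants under test.

# Dual-genome differential expression

## Why per-genome normalization

During takeover the read pool shifts from ~100% host to ~90% phage.
Any normalization across the joint pool would conflate that global
swing with per-gene regulation. The package therefore computes
median-of-ratios size factors from exactly one genome's features at a
time (`sizeFactorsGenome()`): host contrasts are normalized on host
features only, phage contrasts on phage features only, and rRNA-class
features are excluded throughout (the libraries are rRNA-depleted;
residual rRNA is carried in the container but never enters takeover or
testing). This makes a hard contract — adding or removing features of
one genome can never change the other genome's size factors, test
statistics or multiple-testing adjustment — which the test suite
asserts literally, and it means host fold-changes are *relative to
other host genes*. `relativeHostShift()` converts them to
absolute-abundance shifts by dividing by the global host-depletion
factor (`hostDepletionFactor()`, the ratio of mean host read fractions
between two timepoints), so a gene whose relative enrichment exceeds
the global depletion is genuinely accumulating.

## The testing engine

The engine is a self-contained negative-binomial Wald pipeline rather
than a wrap of an existing DE package: the normalization design, not a
particular shrinkage estimator, is the scientific contract here, and a
compact transparent implementation keeps that contract checkable.
Counts are modelled as NB with variance $\mu + \alpha\mu^2$.
Per-feature dispersions are method-of-moments estimates from
normalized counts, pooled within conditions, and shrunk halfway
towards a fitted mean-dispersion trend $\alpha_{tr}(\mu) = a_0/\mu +
a_1$ (`estimateFeatureDispersions()`); the weight (0.5) trades the
noise of 3-replicate moments against per-feature signal. Each feature
is then fit by a GLM with log link, condition indicator and log size
factors as offset (`stats::glm` with the `MASS` NB family; Poisson for
vanishing dispersion), and the Wald statistic is referred to a t
distribution with the model's residual degrees of freedom. The t
reference is a deliberate small-sample choice: with plug-in moment
dispersions at 2–3 replicates the usual normal reference is
anticonservative, while the residual-df t keeps the empirical type-I
error at the nominal 5% level in the package's null simulations
(2000 NB features, 3 vs 3). Benjamini–Hochberg adjustment runs
separately per genome and contrast, matching the independence logic;
all-zero features carry NA statistics and stay out of the adjustment
denominator.

Two presets mirror common reporting choices: `default` (adjusted
p < 0.05) and `paper-host-strict` (|log2FC| > 1.3 with raw p < 0.05)
for stringent host screens.

## Temporal classes

Phage genes are classed from the early-vs-late contrast
(`classifyTemporal()`): early if significantly higher early, late if
significantly higher late. The mid-infection timepoint is a single
descriptive sample, so "middle" is an operational rule, not a test: a
feature that is neither early nor late but whose normalized
mid-timepoint expression is at least twice both flanking condition
means. With no mid sample the class is disabled with a warning.
Windowed (250-bp, both strands, last partial window kept) counting is
available through `binGenome()`/`binCoverageCounts()` for
annotation-free views of phage transcription.

# RNA features from stranded coverage

The callers operationalise what is usually manual strand-aware
coverage curation; every threshold is an exposed parameter with the
defaults below, calibrated on the synthetic suite (the counts of
features reported for any particular real genome are not reproduction
targets).

* `callIntergenicSrna()` — runs of depth ≥ 20 on one strand, merged
  across gaps ≤ 10 bp, 50–500 bp long, overlapping no same-strand CDS.
  By default calls inside opposite-strand genes are also suppressed
  (`intergenicOnly = TRUE`): such signal is antisense territory, and
  the rule keeps the sRNA and asRNA classes disjoint.
* `callAntisense()` — within each annotated gene, opposite-strand runs
  with depth ≥ 20, antisense/(sense+1) ratio ≥ 0.1 and length ≥ 100,
  split small/long at 300 bp.
* `callRiboswitchCandidates()` — the attenuation signature: a
  same-strand intergenic block starting ≥ 70 bp before a gene's 5' end
  (a "significant distance"; 70 bp is a documented default, not a
  literature value), ending within 20 bp of the gene start (it must be
  that gene's leader), whose mean depth exceeds 3x the mean depth in
  the first 30 bp of the CDS. The end-gap requirement is an
  operational addition that prevents any strong intergenic block
  upstream of a gene from being mistaken for its leader.

Coverage is consumed per sample; replicate tracks of a timepoint
should be averaged before calling to suppress single-replicate noise.
`differentialFeatureExpression()` integrates each sample's coverage
over the calls (depth sum / read length) and delegates to the NB Wald
pipeline, attaching fold-changes and adjusted p-values to the calls.
`evaluateCalls()` scores calls against a planted truth by class,
strand and 50% reciprocal overlap.

`scanKmers()` performs exact k-mer matching (default k = 11) of a
small-RNA query against both strands of a target genome, skipping
k-mers containing N, deduplicating by (position, strand, k-mer), and
annotating hits with overlapping features (e.g. "within tRNA").
Sub-feature structural placement (such as position within a tRNA's
T-loop) would require secondary-structure input and is out of scope.
The implementation is checked against a naive sliding-window oracle
and a reverse-complement mirror property.

# Metabolomics

Ion intensities arrive as a strictly positive matrix over timepoints x
biological x technical replicates (default design 6 timepoints x 4
bio x 2 tech). Technical repeats are averaged to biological-replicate
means (`collapseTechnical()`, with an error listing any missing
cells). For each timepoint versus time zero, `differentialIons()`
reports the log2 ratio of mean intensities and a Welch test
(`welchTest()`, unequal variances, Satterthwaite df) on
log-transformed bio-replicate values — the test scale is a design
choice: intensity noise is multiplicative, and the log scale matches
the fold-change framing. P-values are BH-adjusted across ions within
the timepoint. `alteredFraction()` summarises the percentage of all
measured ions passing raw p ≤ 0.05 and |log2FC| ≥ 0.5, split by sign;
these screening thresholds are intentionally distinct from the
enrichment-list thresholds below.

Pathway enrichment uses the rank-subset (prefix) procedure
(`rankSubsetEnrichment()`): ions significant in one direction
(adjusted p < 0.1, |log2FC| ≥ 0.5) are ranked by adjusted p (ties
broken by |log2FC| then ion id, for determinism); for every prefix of
the ranked list each pathway is tested for over-representation with a
one-sided Fisher exact test (hypergeometric tail; one-sided because
the question is enrichment — switchable in principle via the exposed
2x2 helper) over the full measured-ion universe, and the pathway's
minimum p over prefixes is reported with the attaining prefix size,
then BH-adjusted across pathways within (timepoint, direction).
Directions are analysed separately. A pathway's ion set is the union
over each ion's candidate metabolites, so duplicate or ambiguous
annotations (mass isomers) cannot double-count — enrichment is
invariant to repeated (ion, metabolite) rows. The universe choice
(all measured ions vs annotated-only) is exposed; the default is all
measured ions.

# Synthetic data: what it emulates, and what it does not

Every generator takes an explicit integer seed, restores the caller's
RNG state, is bit-reproducible, and emits a truth record (generator
name, seed, all parameters, planted effects) sufficient to re-derive
every plant. Defaults are the study conditions the analysis was built
around, chosen once:

* `simulateTiterSeries()` — logistic curves with a = 5.2e7, k = 0.58889,
  x_c = 18 min, the +CHCl3 curve shifted left 0.7 min, floors 1.05e6
  and 5e4 pfu/mL, lognormal noise sigma = 0.05 on log10 titer, samples
  every 2 min, 4 replicates. The closed-form truth is eclipse
  12.3 min, latency 13.0 min, cycle 18 min, burst ~53 — the kinetics
  of a fast lytic myovirus. `simulateAdsorptionSeries()` defaults give
  k_a = 2.2e-9 mL/min and ~4.6 min to 90% adsorption.
* `simulateDualCounts()` — per sample the depth (2e5) splits between
  genomes by a programmed host fraction (1.0, 0.5, 0.3, 0.12 at
  0/3.5/6.5/13 min — an illustrative takeover trajectory), then NB
  noise (alpha = 0.05, typical bacterial RNA-seq replicate scatter)
  around lognormal feature weights carrying the planted effects: a
  6-gene host operon at 80x, a 10-gene prophage block at 6.8x,
  strict-threshold host features at ±4x, phage early/middle/late
  programs, two sRNA-like phage features at 91x and 12x late-vs-early
  and antisense-like features enriched early by 2–17x. Host effects
  ramp up progressively with time (fold^(t/t_late)); the 6.5-min
  sample is single-replicate and only feeds the descriptive middle
  class.
* `simulateCoverage()` — 60 alternating-strand genes (900 bp, 700-bp
  gaps), Poisson depths (background 2, gene sense 30, planted features
  100), 20 planted features per class. Riboswitch leaders are long
  (520–650 bp) 5' leaders ending at the start of weakly expressed
  genes (sense 8) — long enough that the sRNA length bound keeps the
  classes from colliding, which is a generator layout choice, not a
  claim about real leader lengths.
* `simulateGenomeWithMotifs()` — random genome at GC 0.66 (a high-GC
  bacterium) with a tRNA-T-loop-like 11-mer planted in 8 of 12
  annotated tRNAs (in each tRNA's orientation) and rejection-edited
  out of the background on both strands.
* `simulateIonMatrix()` — 377 ions, lognormal baselines, bio/tech
  noise sd 0.2/0.05 (log scale), ion→metabolite ambiguity for ~37% of
  ions, 20 random pathways plus two 15-ion focal pathways; per
  timepoint (52, 60, 68, 75, 83) ions shift up and (32, 20, 11, 28,
  49) down by |log2FC| = 1, the up-set always containing the coherent
  focal pathway. The planted trajectory traces an altered-fraction
  profile rising among increased ions (~13.8% → ~22%) with a
  transient dip among decreased ions — illustrative percentages, fixed
  before any acceptance measurement.

What passing recovery tests on these inputs shows is that the
estimators and callers are correct and calibrated under their assumed
noise models (lognormal titers, NB counts, Poisson coverage, lognormal
intensities). What they cannot show: real libraries have positional
coverage bias, overlapping transcription units and partial rRNA
depletion; real coverage boundaries are ragged rather than
block-shaped; real metabolomics has correlated ions, batch structure
and heavy-tailed noise. The callers' perfect precision/recall on
block-shaped plants is an upper bound, not a field estimate.

# Numerical choices and degenerate inputs

* Logistic fitting: multi-start Levenberg–Marquardt, parameter bounds
  as above; ties resolved by residual norm; flat series flagged, not
  fitted; < 5 distinct timepoints rejected.
* Adsorption: decay rates below 1e-9/min are treated as "no adsorption
  detected" (a flat series fit can return slope -0 numerically).
* Size factors: features with any zero are excluded from the
  geometric-mean reference; when no all-nonzero feature exists the
  error suggests the +0.5 pseudo-reference fallback
  (`pseudoReference = TRUE`), which sparse phage matrices at the
  0-min timepoint genuinely need.
* Dispersions are floored at 1e-8; below 1e-7 the GLM uses the Poisson
  family.
* BH adjustment passes NA through and keeps it out of the denominator.
* Welch test with zero variance in both groups returns NA (undefined)
  rather than an arbitrary statistic.
* Ranking ties in the enrichment list are broken deterministically
  (adjusted p, then |log2FC| descending, then ion id).
* Coordinates are GRanges-native (1-based inclusive) in memory;
  bedGraph I/O converts to/from the format's 0-based half-open
  convention via rtracklayer, and overlapping bedGraph intervals
  resolve last-wins with a warning.

# Problem sizes

The shipped defaults are desk-scale: 1000 host + 200 phage features x
10 samples, 97-kb coverage genome, 50-kb motif genome, 377 ions x 48
samples. The full simulate-then-analyse pipeline
(`runTakeoverPipeline()`) completes in well under a minute on one CPU
at these sizes, and the whole test suite in a couple of minutes; the
sizes were chosen so that planted-effect recovery is comfortably
inside the estimators' operating range while keeping iteration fast.

# Known limitations

* The DE engine approximates, and does not clone, empirical-Bayes
  shrinkage frameworks: no LFC shrinkage, no outlier refitting, no
  Cook's filtering. For two-group bacterial designs at these depths
  the Wald t with trend-shrunk moment dispersions is calibrated (the
  null simulations assert it), but multi-factor designs are out of
  scope.
* The middle temporal class rests on one descriptive sample by design;
  it is a labelling rule, not an inference.
* Feature calling assumes flat-topped coverage blocks; heavily ragged
  real coverage will need the merge-gap and depth parameters retuned.
* `scanKmers()` is exact matching only — no mismatches, no
  thermodynamics; it finds candidate target sites, not hybridisation
  evidence.
* The enrichment procedure conditions on the significant list; with
  very small lists the per-prefix tables are sparse and min-p over
  prefixes is conservative after BH across pathways.
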