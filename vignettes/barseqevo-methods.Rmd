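---
title: "Methods: barcode-sequencing analysis of pooled fitness assays and experimental evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode-sequencing analysis of pooled fitness assays and experimental evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barseqevo)
```

## The system

barseqevo analyzes serial-transfer experimental evolution of budding
yeast lineages tagged with unique 20-bp genomic barcodes. Two barcoded
strains founded in each well compete over daily 1:*D* dilution cycles;
amplicon sequencing of the barcode locus at sampling timepoints gives
each lineage's relative abundance, and pooled competition assays against
a common ancestral reference convert count ratios into fitness. The
package covers the full path from raw reads to treatment-level
inference, and ships a ground-truthed simulator of the whole design so
every estimator can be validated against known truth.

## Generation accounting

A culture diluted 1:*D* must regrow *D*-fold to saturation, i.e.
undergo log2(*D*) doublings per day. The standard 1:1000 transfer gives
9.97 generations/day and ~250 generations in 25 days; 1:250 and 1:4000
give ~200 and ~300. The same doubling logic sets the assay divisor:
a 48-h, two-overnight-culture competition spans ~20 generations, the
default divisor in the fitness estimator (configurable per assay since
`round(2 * log2(1000)) = 20`).

## Demultiplexing

Reads are laid out as forward index (9–12 bp), constant spacer, 20-bp
barcode, constant spacer, reverse index (9–12 bp). Assignment is exact:
the forward index must match a known index as the read prefix (longest
match wins; sheets in which one index is a strict prefix of another are
rejected at validation), the barcode must match a library sequence at
the implied position, and the reverse index must match after the
reverse spacer. A read failing any element is discarded under its first
failing reason, so retained reads plus the discard tally always equal
the raw count. Exact matching is safe because libraries are constructed
with pairwise Hamming distance ≥ 6: a single sequencing error cannot
convert one barcode into another, and `validate_library()` enforces the
separation. An optional Hamming tolerance (≤ 2) exists but is off by
default. Base qualities are ignored — quality filtering happens
upstream on-instrument.

The spacer sequences in `read_layout()` are a synthetic template: the
true primer-derived constant regions are a property of a particular
primer design, not of the analysis. The simulator's FASTQ emitter and
the demultiplexer share whatever layout is supplied, so round-trip
tests are exact by construction.

## Contamination

For sample *j*, the cross-contamination rate is
B_j = (ΣC_i / m) / T_j: the mean count over the *m* library barcodes
not expected in the sample, as a fraction of the sample total. It is
scale-invariant, and must be computed on raw counts — censoring first
would force B_j = 0. The fixed pipeline order is therefore
demultiplex → contamination → censor → downstream, with B_j retained as
a model covariate. When a sample was sequenced in two runs, the run
with the lower B_j is kept (ties to the first run). Samples with zero
totals have no defined rate; they are excluded from summaries and
listed separately. Comparing two processing runs uses a weighted
one-tailed paired t-test (H1: second run lower) with df = n − 1 pairs;
the exact df convention for weighted paired designs is not canonical,
so the simple pair-count convention is used and documented.

## Fitness estimation

Malthusian fitness per generation is the change in log count ratio of
focal over reference between assay start and end, divided by the
generations elapsed:

m = ( ln(C48/R48) − ln(C0/R0) ) / 20

Wrightian fitness is w = exp(m), and fitness change over evolution is
Δw = w_g250 − w_g0, assuming no frequency-dependent selection. Zero
counts make the estimator undefined; the default policy adds a 0.5
pseudocount to all four counts of an affected assay and flags the
estimate, preserving data at contamination-level counts, while a strict
mode returns a flagged missing value instead. Both are exposed because
neither choice is forced by the estimator itself.

### Read weights

Proportion-based quantities computed from few reads deserve less
influence. Each estimate carries a weight equal to the harmonic mean of
the counts that entered it — the focal-barcode count and the sample
total at each contributing timepoint (four components for one assay).
The harmonic mean is dominated by its smallest component, so one
shallow sample caps the weight no matter how deep the others are; a
zero component gives weight zero. The exact composition of the weight
is configurable in principle (the combination of focal and total counts
is a design choice, not an identity); the default above is used
throughout.

### Replicates and significance

Generation-0 and generation-250 assays are matched by replicate index
when the replicate sets agree; Δw is then computed within replicate and
aggregated by weighted mean, with the record weight the harmonic mean
of replicate weights. When replicate sets disagree, Δw falls back to
the difference of timepoint weighted means with SE propagated in
quadrature. Per-strain tests fit a zero-intercept weighted linear model
on strain indicators — per-strain weighted means tested against zero
with a model-pooled residual variance — two-sided for initial-fitness
deviations, one-tailed (greater) for Δw, followed by Benjamini–Hochberg
adjustment reported at 5% and 1% FDR. Strains whose reads vanished
entirely (all-zero weights) are aggregated unweighted and excluded from
testing rather than silently dropped.

## Lineage dynamics

Seven metrics summarize each two-barcode proportion trajectory sampled
at generations 0/100/150/200/220/240/250: the magnitude and timepoint
of the maximum deviation from the starting proportion (m-max, t-max),
of the maximum per-generation rate of change between adjacent samples
(m-max-rate, t-max-rate), and of the maximum difference between the two
barcodes' proportions (m-max-diff, t-max-diff), plus the total
cumulative change. Because sampling is unevenly spaced, rates are
normalized per generation and the interval's ending generation is
reported; argmax ties break to the earliest generation; missing
timepoints are bridged by their nearest available neighbors with
gap-normalized rates. Fixation is called when either barcode reaches a
proportion ≥ 0.95 at a sampled generation and holds it at every later
sampled generation through 250 — evaluated on sampled generations only,
with no interpolation. Only the first barcode of each pair enters
population-level analyses: the pair's proportions are complementary, so
using both would double-count each trajectory.

## Weighted models

All models use precision weights (weights scale the residual variance
of each observation), matching how weights enter `lm()` and `lmer()`.
The treatment-level model for fitness change is a weighted mixed model,
Δw ~ treatment + contamination + (1 | strain), REML-fit with
Satterthwaite degrees of freedom for the fixed effects; the
contamination covariate is dropped when non-significant (p > 0.05).
The dynamics models regress each metric on treatment with initial
barcode abundance as a droppable covariate under the same rule. The
reference level for all treatment contrasts is the standard-condition
control (diploid, complete medium, 1:1000). Exact coefficient-table
identity with any particular mixed-model implementation is not claimed;
what is validated is parameter recovery and type-I-error calibration on
simulated data. With one observation per population, the dynamics
models have no grouping structure and are fit as weighted least
squares.

## Power

Power calculations use the noncentral t distribution for per-strain
fitness differences (ncp d√n one-sample, d√(n/2) two-sample, with
pooled-variance df 2(n−1)) and the noncentral F distribution for
treatment-level effects (ncp λ = f²(u+v+1)). Both satisfy
power(effect = 0) = α exactly and are verified against 10⁵-replicate
Monte-Carlo simulation. The Monte-Carlo oracle for the f² family must
hold the design fixed (scaled so the slope test's noncentrality is
exactly f²(u+v+1)); with a random regressor the realized noncentrality
varies and Jensen's inequality biases simulated power by ~1% at
moderate effect sizes. Published headline power numbers for this kind
of design depend on exactly how replicate counts and the replicate rMSE
are combined into the test's d, which is a reporting convention rather
than a property of the distributions; the module exposes all test
types so any convention can be reproduced, and no particular one is
hard-coded.

The noise scale fed to power analyses is the pooled replicate rMSE:
deviations of replicate fitness measurements from their per-strain
means, pooled over strains, sqrt(ΣΣ(x_ir − x̄_i)² / Σ(n_i − 1)).

## The simulator

The generator mirrors the design it stands in for: 76 two-barcode
populations (21 in the control arm, 11 in each of ethanol, NaCl,
1:4000, 1:250, and haploid arms), 25 daily cycles, dynamics samples at
the seven sampling generations, and 0 h/48 h pooled assays of all 152
strains in four replicates (8–22 barcodes per pool against a
ploidy-matched reference at 50%), at 3,000 reads per barcode per sample
with diffuse cross-contamination at 0.04% per sample.

Within-day growth is deterministic exponential with selection
(class frequency ∝ e^{s·g}, g = log2(D)); stochasticity enters only at
the multinomial bottleneck (N_b = 3.0×10⁸ cells/ml × 0.6 ml / D), at
Poisson mutation arrivals (U·N_b·g per day, exponential effect sizes
added to the parent's), and at sequencing (multinomial reads). This is
the standard serial-transfer approximation, and it keeps closed forms
available: in deterministic mode a two-class trajectory follows the
logistic form r_t = r_0·e^{st} exactly (tested to 1e-9), and a pooled
assay changes the focal/reference count ratio by exactly e^{s·20}.

Contamination is injected so the expected measured rate equals the
configured β: with m contaminants and uncontaminated total T₀ each
contaminant receives Poisson(β·T₀/(1 − mβ)) counts, which makes the
Eq.-style estimator recover β in expectation (deterministic mode uses
rounded expectations).

Parameters nothing pins down directly were chosen once and documented:

* **Mutation supply** (U, s̄ per treatment) is illustrative — chosen to
  produce qualitatively realistic regimes (appreciable adaptation, with
  fixation in roughly 10% of populations concentrated in the
  stronger-selection NaCl and haploid arms, occasionally elsewhere).
  Defaults are U = 5×10⁻⁸ with s̄ = 0.02 for the diploid arms
  (s̄ = 0.015 under ethanol, reflecting stress-limited benefits),
  U = 1×10⁻⁷ with s̄ = 0.05 for NaCl, and U = 2×10⁻⁷ with s̄ = 0.04 for
  haploids (recessive beneficial mutations are immediately exposed).
  Ploidy is phenomenological — different (U, s̄), not explicit genetics.
* **Replicate assay noise**: real pooled assays carry biological and
  preparation noise far above counting noise; replicate end-point
  measurements show w-scale rMSE near 4×10⁻². The generator perturbs
  each replicate's per-assay Malthusian fitness by N(0, 0.03), giving a
  replicate Δw noise sd near 0.042, matching that scale. Set it to 0
  for pure counting noise.

What the simulator does **not** emulate: PCR jackpotting and
amplification bias (noise is multinomial given the template), index
hopping structure (contamination is uniform over non-expected
barcodes), frequency-dependent selection, clonal interference across
wells, autodiploidization, or instrument-specific artifacts. Passing
tests therefore demonstrate that the estimators recover truth under
the stated generative assumptions, not that real libraries satisfy
those assumptions.

## Numerical and design choices

* Argmax ties: earliest generation; rate intervals report their ending
  generation.
* Zero-count assays: 0.5 pseudocount on all four counts, flagged;
  strict mode yields flagged missing values.
* Zero-estimate/zero-variance strain tests report t = 0 (no evidence),
  not NaN.
* Weighted SEs use count-weight semantics (weights normalized to sum to
  n), so equal weights reduce exactly to unweighted formulas.
* BH adjustment is order-invariant; re-applying it to adjusted values
  is not a no-op and is not claimed to be.
* Reruns are bit-identical: every stage is a pure function of (inputs,
  seed), and run manifests record seeds and input checksums.

## Problem sizes used in validation

The shipped validation runs use the full design scale for the study
itself (676 samples × 154 barcodes; 532 dynamics samples; 1,216 fitness
measurements) and scaled Monte-Carlo loops elsewhere: 10⁵ replicates
for power oracles, 1,000 replicates for estimator recovery at depth
3,000, 500 samples for contamination recovery, 200 simulations for
type-I-error calibration of the treatment model, and 1,000 random
trajectories for the dynamics brute-force comparison. These sizes give
Monte-Carlo standard errors comfortably below the tolerances being
checked.

## Known limitations

* The demultiplexer's exact-match rule discards all reads with any
  error in index or barcode; with ~40 bp of constraint this is a
  10–30% read loss at typical error rates, the price of zero
  misassignment given ≥ 6-substitution library separation.
* Δw pairing by replicate index assumes replicates are exchangeable
  across timepoints; when replicate sets differ the quadrature fallback
  loses the within-replicate correlation.
* Mixed-model df are Satterthwaite approximations; small-sample p-values
  near thresholds should be treated accordingly.
* The fitness model assumes no frequency dependence; lineages whose
  final pool frequency collapsed are estimated from few reads and are
  down-weighted but not modeled further.
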