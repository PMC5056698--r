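---
title: "Methods: screening for Ftz-F1 targets and prioritizing their enhancers"
author: "stripecre"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening for Ftz-F1 targets and prioritizing their enhancers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models behind `stripecre`, the
parameters that matter, the design decisions taken where the design was
genuinely open, and what the synthetic-data tests do and do not show about
real data.

## The expression screen

Each probeset's log2 intensities across the 18 arrays are modelled as

    y = Stage + Genotype + Batch + error,

with stage (5, 6, 8), genotype (control / maternal-mutant) and
hybridization batch as categorical fixed effects. In this balanced design
the genotype F-test from the fixed-effect fit coincides with the
mixed-model formulation in which batch is a random ("non-repeatable")
term, so the fixed fit is used for determinism and testability. Residual
degrees of freedom are 18 − 6 = 12.

**Permutation p-values.** The F statistic for the genotype term is
calibrated by permutation: genotype labels are reshuffled *within stage
strata* (stage and batch stay in the model), which preserves the stage
structure under the null. With `n_perm = 100` label shuffles, a single
probeset's p-value has resolution 1/101 — far too coarse for any FDR
procedure to separate a handful of true targets from the ~1 % of null
probesets that tie them at the minimum attainable p. The matrix-level
screen therefore pools permuted F statistics across probesets (the
behaviour of the standard microarray permutation-ANOVA packages), giving
resolution `1/(n_perm × n_probesets + 1)`. `fit_probeset_anova()` retains
the per-probeset `(1 + b)/(n_perm + 1)` convention for single responses.
Probesets with no variation beyond the reduced fit are assigned F = 0 and
p = 1 (relevant in noiseless simulations).

**q-values.** Storey's estimator `pi0 = mean(p > 0.5)/0.5` (capped at 1)
multiplies Benjamini–Hochberg adjusted p-values; with fewer than 100
p-values the estimator is too unstable and pi0 falls back to 1.

**Fold changes and the cascade.** The signed fold change of two log2
means is `2^d` for `d ≥ 0` and `−2^(−d)` otherwise, so magnitudes are
always ≥ 1 and a halving reads −2. The cascade keeps probesets with
q < 0.05, a stage-5→6 signed fold change ≥ +1.1 *in control arrays only*
(the wording of the source criterion refers to wildtype arrays), and a
negative genotype fold change (means averaged over all three stages);
ranking is by |genotype fold change|. Reported percentages round half
away from zero. The −1.49 value quoted for the top candidates is an
observed property of that list, not a threshold.

**Power at the study's scale.** With 10 planted −1.5-fold targets among
1000 probesets, per-array noise SD 0.2 and 3 replicates, the genotype
contrast has noncentrality ≈ 6.2 but only 12 residual df; the BH cutoff
at rank 10 of 1000 demands p ≈ 5×10⁻⁴, where per-target power is ≈ 0.87.
The screen's measured sensitivity (~0.85–0.89 over 20 seeds, FDP ≈ 0.01)
sits at this oracle ceiling; variance-shrinkage statistics would raise it
but are deliberately out of scope. This is a property of the design size,
not of the implementation.

## Interval conventions and enhancer selection

Internally all intervals are `GRanges` (1-based, closed), the native
convention of the Bioconductor stack this package builds on. Printed
coordinates (`"2R:23868513..23869466"`) are parsed as 1-based closed, so
printed length is `end − start + 1`; BED I/O converts to 0-based
half-open per the standard. The 2,016-bp 5-HT2A exception validates the
arithmetic.

Peak windows for motif analysis are the peak maximum ± 200 bp (401 bp
total; odd widths required); windows running off a chromosome end are
clamped and flagged rather than rejected. Candidate enhancer regions are
the peak maximum ± 500 bp (~1 kb, configurable; the consensus site is
required anywhere in this region, the broader of the two readings of the
source procedure). Selection takes, among strict-tier peaks within 70 kb
of the gene, the highest-scoring peak whose region contains ≥ 1 consensus
match; ties break by distance of the peak maximum to the gene's nearest
edge, then leftmost coordinate (the source does not define tie-breaking).
If no strict peak qualifies, the relaxed tier is tried; failing that, the
result is an explicit absence with a reason code (`no_peaks` /
`no_consensus`), not an error.

Degenerate consensus matching (default `BSAAGGHYRHH`) runs on both
strands; hard-masked `N` never matches any code (including a pattern `N`),
and soft-masked lowercase matches by default with an option to exclude,
since the source masked repeats for background building but does not
state a masking policy for consensus scanning.

## Markov backgrounds, k-mer tests, and PWM scanning

**Background model.** `build_markov_background()` estimates a plain
order-k Markov chain (default k = 5) with strand-averaged counts,
skipping k-mers containing non-ACGT letters — the behaviour of the
standard background-builder utilities (which despite the word "hidden" in
some descriptions produce a plain chain). Pseudocount 1 by default.
Lower-order models for sequence starts are estimated alongside. Synthetic
composition models drawn for simulation are passed through
`stationarize_model()`, which replaces their lower orders by the
marginals of the chain's stationary distribution, so that the model's
k-mer probabilities describe windows anywhere in a long sequence; models
estimated from data satisfy this automatically.

**K-mer over-representation.** The discriminative motif-discovery step is
re-cast as an explicit word-count test over k = 4–10 (the conventional
maximum motif width caps the range). The statistic is the number of
*sequences* containing at least one occurrence of the word or its reverse
complement — the zero-or-one-per-sequence convention of discriminative
motif finders — rather than total occurrence counts, because
self-overlapping words clump and make occurrence counts overdispersed
relative to any Poisson reference. Under the background model a sequence
with m windows contains the word with probability ≤ 1 − exp(−m·p)
(Poisson clumping bound, conservative exactly where clumping bites), and
the p-value is the exact binomial upper tail; BH-adjusted q-values run
over the whole word family. Raw counts and expectations are reported
alongside.

**PWM scanning.** JASPAR count matrices are normalized per position with
a total pseudocount of 0.8 split by the background marginals (the
conventional value, avoiding −∞ log-odds), and windows are scored as
`Σ log(p_position(base)/background(base))` with the background taken from
the order-0 marginal of the background model — the Gaussian null then
absorbs higher-order structure. The null is fitted to best-of-two-strand
scores of n random windows (default 10,000; model samples or genome
slices — both provided since the source does not say which was used), and
scanning reports, per position, the best-strand score and its probability
score `Φ((s − μ)/σ)`. The 0.9 threshold therefore tolerates ≈ 10 % of
background positions by construction; it is a *candidate* threshold. The
Gaussian is an approximation: for very sharp matrices the true score
distribution is a discrete mixture and tail probabilities wobble, so
calibration tests use a moderate-information matrix and allow a small
documented slack beyond binomial error. A degenerate null (σ = 0, e.g. a
matrix equal to the background) is an error, never silently usable.

**Presence/absence classification.** Because a ~1 kb region offers ~2,000
strand-best positions, a per-position threshold of 0.9 would mark
essentially every motif present in every region. Region-level
presence/absence contrasts (the confirmed-vs-false comparison) therefore
use a much stricter per-position threshold, default 0.9999, chosen so the
expected number of chance hits per kb is well below 1; the presence
matrix is monotone in this threshold. The discriminating-motif contrast
is implemented literally as "present in all of one group but not all of
the other", with homeodomain-flagged motifs excludable (their sites mimic
the bait factor's own); a Fisher-exact contrast is available as a clearly
labelled extension. "Near" in chromatin-track overlap defaults to ±1 kb.

## The synthetic universe

The generator's defaults are the study's conditions: 18 arrays
(3 stages × 2 genotypes × 3 batches), planted targets reduced by
−log2(1.5) in the mutant at all stages, per-array noise SD 0.2, per-batch
random effects SD 0.1, and a +0.6 log2 stage-5→6 step for targets — a
strong zygotic induction chosen so that the 1.1-fold stage filter is not
the binding constraint under the stated noise (the standard error of a
stage-mean difference is ≈ 0.16). Forty percent of non-targets drift with
stage (SD 0.4) to make the stage filter non-trivial.

The toy genome places one target gene per chromosome so that each
candidate search is unambiguous: one true peak per target with an exact
consensus instance planted inside its ±500 bp window, plus consensus-free
decoy peaks (rejection-sampled until their windows are consensus-free,
capped at 1000 attempts) that may outscore the true peak and so exercise
the consensus requirement. One target's peak exists only at the relaxed
FDR tier and one has no peak at all, exercising the fallback and absence
paths. Chromosome sequences come from a seeded order-2 Dirichlet-drawn
composition model, giving the background-builder non-trivial structure to
estimate. The motif bank plants a composite-consensus motif everywhere,
one motif in all confirmed enhancers only, and five in all false
enhancers only, then rejection-samples each enhancer sequence until its
scanned presence column equals the design — so the end-to-end truth
comparison is exact, not probabilistic.

What these tests show: every operation recovers exactly what was planted
under its own model assumptions, and the null calibrations hold at the
stated tolerances. What they do not show: robustness to probe-level
artifacts, unbalanced designs, chromatin-driven binding without sequence
signal, heteroscedastic noise, or genome-scale repeat structure — none of
which the generator emulates.

## Problem sizes and reproducibility

Default test and acceptance problem sizes — 1,000 probesets, 100
permutations, 8×60 kb chromosomes, 10,000-window nulls, 20-seed
replicates — are the package's chosen balance of statistical resolution
against runtime on a single core. Every random draw flows from one master
seed through named substreams (`substream_seed()`), so no stage perturbs
another's stream and any run is exactly reproducible; generator functions
restore the caller's RNG state.
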