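---
title: "Reference-gene stability: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
library(dplyr)
```

## The problem

Relative RT-qPCR quantification divides a gene of interest by a
normalisation factor built from reference genes assumed to be stably
expressed. In developing tissue that assumption is dangerous: classical
references (GAPDH, ACTB, B2M, HPRT1) are themselves developmentally
regulated in many systems. `refstab` treats stability as something to be
measured, using four algorithms with different failure modes, and treats the
analysis pipeline itself — replicate collapse, plate calibration, cDNA batch
QC — as part of the statistical problem.

## Data model and preprocessing

Input is a long well-level table: `sample_id`, `gene`, `cq`, plus `well`,
`plate`, and the sample covariates `tissue`, `age_days`, `litter`,
`cdna_batch`, `is_calibrator`. Cq values must lie in (0, 45) cycles; rows
failing that are rejected with row indices, while explicit `NA`s are kept
and tracked as missing.

* **Replicate collapse.** Technical wells are averaged per (gene, sample);
  the replicate SD is recorded and cells with SD above `max_sd` (default
  0.5 cycles, roughly the point at which duplicate wells disagree by more
  than two-fold in template) are *flagged, never dropped*. A single well
  yields SD 0.
* **Plate calibration.** Plates share calibrator samples; the per-plate
  offset is the mean over shared (calibrator, gene) pairs of the Cq
  difference to the reference plate (lexicographically first unless set).
  Offsets are pooled across genes by default — Cq offsets from pipetting
  and mastermix differences are well approximated as gene-independent — but
  a `per_gene = TRUE` mode exists since chemistry can in principle interact
  with amplicons. The correction is additive on the Cq scale and idempotent.
* **Linearisation.** RQ = E^(Cq_min − Cq) per gene, with the calibrator
  chosen as the per-gene minimum Cq across the analysed subset. This bounds
  RQ in (0, 1] and cancels from every ratio- or centring-based statistic
  downstream, so the choice is a convenience, not an assumption. Efficiency
  E defaults to 2.0 (exact doubling) for all genes, appropriate when primer
  efficiencies are validated to be near 100%; per-gene overrides are
  accepted within [1.6, 2.1], the plausible range for usable assays.
* **Missing data.** All stability analyses are complete-case on the
  gene × sample submatrix: genes missing in more than 20% of the subset's
  samples are excluded with a warning, then only samples complete for the
  remaining genes are kept. Flags and exclusions are reported, never silent.

## The four stability algorithms

**geNorm.** Pairwise variation `V_jk` is the sample SD (n−1 denominator
throughout the package) of log2(RQ_j/RQ_k) across samples; gene stability
`M_j` is the mean of `V_jk` over partners. The iterative procedure removes
the highest-M gene, recomputes, and stops at two genes — the best pair,
which by construction share their final M (their mutual V). Because the
paper-trail of an iterative method is ambiguous ("the" M of a gene could be
its full-panel value or its value when removed), `genorm_rank()` reports
both `m_full` and `m_at_removal`. Exact ties in the running maximum M are
broken by removing the alphabetically last gene name, deterministically,
and any tie is recorded in the fit. The V(n/n+1) curve compares
normalisation factors built from the top n and n+1 ranked genes
(per-sample geometric means of RQ); values below the conventional 0.2
suggest the extra gene adds little.

**deltaCt.** The mean over partners of the SD of pairwise Cq differences,
computed directly on mean Cq. At E = 2 this equals geNorm's full-panel M
exactly; the package exploits that as a cross-implementation oracle in its
tests (the two routes go through Cq and RQ respectively).

**BestKeeper.** The index is the per-sample *geometric* mean of the panel
Cqs, following the method's original description; an arithmetic variant is
available behind a flag. Genes are ranked by Pearson r against the index;
per-gene Cq SD and CV are reported as descriptors. A zero-variance gene
has no defined correlation: it is assigned r = 0 with a recorded warning.
This inherits a known quirk of correlation-based ranking — a perfectly
constant gene (an ideal reference!) scores as badly as an uncorrelated
one. The package documents rather than "fixes" this, because the
downstream consensus expects the method's native behaviour.

**NormFinder.** On y = log2 RQ, a two-way model y_gs = α_g + β_s + ε_gs
with heteroscedastic gene variances. After double centring, the residual
variance s²_g is bias-corrected to
σ̂²_g = (k/(k−2))(s²_g − s̄²/(k−1)), floored at zero; stability is √σ̂²_g.
The correction matters: without it every gene absorbs a share of the panel
average. The estimator is mean-unbiased (verified against simulations with
known σ in the test suite) and requires k ≥ 3. Grouped mode applies the
same estimator within each group, computes each gene's intergroup deviation
d (sample-centred group mean minus grand mean; deviations sum to zero over
genes within a group), shrinks it by d·γ̂²/(γ̂² + σ̂²/n_g) where γ̂² is the
across-gene variance of d in the group, and scores genes by the mean over
groups of |d̃| + √(σ̂²/n_g). The best pair minimises the two-gene analogue
mean over groups of |(d̃₁+d̃₂)/2| + √((σ̂²₁+σ̂²₂)/(4n_g)), searched
exhaustively — this is what lets two genes with opposite group biases pair
well even though neither is individually best. Published ports of the
method differ in small constants; the formulas above are fixed here and
validated by parameter recovery rather than by matching any one port
bit-for-bit. Log base 2 is used throughout; the base rescales all
stabilities uniformly and cannot change ranks.

## Consensus integration

The integrated score is the per-gene geometric mean of: geNorm
`m_at_removal` (both best-pair genes carrying the shared final M — the
at-removal quantity is the one for which "both genes share a score" is
well-defined; full-panel M is available behind a flag), the deltaCt score,
the inverted BestKeeper correlation 1 − max(r, 0) (so any negatively
correlated gene scores exactly 1), and the *ungrouped* NormFinder
stability. Scores are floored at ε = 1e−6 before the geometric mean so a
single exact-zero method score cannot collapse the consensus to zero;
ε only matters for synthetic noise-free panels. Genes are ranked ascending.
Grouped NormFinder results are deliberately excluded from the consensus:
they answer a different question (which pair for *this* grouping) and are
reported alongside.

## Priming QC

Random priming failures in cDNA synthesis leave oligo-dT-primed transcripts
untouched but shift priming-dependent targets — non-polyadenylated RNAs
such as 18S rRNA, and 5′ regions of very long transcripts — several cycles
later, batch-wide. The screen contrasts, per batch, the median Cq deviation
of sentinel genes (default `18S`; additional long-transcript sentinels can
be supplied) against that of the rest of the panel. Deviations are first
centred on the batch's median deviation across *all* genes, so a batch-wide
global shift (sample quality, input amount) cancels and can neither mimic
nor mask a priming defect; what remains is the sentinel-specific signal. A
batch is flagged when the centred sentinel deviation is at least 1.5 cycles
(≈3-fold template loss, half the magnitude of a typical hard failure, so a
real defect is flagged with margin) while the centred panel deviation stays
within 0.5 cycles. Both thresholds are arguments. The known failure mode —
visual diagnosis turned into a rule — is documented by the null behaviour:
with identically prepared batches, centred deviations are a few hundredths
of a cycle and false flags are essentially absent.

## Normalisation validation

`normalization_factor()` builds NF_s as the geometric mean of the reference
RQs; `normalize_goi()` divides by it (RQs are linear, so normalisation is
division). Validation contrasts the *summed per-timepoint CoV*: within each
tissue, the coefficient of variation (SD/mean) is computed per gestational
timepoint and summed. Summing per-timepoint CoVs rather than pooling all
samples is what makes the measure trend-agnostic: a genuine developmental
trajectory contributes almost nothing, while shared sample-quality noise
contributes at every timepoint. Good references therefore reduce the total
CoV of a trending target without flattening its trend. `compare_nfs()`
reports Pearson r and the OLS gradient (free intercept by default, as the
common desktop tools fit it; slope-through-origin behind a flag) between
normalisation factors built from different reference sets — e.g. three
genes versus two — to ask whether a smaller set would do.

## The synthetic generator

`simulate_cq()` draws well-level Cq as

Cq = b_g − s_{g,tissue}·(age − 14.5) + c_g·u_s + q_s + δ_plate +
δ_batch·[g priming-sensitive] + ε_{g,s} + η_{g,s,w}

with b the gene baseline, s the tissue-specific trend (log2 expression per
day, entering Cq with a minus sign), u_s a per-sample latent trajectory
loaded by co-trending genes, q_s a global per-sample quality effect,
ε biological and η technical noise. Age is centred at 14.5 days (the design
midpoint), so baselines are mid-gestation expectations.

The default design is 44 samples — embryos at seven ages
(n = 3/3/4/3/3/3/5 for E11.5–E18.5), heads (3/3/5) and forelimbs (3/3/3)
at E13.5/E16.5/E18.5 — with litters shared within tissue/age blocks, four
cDNA batches (early embryos, late embryos, heads, forelimbs), three plates,
and three embryo samples carried on every plate as shared calibrators.
Litter effects are off by default: gestational ages are approximate and
litters are pooled within timepoints, so a separate litter variance is not
identifiable at this design size.

Default archetypes (15 genes): eight stable genes (σ_g 0.10–0.15 cycles),
two up-trending genes (+0.30/+0.35 log2/day — about a 2-cycle drop across
the time course, matching a clearly regulated transcript), a co-trending
pair sharing a strong latent loading (c = 0.8 cycles per latent SD, σ_g
0.10) with a modest −0.10 log2/day trend, two tissue-conditional genes
(stable in embryos, −0.25 log2/day in heads and forelimbs), and a
priming-sensitive rRNA-like gene (baseline Cq 9.5). Noise defaults —
quality σ_q = 0.5, technical σ = 0.15, plate σ = 0.3 cycles, and a
+3-cycle priming offset in one batch — are chosen so that raw per-gene Cq
spreads sit in the ~0.5–1 cycle range typical of a well-run embryonic
panel, the quality effect dominates gene noise (the regime in which
normalisation is worth doing), and the priming defect has the ~10-fold
template-loss magnitude a hard failure produces. The returned ground truth
records every realised effect (q, u, plate and batch offsets, slopes and
the noise-free expected Cq), enabling parameter-recovery tests. Standard
normal draws are scaled outside the RNG so that setting a variance to zero
leaves all other realisations untouched — this is what makes "the quality
effect cancels exactly" testable as an identity rather than a tolerance.

What the generator deliberately does *not* model: amplification curves and
Cq calling, efficiency drift, melt behaviour, litter pedigree structure,
and any gene–gene regulatory network beyond the single shared latent.
Passing tests on synthetic data therefore demonstrate algorithmic
correctness and the intended operating characteristics under the modelled
effects — not biological validity on any particular real dataset.

## A structural note on correlated reference pairs

geNorm's known weakness is co-regulation: two genes tracking each other
survive the iterative exclusion on the strength of their mutual agreement,
regardless of their joint drift. The generator's co-trending pair lets the
package demonstrate both sides of this, but the two sides live in
*different* noise regimes, and the trade-off is worth stating precisely.
With s comparable stable genes remaining, the pair survives an exclusion
round roughly when V_CC + (s−2)·V_CS < (s−1)·V_SS (mutual, cross and
stable-pair variations respectively). Being *strictly worse* than every
stable gene under deltaCt/NormFinder requires the pair's total per-gene
variance to exceed every stable gene's — which pushes V_CS above V_SS and
violates the survival condition mid-iteration. The two behaviours are
therefore demonstrated separately: at defaults (strong latent), the pair
correlates tightly, scores clearly worse than the stable set under
deltaCt/NormFinder, and the consensus cleanly separates stable from
trending genes; in a small-panel regime with moderately noisy stable genes
(σ_g = 0.25) and a moderate loading (c = 0.25), the pair robustly captures
the geNorm best pair while the other methods rate it unremarkably. Real
datasets sit somewhere between — a correlated pair typically wins geNorm
while ranking mid-pack elsewhere — which is exactly why a consensus over
methods, and a validation step independent of all of them, are worth the
trouble.

## Numerical choices and edge cases

* Sample SDs use the n−1 denominator everywhere.
* Degenerate inputs fail loudly with classed conditions (schema / data /
  I/O), which the CLI maps to distinct exit codes.
* `pairwise_v()` and the panel methods require ≥3 complete samples;
  NormFinder requires k ≥ 3 genes (the bias correction is undefined below);
  grouped mode refuses single-sample groups by name.
* Zero-variance genes: geNorm/deltaCt handle them naturally (V = 0 against
  proportional partners); BestKeeper assigns r = 0 with a warning.
* The consensus epsilon (1e−6) and the replicate-SD flag threshold
  (0.5 cycles) are arguments, not constants.

## Test-suite problem sizes

The suite exercises the estimators at sizes where their statistical
contracts are sharp but cheap: 6 gene × 10 sample random panels (100 of
them) for the geNorm/deltaCt identity; k = 8, n = 20 with 1000 replicates
for NormFinder variance recovery; 10–20 seeded replicates of the default
15 × 44 design for the end-to-end recovery, priming-QC and validation
properties. These sizes were chosen so each property is measured with
comfortable Monte-Carlo margin while the whole suite stays fast enough to
run habitually.
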