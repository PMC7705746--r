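---
title: "Dating duplications and allopolyploidy: models, defaults, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating duplications and allopolyploidy: models, defaults, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allodate)
```

This vignette is the package's account of its science: what each model
assumes, why the defaults are what they are, what the simulators do and do
not emulate, and where the design was genuinely open.

## The 4DTv statistic

A codon is fourfold degenerate (4D) when any nucleotide at its third
position encodes the same amino acid; under the standard code that is 8
codon families, 32 of the 64 codons (`genetic_code()` derives this from
the code table rather than enumerating it). Substitutions at 4D third
positions are synonymous regardless of what they change to, so they
accumulate nearly neutrally, and the *transversion* fraction among them —
the 4DTv distance *v* — saturates slowly enough to resolve ancient
duplications: under a symmetric substitution process the expected value is
$q(t) = \tfrac12\,(1 - e^{-4\beta t})$ for total separation time $t$ and
per-target transversion rate $\beta$, approaching ½ from below.

`four_dtv()` counts a column only when (i) both codons are gap-free and
unambiguous, (ii) the first two codon positions are identical in the two
sequences, and (iii) that shared prefix heads a 4D family. Requiring
identical prefixes guarantees both third positions are genuinely
synonymous for the *same* amino acid; it is the conservative convention,
and it makes condition (iii) a single check. Ambiguity codes are unscored
sites — excluded from numerator and denominator — and gaps must cover
whole codons (frame-breaking alignments are rejected at the door rather
than silently rescued; alignment hygiene is upstream's job).

Raw *v* is the default output. A multiple-hit correction
(`hky_correct_4dtv()`: the transversion-only distance
$-2\pi_R\pi_Y\log(1 - v/(2\pi_R\pi_Y))$ under observed third-position
composition) is available behind `correct = TRUE` because corrected
distributions are common in the field, but the peak arithmetic this
package reproduces treats the distances as raw, so raw stays the default.
At the table level a saturated correction yields `NA` with the pair
retained; only the scalar function raises an error.

## The Kimura two-parameter distance

With transition proportion *P* and transversion proportion *Q* over
comparable sites,
$$d = -\tfrac12 \log\big((1 - 2P - Q)\sqrt{1 - 2Q}\big),$$
undefined when either log argument is non-positive (saturation). The
scalar `k2p_distance()` errors on saturation; the table verb
`kimura_distance()` flags and keeps such pairs, because batch runs need to
audit what was dropped and why. The estimator is cross-checked in the test
suite against an independent implementation (`ape::dist.dna`, model K80).

## From distances to dates

All conversions use $T = d / (2R)$: a distance between two diverged copies
accumulates along *both* lineages (or both LTR copies), so each lineage
carries $d/2$. With a published rate interval the faster rate gives the
younger bound. This arithmetic reproduces, from peak locations 0.48, 0.08
and 0.01 and the Salicaceae synonymous interval
$R \in [0.67, 1.09]\times 10^{-9}$/site/year, the familiar interval
triplets 220–358, 36.7–59.7 and 4.6–7.5 MY — which is the package's
acceptance anchor for this layer. Display rounding (`format_my()`) is one
decimal below 100 MY and whole numbers above, matching how such intervals
are conventionally printed; all stored values keep full precision.

Applying a synonymous-rate interval to raw 4DTv distances conflates two
distance scales slightly; we reproduce the published procedure as-is and
expose the correction separately rather than mixing the two.

## Peak detection

`detect_peaks()` is deliberately histogram-first: values are binned at
`bin_width = 0.01` from zero, peaks are *strict* local maxima holding at
least `min_fraction = 0.01` of all observations, and each peak location is
refined to the kernel-density mode (Gaussian KDE, bandwidth half a bin)
within ±1 bin of the peak bin's midpoint. The 0.01 bin matches the
resolution of the smallest peak the method is expected to resolve; the KDE
is confined to ±1 bin so it can sharpen a location but never relocate a
peak — keeping the procedure deterministic and explainable. Strict maxima
plus the count floor suppress plateau and noise bins; adjacent shoulder
bins of a broad cohort can still qualify as secondary peaks, which is
honest behaviour (they are visible in the histogram) and harmless because
peaks are reported sorted by height.

## LTR insertion ages

The two LTRs of a retrotransposon are identical at insertion and diverge
independently afterwards, so `age = d / (2r)` with the element-level clock
`r = 7.3e-9` substitutions/site/year (the conventional value for this
family of analyses; it is a parameter, not a constant). 5′ and 3′ LTRs
are globally aligned (Needleman–Wunsch, affine gaps, match 2 / mismatch −1,
open 10 / extend 0.5) and *d* is the K2P distance over ungapped columns.
Saturated elements are reported with `NA` age and a flag. Age histograms
(`ltr_age_distribution()`) use half-open 0.5 MY bins — a convention
choice; the bin width is a parameter.

## Collinearity: which pairs enter the distribution

Candidate protein pairs are found by exact shared 5-mer screening and
scored with Smith–Waterman under BLOSUM62 and affine gaps (open 11,
extend 1 — the classic protein-search penalties). Two filters follow: a
raw score floor (`min_score = 100`), playing the role a
database-size-dependent E-value cutoff plays in search engines (no search
engine is reimplemented here, and raw scores are deterministic and
self-contained), and the C-score — a hit's score divided by the best score
involving either of its genes — kept when strictly above 0.5, so only
near-best partners survive. C-score filtering is idempotent by
construction.

Chaining works in gene-rank space, not base pairs: ranks make gap
constraints scale-free and are what the block structure is about. The DP
finds, per chromosome pair and orientation (both ranks increasing, or
`rank_a` increasing and `rank_b` decreasing), the maximum-size chain with
consecutive rank gaps ≤ `max_gap = 25`; blocks are extracted greedily by
decreasing chain size (ties by summed anchor score, then earliest end),
each anchor used at most once, and chains below `min_block = 5` anchors
are discarded. The defaults are the field's conventional
anchor-chaining settings; the DP is verified against exhaustive chain
search on every random instance with ≤ 12 anchors in the test suite.

## Subgenome partitioning

Chromosomes are ranked by the median best-hit identity of their genes to a
diploid reference and the ranking is split at the largest gap between
adjacent medians; the higher group is labelled A. This mirrors reading an
identity boxplot, is deterministic (ties broken by mean identity then
name), is invariant under any strictly monotone transform of the
identities, and imposes no constraint that the split be even — a 19 + 19
outcome is reported, never enforced. All-equal medians raise an ambiguity
error instead of an arbitrary split. The module accepts any per-gene
identity table; it does not assume which aligner produced it.

## What the simulators emulate — and what they do not

`evolve_sequence_pair()` runs the exact site-wise transition probabilities
of the two-rate (transition $\alpha$, per-target transversion $\beta$)
process, so simulated pairs are draws from precisely the model the K2P
estimator inverts — that is the point: estimator consistency can be tested
without confounding model error. Planted cohorts in
`simulate_wgd_pairs()` are placed through the inverse of the transversion
saturation curve, with defaults $\alpha + 2\beta = 0.88\times10^{-9}$
(mid-interval synonymous rate), $\kappa = \alpha/\beta = 2$, and cohorts
at expected 4DTv 0.01 / 0.08 / 0.48 — the three-cohort structure a
Salicaceae-style paralog distribution shows. Codon positions 1–2 evolve at
`pos12_scale = 0.2` of the third-position rate, a simple stand-in for
purifying selection on nonsynonymous sites; without it, deeply diverged
pairs would retain almost no columns with identical codon prefixes, which
real proteins (where nonsynonymous sites evolve several-fold slower) do
retain.

The simulators do **not** emulate: indels within alignments (pairs come
pre-aligned), rate heterogeneity across sites beyond the positional
scaling, selection on specific genes, base-composition bias, segmental
heterogeneity of LTR clocks, or chromosome-scale rearrangement beyond the
planted parallel/inverted blocks. Passing recovery tests therefore shows
the estimators are consistent under their own assumptions at realistic
sizes — not that real genomes satisfy those assumptions.

Reproducibility: every generator is bit-reproducible given `seed`;
`derive_seed()` expands one run seed into fixed per-component substreams
so components can be reproduced independently.

## Experiment scales

The recovery experiments in the test suite and acceptance script use fixed
problem sizes chosen to make their tolerances statistically meaningful:
peak recovery uses 2000 pairs × 6000 nt (≈ 300–700 comparable 4D sites per
pair, putting the per-pair standard error well inside the ±0.01
localization check); LTR age recovery uses 100 elements × 600 bp per
planted class (60 kb aggregate, so class means sit within a few percent of
truth); anchor recovery uses two chromosomes with 50 planted anchors each;
the subgenome experiment uses the full 19 + 19 karyotype at 92% vs 85%
identity with 1% within-chromosome spread. Oracle-equivalence checks
(4DTv per-column oracle, exhaustive chain search, cumulative-sum Nxx) run
at 10³ random instances.

## Known limitations

- 4DTv and K2P assume homogeneous, time-reversible substitution; lineage
  rate variation folds directly into the dates, which is why interval
  clocks are first-class here.
- Peak locations of very broad cohorts (4DTv near saturation) are
  intrinsically noisy; report them with their histogram, not alone.
- The anchor scorer is a screen for collinearity input, not a search
  engine: its raw scores are comparable within a run but are not E-values.
- The largest-gap subgenome split assumes the two parental identity levels
  are separated relative to within-genome spread; when they are not, the
  method refuses (ambiguity error) rather than guessing.
- `read_gene_models()` takes genes from `type=gene` GFF3 records with `ID`
  attributes and ranks them by start; exotic annotation layouts need
  pre-processing.
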