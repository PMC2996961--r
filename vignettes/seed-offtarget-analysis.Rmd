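---
title: "Detecting seed-driven off-target structure in arrayed siRNA screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting seed-driven off-target structure in arrayed siRNA screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedscreen)
```

## The problem

An siRNA loaded into the silencing complex behaves, in part, like a
microRNA: transcripts whose 3'UTRs contain matches to nucleotides 2-7
(the hexamer seed) or 2-8 (the heptamer seed) of the guide strand can be
repressed even though they are not the intended target. In a phenotypic
screen this has a characteristic statistical signature. Because selection
acts on the phenotype, not on the annotation, screening *enriches* for
siRNAs whose seed happens to perturb a phenotype-relevant gene: the same
seed shows up repeatedly among top-scoring siRNAs, and the set of all
siRNAs sharing that seed drifts towards the top of the ranked list.
`seedscreen` quantifies that signature, corrects for it, and exploits it
(a seed enriched in a screen may belong to an endogenous miRNA that
regulates the pathway under study).

## Screen scoring

The scoring model follows standard arrayed-screen practice:

1. **Survival ratio.** Each well is measured before and after treatment;
   survival is `post / pre`. A pre-treatment reading of zero flags the
   well invalid rather than producing `NaN`, and wells missing a phase
   are reported with a reason.
2. **Viability filter.** Per replicate, the bottom `fraction`
   (default 0.2) of sample wells by pre-treatment fluorescence is
   removed across the whole screen. The cut is rank-based with a
   deterministic tie-break (pre-treatment value, then plate, then well),
   so re-running the filter can never reshuffle borderline wells.
   Control wells are never removed. The filter is screen-level rather
   than plate-level because "too few cells to trust the ratio" is a
   property of the well, not of its plate.
3. **Normalisation and robust z.** Log survival is centred at its plate
   median (computed over sample wells only), then converted to
   `z = (x - median(x)) / (1.4826 * MAD(x))` with location and scale
   estimated over all sample wells of the replicate. The 1.4826 factor
   makes the MAD consistent with a normal standard deviation. Controls
   receive z scores from the sample-derived parameters but never
   influence them, since control wells are drawn from different
   distributions by design. A `scale_within = "plate"` switch estimates
   median/MAD per plate instead; the replicate-level default treats the
   plate-median centring as having already absorbed plate effects.
4. **Min over replicates.** An siRNA's score is the *minimum* of its
   replicate z scores: both replicates must support resistance. If any
   replicate is missing (filtered well, invalid well, zero-MAD
   replicate) the score is missing and the siRNA is excluded from
   ranking — a conservative policy that follows directly from defining
   the statistic as a minimum. Ranking is descending with ties broken by
   siRNA id.

The natural log is used throughout; any base cancels in the z score, so
this only fixes the scale of the intermediate columns. Note one property
of the min-of-two summary worth keeping in mind when interpreting score
distributions: for two independent standard z scores the median of the
minimum is `qnorm(1 - sqrt(0.5))` (about `-0.54`), not 0, so a perfectly
null screen has a slightly negative score median. Assay quality is
summarised by the Z' factor,
`1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|`, computed from control
wells; equal control means make Z' undefined and raise an error.

## Seeds and the orientation convention

Seeds are extracted from the guide strand read 5'→3': positions 2-7
(hexamer) and 2-8 (heptamer), with U and T treated as equivalent
everywhere so RNA-written and DNA-written tables interoperate. By this
definition the heptamer extends the hexamer by one base on the 3' side.

Published seed tables are not always in this orientation: a seed printed
as a *target-site* sequence is the reverse complement of the guide seed,
and there the heptamer extends the hexamer on the 5' side. The packaged
reference tables are transcriptions of published, target-site-oriented
seeds, which is why matching them against mature miRNA seeds succeeds
under the `revcomp` orientation and fails under `identical`, while seeds
extracted by this package from guide strands behave the other way
around. Because the strand convention of a vendor library file is often
undocumented, `match_seeds()` defaults to reporting *both* orientations
with a label, and `swap_seed()`/`revcomp()` are provided to move between
conventions explicitly.

## Multiplicity of seeds among the top k

The first detection tool asks: among the top `k` siRNAs (default 20),
how surprising is the observed seed repetition? The null is built by
sampling `k` siRNAs from the library (without replacement by default,
which preserves the library's seed composition; a with-replacement mode
exists) and recording a repetition statistic, repeated `n_iter` times
(default 5,000). Three statistics are offered: the number of seeds
appearing at least twice (`n_repeated`), the largest multiplicity
(`max_count`), and the number of seeds appearing at least `m` times.
The p-value uses the add-one convention
`p = (#{samples >= observed} + 1) / (n_iter + 1)`, which can never be
exactly zero; when no sample reaches the observed value the result is
reported as a bound (`"P < 0.0002"` at 5,000 iterations). The null
depends on the seed composition of the *actual* library, so p-values
from different libraries are not comparable; calibration is validated on
synthetic libraries, including an analytic birthday-collision benchmark
(for `k` draws from `4^6` equiprobable hexamers,
`P(any repeat) = 1 - prod(1 - i/4096)` for `i = 1..k-1`).

## The pre-ranked enrichment engine

Seed sets (all siRNAs sharing a seed) are tested for concentration at
the top of the ranked list with a weighted running-sum statistic.
Walking the list from top to bottom, a member adds
`|s|^p / sum_members |s|^p` and a non-member subtracts `1/(N - n)`; the
enrichment score (ES) is the signed maximum deviation from zero, always
in `[-1, 1]`. `p_weight = 1` is the default; `p_weight = 0` gives the
classic unweighted Kolmogorov-Smirnov-like statistic. Two numerical
choices are worth recording: when the positive and negative extremes tie
in magnitude (within 1e-12) the positive one is reported, so all code
paths (full profile, the O(set size) shortcut used inside permutations,
and the brute-force oracle in the test suite) agree bit-for-bit; and a
set whose members all have zero score falls back to uniform hit weights
rather than dividing by zero.

Significance is calibrated per set by drawing `n_perm` (default 1,000)
random member sets of the same size from the universe — the only null
meaningful for pre-ranked input. NES is the ES divided by the mean of
same-sign null ES; the nominal p is the add-one same-sign tail fraction.
The family-wide error rate uses the distribution of the *maximum*
same-sign null NES across all tested sets: `fwer_p` of a set is the
add-one fraction of permutations whose max-NES reaches its NES. The
add-one form is used deliberately (it makes the permutation rank test
exact at its level and matches the multiplicity test's convention), so a
recomputed `fwer_p` is small but never exactly zero. Sets with fewer
than `min_size` members in the ranked universe (default 5) are dropped
with a warning: smaller sets make the discrete null too coarse to
calibrate. `select_enriched()` keeps positive-NES sets at
`fwer_p <= 0.05` — enrichment of *high*-scoring siRNAs is the
phenomenon of interest; depletion is not selected.

Like all max-statistic corrections over heterogeneous set sizes, the
FWER is approximate for very small sets; in repeated synthetic screens
the per-run family-wise flag rate for 100 null decoy seed sets sits
close to, and within Monte-Carlo error of, its nominal 5% (this is
measured by the acceptance suite rather than asserted here).

## Masking and the false-negative rescue

Off-target seeds do not only create false positives; by crowding the top
of the ranking they can hide true hits. `mask_enriched()` removes every
siRNA whose hexamer is in the enriched-hexamer list or whose heptamer is
in the enriched-heptamer list (seed-position reading; a
`mode = "substring"` alternative removes guides containing an enriched
seed anywhere), then re-ranks the remainder without changing their
relative order. Enriched-seed lists from the enrichment engine and
seeds repeated among confirmed top-k siRNAs can be supplied together.
`known_gene_enrichment()` lifts a gene set to the siRNA level (all
siRNAs targeting the listed genes; absent genes are skipped with a
warning) and runs the single-set pre-ranked analysis before and after
masking.

The rescue is validated as a directional property on synthetic screens
designed to mimic the regime in which it matters: a known-gene set whose
(moderate) signal is not reliably significant before masking because a
population of strong seed-carrier siRNAs both crowds the top of the
ranking and inflates the permutation null, and becomes significant once
they are removed. The validation scenario plants the 17 packaged
enriched hexamers at 3 z-units on 30 carriers each (on genes outside the
known set) and a 1.2 z-unit protective effect on 12 known genes, in a
3,000-siRNA library; before/after p-values are computed with 1,000
permutations and a shared permutation seed so the comparison is not
dominated by null-sampling noise.

## Confirmation-status rules

`classify_gene()` encodes a two-stage confirmation logic. The screen
siRNA must reproduce its phenotype in a secondary assay, otherwise the
gene is a **FalsePositive**. A **Hit** requires at least two
phenotype-positive siRNAs with measured knockdown, all knocking down the
target more strongly than every phenotype-negative siRNA; when the
target's expression is undetectable in every sample, three
phenotype-positive siRNAs suffice. **OffTarget** covers a reproducible
phenotype that cannot be attributed to the target: some
phenotype-negative siRNA knocks down at least as strongly, or the
phenotype-positive siRNAs show no measurable knockdown. Everything else
— reproducible, but corroborating siRNAs neither phenocopy nor knock
down as strongly — is **Unconfirmed**. Knockdown comparisons use an
absolute tolerance (`kd_tol`, default 0.05 on the fraction of mRNA
remaining) so that qPCR-level noise cannot decide a call, and a fraction
remaining above `1 - kd_tol` counts as no knockdown. The
boundary between OffTarget and Unconfirmed when knockdowns are partially
unmeasured is interpretive; the rules here follow the worked narratives
the published statuses came from, and classification is invariant to
evidence row order. Phenotype significance is supplied as a boolean
input: the secondary-assay statistics (t-tests with multiplicity
correction) belong to the assay, not to this rule system.

## The synthetic screen generator

`sim_config()`/`simulate_screen()` generate the structures the analysis
consumes: a library of random 21-nt guides (two per gene by default),
96-well plates filled in library order with a per-plate control
complement (2 positive, 1 transfection, 4 negative wells), lognormal
pre-treatment fluorescence, and log survival decomposed additively as
`baseline + gene effect + seed effect + noise`, drawn independently per
replicate. Planted seed effects are written into the hexamer position of
a configurable number of carriers; guides that acquire a planted hexamer
by chance also receive the effect and are reported separately in the
ground truth. Effects are expressed in z-units of the sample noise
(default SD 1), matching the scale on which the pipeline scores, and the
additive-on-log-survival form matches the pipeline's log-scale scoring;
the attenuation introduced by the min-of-two summary is a property of
the statistic and is deliberately not corrected. Controls get their own
fixed effects with a smaller noise SD (reagent controls are more
reproducible than arbitrary library siRNAs), so Z' is exercised at
realistic values. Defaults: 500 genes, two replicates, baseline survival
0.4 under treatment, positive controls +3, transfection control -1.5.

What the generator does *not* emulate — spatial plate artefacts, edge
effects, transfection-efficiency gradients, per-gene knockdown
variability, or any relationship between guide sequence and efficacy —
bounds what passing tests show: they validate the statistical machinery
under the stated model, not robustness to every failure mode of real
plates.

## Problem sizes used in validation

The test and acceptance suites run at the following sizes, chosen to
match the screen design the package addresses while keeping a full
validation run in the minutes range: recovery experiments use a
12,190-siRNA library (6,095 genes x 2) with one planted hexamer at 2
z-units on 30 carriers, tested against 100 decoy seed sets at 400
permutations, repeated 50 times; rescue experiments use the 3,000-siRNA
scenario above, repeated 50 times; nominal-p calibration uses 2,000
random sets of size 10 in a 1,000-item ranking at 500 permutations; the
multiplicity null uses 5,000 iterations, matching its default.

## Known limitations

* The enrichment engine tests seed sets independently; overlapping
  signals (a heptamer set nested in a hexamer set) are reported
  separately, not deconvolved.
* FWER control is approximate for sets near `min_size`.
* Masking removes whole siRNAs; it cannot apportion an siRNA's effect
  between its target and its seed, so a masked siRNA's gene may still be
  a genuine hit (flagging, not adjudication).
* p-values from the multiplicity test are conditional on the library's
  seed composition and not transferable across libraries.
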