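# seedscreen

Seed-sequence off-target analysis for arrayed siRNA screens.

siRNAs can act like microRNAs: nucleotides 2–7 (hexamer) or 2–8
(heptamer) of the guide strand — the *seed* — can repress transcripts
with complementary 3'UTR sites, producing phenotypes that have nothing
to do with the intended target. Because a phenotypic screen selects on
phenotype, it *enriches* for siRNAs with phenotype-relevant seeds, so
off-target structure leaves a statistical fingerprint in the ranked hit
list: repeated seeds among the top siRNAs, and seed-defined siRNA sets
drifting to the top of the ranking. `seedscreen` is for screeners and
screen analysts who want to detect that fingerprint, correct for it, and
mine it (an enriched seed shared with an endogenous miRNA nominates that
miRNA as a pathway regulator).

The package implements the full chain:

1. **Screen scoring** — per-well survival `post/pre`, a bottom-20%
   pre-treatment viability filter, plate-median normalisation of log
   survival, a robust z score
   `z = (x − median(x)) / (1.4826·MAD(x))`, and the *minimum of
   replicate z scores* as the per-siRNA score; assay quality via the Z'
   factor `1 − 3(σ₊+σ₋)/|μ₊−μ₋|`.
2. **Seed tools** — hexamer/heptamer extraction, a seed→siRNA index
   (the "gene sets" of the enrichment analysis), seed swapping and
   reverse complement.
3. **Top-k multiplicity test** — how surprising is the observed seed
   repetition among the top 20 siRNAs, against a null built by sampling
   20 siRNAs from the library 5,000 times; add-one empirical p with the
   `"P < 0.0002"` bound convention.
4. **Pre-ranked enrichment engine** — weighted running-sum enrichment
   score (ES), size-matched permutation null, NES, and a max-NES
   family-wise error rate; enriched seeds selected at FWER ≤ 0.05.
5. **Masking re-analysis** — remove every siRNA carrying an enriched
   seed, re-rank, and re-test a known-gene set (the false-negative
   rescue).
6. **miRNA matching** — compare enriched seeds to mature miRNA seeds
   (miRBase-style FASTA), reporting both `identical` and `revcomp`
   orientations because library strand conventions vary.
7. **Confirmation logic** — classify genes as `Hit` / `OffTarget` /
   `Unconfirmed` / `FalsePositive` from secondary-assay and knockdown
   evidence.
8. **Synthetic screens** — a generator with planted gene and seed
   effects, used to validate every stage end to end.

Reference fixtures (a published top-20 siRNA table, enriched-seed table,
known-TRAIL-gene list, and a three-miRNA mature FASTA) are packaged
under `inst/extdata/` with accessors `fixture_table1()`,
`fixture_table2()`, `fixture_known_genes()`, `fixture_mirna_fasta()`.

## Worked example

Simulate a 2,000-siRNA duplicate screen with one planted seed
(`ACTTGA`, +2.5 z-units on 30 carriers), score it, and chase the seed:

```r
library(seedscreen)

cfg <- sim_config(n_genes = 1000, planted_seed_effects = c(ACTTGA = 2.5),
                  seed_carriers = 30, rng_seed = 42)
sim <- simulate_screen(cfg)

scores <- score_screen(sim$library, sim$measurements)
#> 628 siRNA(s) excluded from ranking (missing replicate z)
head(scores[, c("sirna_id", "z_rep1", "z_rep2", "score", "rank")], 3)
#>     sirna_id   z_rep1   z_rep2    score rank
#> 1 g00973_si1 4.636594 3.834733 3.834733    1
#> 2 g00138_si2 3.450882 3.562585 3.450882    2
#> 3 g00670_si2 3.373857 4.781622 3.373857    3
```

(The exclusions are siRNAs losing a replicate to the 20% viability
filter: the score is defined as the min over *complete* replicates.)
The planted seed dominates the top of the list and the multiplicity
test calls it:

```r
ranked <- scores[!is.na(scores$score), c("sirna_id", "score")]
seeds  <- extract_seed(setNames(sim$library$guide_seq, sim$library$sirna_id), 6)
mult   <- top_k_seed_multiplicity(ranked$sirna_id, seeds, k = 20)
mult
#> Seed multiplicity among top 20 siRNAs: 1 seed(s) repeated, max count 17
#>   ACTTGA x17
null <- sample_null(unname(seeds), k = 20, n_iter = 5000,
                    statistic = "max_count", rng_seed = 1)
empirical_p(null, mult$max_count)$label
#> [1] "P < 0.0002"
```

The enrichment engine recovers it family-wide, masking removes its
carriers, and the seed points at miR-26a:

```r
idx <- build_seed_index(sim$library, 6)
res <- gsea_preranked(ranked, idx, n_perm = 1000, min_size = 5, rng_seed = 1)
(enr <- select_enriched(res, fwer_threshold = 0.05))
#>     name size       es      nes p_nominal      fwer_p
#> 1 ACTTGA   22 0.960337 3.597949    0.0125 0.000999001

mask_enriched(ranked, sim$library, enriched_hexamers = enr$name)
#> Mask report (seed_position): 22 siRNA(s) removed, 1264 retained

match_seeds(enr$name, read_mature_fasta(fixture_mirna_fasta()),
            seed_length = 6, mode = "both")
#>     seed       mirna orientation
#> 1 ACTTGA hsa-miR-26a     revcomp
```

`ACTTGA` here is a *guide-strand* seed, so it matches the reverse
complement of the miR-26a seed (`UCAAGU`); seed tables printed in
target-site orientation match under `identical` instead — which is why
`match_seeds()` defaults to reporting both orientations, labelled.

`run_pipeline(pipeline_config(...))` chains all stages and writes the
stage TSVs, a `summary.json`, and a run log; `exec/seedscreen` exposes
the same stages as shell subcommands
(`run`, `simulate`, `score`, `seeds`, `topk-test`, `mask`, `mirna`,
`fixtures`).

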