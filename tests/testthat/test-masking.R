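test_that("masking removes seed carriers and preserves retained order", {
  lib <- data.frame(sirna_id = c("a", "b", "c"),
                    gene_id = c("g1", "g2", "g3"),
                    guide_seq = c("GACTTGAGGGGGG", "GTTTTTTGGGGGG",
                                  "GCCCCCCGGGGGG"))
  ranked <- data.frame(sirna_id = c("a", "b", "c"), score = c(3, 2, 1))
  # no enriched seeds: identity
  m0 <- mask_enriched(ranked, lib)
  expect_equal(m0$retained$sirna_id, c("a", "b", "c"))
  expect_equal(length(m0$removed_ids), 0L)
  # rank-1 siRNA carries an enriched hexamer
  m1 <- mask_enriched(ranked, lib, enriched_hexamers = "ACTTGA")
  expect_equal(m1$removed_ids, "a")
  expect_equal(m1$retained$sirna_id, c("b", "c"))
  expect_equal(m1$retained$new_rank, c(1L, 2L))
  expect_error(mask_enriched(rbind(ranked, data.frame(sirna_id = "zz", score = 0)),
                             lib), "not present")
  expect_error(mask_enriched(ranked, lib, enriched_hexamers = "ACTT"), "6-mers")
})

test_that("masking the fixture by its '+' seed set removes the 10 flagged rows", {
  t1 <- fixture_table1()
  # reconstruct guides whose hexamer seed equals the printed hexamer
  lib <- data.frame(sirna_id = t1$symbol, gene_id = t1$symbol,
                    guide_seq = paste0("G", t1$hexamer, "ACGTACGTACGTAC"))
  ranked <- data.frame(sirna_id = t1$symbol, score = t1$score)
  plus_hex <- unique(t1$hexamer[t1$enriched == "+"])
  m <- mask_enriched(ranked, lib, enriched_hexamers = plus_hex)
  expect_equal(length(m$removed_ids), 10L)
  expect_setequal(m$removed_ids,
                  c("TEGT", "CCNT1", "ACO1", "HAPIP", "LRPAP1", "INADL",
                    "GPR132", "ADORA1", "MAGED1", "MYC"))
  expect_setequal(m$removed_ids, t1$symbol[t1$enriched == "+"])
  # retained siRNAs keep their relative score order
  expect_equal(m$retained$sirna_id,
               m$retained$sirna_id[order(-m$retained$score,
                                         m$retained$sirna_id)])
})

test_that("removed count matches seed-level inclusion-exclusion", {
  sim <- simulate_library(sim_config(n_genes = 400, rng_seed = 13))
  lib <- sim$library
  hex <- extract_seed(setNames(lib$guide_seq, lib$sirna_id), 6)
  hept <- extract_seed(setNames(lib$guide_seq, lib$sirna_id), 7)
  ehex <- unique(hex)[1:5]
  ehept <- unique(hept)[3:8]
  ranked <- data.frame(sirna_id = lib$sirna_id,
                       score = seq(nrow(lib), 1) / 100)
  m <- mask_enriched(ranked, lib, ehex, ehept)
  in_hex <- hex %in% ehex
  in_hept <- hept %in% ehept
  expect_equal(length(m$removed_ids),
               sum(in_hex) + sum(in_hept) - sum(in_hex & in_hept))
  expect_setequal(c(m$removed_ids, m$retained$sirna_id), lib$sirna_id)
})

test_that("substring mode removes any guide containing the seed anywhere", {
  lib <- data.frame(sirna_id = c("a", "b"), gene_id = c("g1", "g2"),
                    guide_seq = c("GGGGGGGGACTTGAGG", "GGGGGGGGGGGGGGGG"))
  ranked <- data.frame(sirna_id = c("a", "b"), score = c(1, 2))
  m_pos <- mask_enriched(ranked, lib, enriched_hexamers = "ACTTGA",
                         mode = "seed_position")
  m_sub <- mask_enriched(ranked, lib, enriched_hexamers = "ACTTGA",
                         mode = "substring")
  expect_equal(length(m_pos$removed_ids), 0L)  # seed not at positions 2-7
  expect_equal(m_sub$removed_ids, "a")
})

test_that("known-gene enrichment validates its inputs", {
  sim <- simulate_library(sim_config(n_genes = 50, rng_seed = 23))
  lib <- sim$library
  withr::local_seed(2)
  ranked <- data.frame(sirna_id = lib$sirna_id, score = rnorm(nrow(lib)))
  genes <- unique(lib$gene_id)[1:6]
  r <- known_gene_enrichment(ranked, lib, genes, n_perm = 100, rng_seed = 1)
  expect_equal(nrow(r), 1L)
  expect_gt(r$p_nominal, 0)
  expect_lte(r$p_nominal, 1)
  expect_warning(known_gene_enrichment(ranked, lib, c(genes, "NOPE"),
                                       n_perm = 100, rng_seed = 1),
                 "NOPE")
  expect_error(known_gene_enrichment(ranked, lib, unique(lib$gene_id),
                                     n_perm = 100),
               "whole")
})
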