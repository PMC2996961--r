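test_that("seed extraction reads positions start..start+len-1 of the guide", {
  expect_equal(extract_seed("GACTTGATCGAAGCTAGCTAA", 6), "ACTTGA")
  g <- paste0("GTCAAGGT", "ACGTACGTACGTA")  # positions 2-8 read TCAAGGT
  expect_equal(extract_seed(g, 6), "TCAAGG")
  expect_equal(extract_seed(g, 7), "TCAAGGT")
  expect_equal(substr(extract_seed(g, 7), 1, 6), extract_seed(g, 6))
  # RNA input is accepted
  expect_equal(extract_seed("ACGUUCGA", 6), "CGTTCG")
  expect_error(extract_seed("ACGUU", 6), "too short")
  expect_error(extract_seed(c(x = "ACGTNNGTA"), 6), "x")
})

test_that("printed fixture seeds extend hexamer to heptamer by one 5' base", {
  # the published table prints seeds in target-site orientation, so the
  # heptamer ends with the hexamer
  t1 <- fixture_table1()
  expect_true(all(substr(t1$heptamer, 2, 7) == t1$hexamer))
  expect_true(all(nchar(t1$hexamer) == 6L & nchar(t1$heptamer) == 7L))
})

test_that("seed index partitions the library and ignores row order", {
  lib <- data.frame(sirna_id = c("a", "b", "c"),
                    gene_id = c("g1", "g1", "g2"),
                    guide_seq = c("GACTTGATTTTTT", "GACTTGACCCCCC",
                                  "TTTTTTTTTTTTT"))
  idx <- build_seed_index(lib, 6)
  expect_equal(idx$size[idx$seed == "ACTTGA"], 2L)
  expect_equal(idx$sirna_ids[idx$seed == "ACTTGA"][[1]], c("a", "b"))
  expect_equal(sum(idx$size), nrow(lib))
  idx2 <- build_seed_index(lib[c(3, 1, 2), ], 6)
  expect_equal(idx, idx2, ignore_attr = TRUE)
  expect_error(build_seed_index(rbind(lib, lib[1, ]), 6), "duplicate")
  expect_equal(nrow(build_seed_index(lib[0, ], 6)), 0L)

  # conservation on a simulated library
  sim <- simulate_library(sim_config(n_genes = 400, rng_seed = 3))
  for (len in c(6, 7)) {
    expect_equal(sum(build_seed_index(sim$library, len)$size), 800L)
  }
})

test_that("top-k multiplicity reproduces the printed top-20 counts", {
  t1 <- fixture_table1()
  ids <- t1$symbol[order(-t1$score, t1$symbol)]
  hex <- top_k_seed_multiplicity(ids, setNames(t1$hexamer, t1$symbol), 20)
  expect_equal(hex$n_repeated, 3L)
  expect_equal(hex$max_count, 4L)
  expect_equal(unname(hex$counts["ACTTGA"]), 4L)
  expect_equal(unname(hex$counts[c("CAAGGT", "TGTCCA")]), c(2L, 2L))
  hept <- top_k_seed_multiplicity(ids, setNames(t1$heptamer, t1$symbol), 20)
  expect_equal(sum(hept$counts == 2L), 3L)
  expect_equal(hept$max_count, 2L)

  # all-distinct seeds
  d <- top_k_seed_multiplicity(letters[1:20], setNames(sprintf("S%02d", 1:20),
                                                       letters[1:20]), 20)
  expect_equal(d$n_repeated, 0L)
  expect_equal(d$max_count, 1L)
  expect_error(top_k_seed_multiplicity(ids, setNames(t1$hexamer, t1$symbol), 0),
               "positive")
  expect_error(top_k_seed_multiplicity(ids[1:5], t1$hexamer[1:5], 6), "exceeds")
})

test_that("k = n multiplicity equals the seed-index sizes", {
  sim <- simulate_library(sim_config(n_genes = 100, rng_seed = 9))
  seeds <- extract_seed(setNames(sim$library$guide_seq, sim$library$sirna_id), 6)
  m <- top_k_seed_multiplicity(sim$library$sirna_id, seeds, nrow(sim$library))
  idx <- build_seed_index(sim$library, 6)
  expect_equal(unname(m$counts[idx$seed]), idx$size)
})

test_that("seed swapping is positional, idempotent and round-trips", {
  s <- "GGGGGGGGGGGGGGGGGGGGG"
  s2 <- swap_seed(s, "ACTTGA")
  expect_equal(extract_seed(s2, 6), "ACTTGA")
  expect_equal(substr(s2, 1, 1), "G")
  expect_equal(substr(s2, 8, 21), substr(s, 8, 21))
  expect_equal(swap_seed(s2, "ACTTGA"), s2)
  # the published mutant seed differs from the enriched seed at 2 positions
  a <- strsplit("ACTTGA", "")[[1]]
  b <- strsplit("ATCTGA", "")[[1]]
  expect_equal(sum(a != b), 2L)
  expect_equal(extract_seed(swap_seed(s2, "ATCTGA"), 6), "ATCTGA")
  expect_error(swap_seed(s, "ACGT"), "length")
})

test_that("reverse complement is a DNA involution", {
  expect_equal(revcomp("ACTTGA"), "TCAAGT")
  expect_equal(revcomp("TAGGAA"), "TTCCTA")
  withr::local_seed(21)
  x <- vapply(1:20, function(i) {
    paste(sample(c("A", "C", "G", "T"), 12, TRUE), collapse = "")
  }, "")
  expect_equal(revcomp(revcomp(x)), x)
  expect_error(revcomp("ACGX"), "illegal")
})
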