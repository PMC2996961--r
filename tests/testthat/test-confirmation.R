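# Evidence archetypes mirroring the worked confirmation narratives.
ev_row <- function(gene, id, pheno, kd, expr = TRUE, screen = FALSE) {
  data.frame(sirna_id = paste0(gene, "_", id), gene_id = gene,
             phenotype_significant = pheno, knockdown_fraction = kd,
             expression_detectable = expr, was_screen_sirna = screen)
}

archetype <- function(gene, kind) {
  switch(kind,
    hit = rbind(ev_row(gene, 1, TRUE, 0.30, screen = TRUE),
                ev_row(gene, 2, TRUE, 0.35),
                ev_row(gene, 3, FALSE, 0.97)),
    hit_no_expression = rbind(ev_row(gene, 1, TRUE, NA, expr = FALSE, screen = TRUE),
                              ev_row(gene, 2, TRUE, NA, expr = FALSE),
                              ev_row(gene, 3, TRUE, NA, expr = FALSE)),
    ote = rbind(ev_row(gene, 1, TRUE, 0.50, screen = TRUE),
                ev_row(gene, 2, TRUE, 0.55),
                ev_row(gene, 3, FALSE, 0.30)),
    unconfirmed = rbind(ev_row(gene, 1, TRUE, 0.40, screen = TRUE),
                        ev_row(gene, 2, FALSE, 0.70),
                        ev_row(gene, 3, FALSE, 0.80)),
    false_positive = rbind(ev_row(gene, 1, FALSE, 0.40, screen = TRUE),
                           ev_row(gene, 2, FALSE, 0.60)))
}

test_that("the four worked confirmation narratives classify as published", {
  # two phenotype-positive siRNAs knock down, a third shows no knockdown
  expect_equal(classify_gene(archetype("IGF1R", "hit"))$status, "Hit")
  # the phenotype-negative siRNA has the strongest knockdown
  expect_equal(classify_gene(archetype("LRPAP1", "ote"))$status, "OffTarget")
  # only the screen siRNA phenocopies; others are weaker knockdowns
  expect_equal(classify_gene(archetype("GPR132", "unconfirmed"))$status,
               "Unconfirmed")
  # expression undetectable but three independent phenotype-positive siRNAs
  expect_equal(classify_gene(archetype("PDE11A", "hit_no_expression"))$status,
               "Hit")
  # non-reproducible screen phenotype
  expect_equal(classify_gene(archetype("KCNV1", "false_positive"))$status,
               "FalsePositive")
})

test_that("a strong phenotype-negative knockdown demotes a hit, never promotes", {
  hit_ev <- archetype("IGF1R", "hit")
  expect_equal(classify_gene(hit_ev)$status, "Hit")
  demoted <- rbind(hit_ev, ev_row("IGF1R", 9, FALSE, 0.10))
  expect_equal(classify_gene(demoted)$status, "OffTarget")
  # adding it to an already-off-target gene cannot promote
  ote_ev <- rbind(archetype("LRPAP1", "ote"), ev_row("LRPAP1", 9, FALSE, 0.05))
  expect_equal(classify_gene(ote_ev)$status, "OffTarget")
})

test_that("classification ignores evidence row order and rejects bad input", {
  ev <- archetype("IGF1R", "hit")
  for (i in 1:5) {
    expect_equal(classify_gene(ev[sample(nrow(ev)), ])$status, "Hit")
  }
  contradictory <- rbind(ev, transform(ev[1, ], knockdown_fraction = 0.9))
  expect_error(classify_gene(contradictory), "contradictory")
  expect_error(classify_gene(ev[0, ]), "no evidence")
  expect_error(classify_gene(transform(ev, was_screen_sirna = FALSE)),
               "screen siRNA")
  expect_error(classify_gene(rbind(ev, archetype("LRPAP1", "ote"))), "single")
})

test_that("knockdown comparison tolerates qPCR-level noise", {
  # phenotype-negative knockdown within the tolerance band of the positive
  # knockdowns is treated as "at least as strong" -> OffTarget
  ev <- rbind(ev_row("G", 1, TRUE, 0.40, screen = TRUE),
              ev_row("G", 2, TRUE, 0.42),
              ev_row("G", 3, FALSE, 0.44))
  expect_equal(classify_gene(ev, kd_tol = 0.05)$status, "OffTarget")
  expect_equal(classify_gene(ev, kd_tol = 0)$status, "Hit")
})

test_that("archetype evidence for all 20 fixture genes reproduces the status column", {
  t1 <- fixture_table1()
  kind_of <- c(Hit = "hit", OTE = "ote", Unconfirmed = "unconfirmed",
               `False +ve` = "false_positive")
  evidence <- do.call(rbind, lapply(seq_len(nrow(t1)), function(i) {
    gene <- t1$symbol[i]
    kind <- if (gene == "PDE11A") "hit_no_expression" else kind_of[[t1$status[i]]]
    archetype(gene, kind)
  }))
  got <- classify_genes(evidence)
  want <- ifelse(t1$status == "OTE", "OffTarget",
                 ifelse(t1$status == "False +ve", "FalsePositive", t1$status))
  expect_equal(got$status[match(t1$symbol, got$gene_id)], want)
})

test_that("retesting with additional siRNAs can reclassify a hit as off-target", {
  # two screen siRNAs phenocopy and knock down: looks like a hit
  tegt_screen <- rbind(ev_row("TEGT", 1, TRUE, 0.35, screen = TRUE),
                       ev_row("TEGT", 2, TRUE, 0.40, screen = TRUE))
  expect_equal(classify_gene(tegt_screen)$status, "Hit")
  # further independent siRNAs knock down but fail to phenocopy
  tegt_extra <- rbind(tegt_screen,
                      ev_row("TEGT", 3, FALSE, 0.30),
                      ev_row("TEGT", 4, FALSE, 0.38))
  expect_equal(classify_gene(tegt_extra)$status, "OffTarget")
})
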