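# Packaged reference fixtures: transcriptions of the published top-20
# siRNA table, the enriched-seed table and the known-TRAIL-gene list, plus
# a three-record mature-miRNA FASTA covering the published seed/miRNA
# pairs so the matching stage is testable without downloading miRBase.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "seedscreen")
  if (p == "") stop("fixture not found: ", file, call. = FALSE)
  p
}

#' Top-20 siRNA fixture table
#'
#' The published top-20 screen siRNAs: transcript, gene symbol, screen
#' score, hexamer and heptamer seed (printed in target-site orientation),
#' confirmation status (`Hit`, `OTE`, `Unconfirmed`, `False +ve`) and the
#' enriched-seed flag (`+` seed in an enriched set, `-` not, `*` repeated
#' in the top 20 only).
#'
#' @return Data frame with 20 rows.
#' @export
fixture_table1 <- function() {
  utils::read.delim(fixture_path("table1.tsv"), stringsAsFactors = FALSE,
                    colClasses = c(score = "numeric"))
}

#' Enriched-seed fixture table
#'
#' The published enriched seeds: seed, seed length (6 or 7), set size,
#' normalised enrichment score and FWER-corrected p-value.
#'
#' @return Data frame with 30 rows (17 hexamers, 13 heptamers).
#' @export
fixture_table2 <- function() {
  utils::read.delim(fixture_path("table2.tsv"), stringsAsFactors = FALSE)
}

#' Known TRAIL-pathway gene list fixture
#'
#' The 12 genes previously associated with TRAIL-induced apoptosis whose
#' siRNAs were present in the screened library, used for the known-gene
#' enrichment re-test after masking.
#'
#' @return Character vector of 12 gene symbols.
#' @export
fixture_known_genes <- function() {
  readLines(fixture_path("known_trail_genes.txt"))
}

#' Path to the packaged mature-miRNA FASTA fixture
#'
#' Three human mature miRNA records (miR-26a, miR-145, miR-384) in
#' miRBase `mature.fa` dialect.
#'
#' @return File path.
#' @export
fixture_mirna_fasta <- function() {
  fixture_path("mirna_mature.fa")
}
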