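#' Remove siRNAs carrying enriched seeds and re-rank
#'
#' An siRNA is removed when its hexamer seed is one of the enriched
#' hexamers or its heptamer seed is one of the enriched heptamers
#' (`mode = "seed_position"`), or when its guide contains any enriched
#' seed anywhere (`mode = "substring"`). Retained siRNAs keep their scores
#' and relative order and are re-ranked 1..m.
#'
#' @param ranked Score table with `sirna_id` and `score` columns (rows in
#'   rank order, or carrying a `rank` column; missing scores are dropped).
#' @param library siRNA library supplying the guide sequences from which
#'   seeds are taken (every ranked id must be present).
#' @param enriched_hexamers,enriched_heptamers Character vectors of
#'   enriched seeds (6-mers / 7-mers; either may be empty).
#' @param mode `"seed_position"` (default) or `"substring"`.
#' @param start 1-based seed start (default 2).
#' @return A list of class `mask_report`: `retained` (re-ranked data frame
#'   with `new_rank`), `removed_ids`, the seed lists and the mode.
#' @export
mask_enriched <- function(ranked, library, enriched_hexamers = character(0),
                          enriched_heptamers = character(0),
                          mode = c("seed_position", "substring"),
                          start = 2L) {
  mode <- match.arg(mode)
  library <- validate_library(library)
  if (!all(c("sirna_id", "score") %in% names(ranked))) {
    stop("ranked table needs 'sirna_id' and 'score' columns", call. = FALSE)
  }
  r <- ranked[!is.na(ranked$score), , drop = FALSE]
  unknown <- setdiff(r$sirna_id, library$sirna_id)
  if (length(unknown)) {
    stop("ranked sirna_id not present in the library: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  ehex <- if (length(enriched_hexamers)) {
    s <- norm_dna(enriched_hexamers, what = "enriched hexamer")
    if (any(nchar(s) != 6L)) stop("enriched hexamers must be 6-mers", call. = FALSE)
    s
  } else character(0)
  ehept <- if (length(enriched_heptamers)) {
    s <- norm_dna(enriched_heptamers, what = "enriched heptamer")
    if (any(nchar(s) != 7L)) stop("enriched heptamers must be 7-mers", call. = FALSE)
    s
  } else character(0)
  guides <- stats::setNames(library$guide_seq, library$sirna_id)[r$sirna_id]
  if (mode == "seed_position") {
    hex <- extract_seed(guides, 6L, start)
    hept <- extract_seed(guides, 7L, start)
    hit <- hex %in% ehex | hept %in% ehept
  } else {
    pat <- c(ehex, ehept)
    hit <- rep(FALSE, length(guides))
    for (p in pat) hit <- hit | grepl(p, guides, fixed = TRUE)
  }
  r <- r[order(-r$score, r$sirna_id), , drop = FALSE]
  hit <- hit[match(r$sirna_id, names(guides))]
  retained <- r[!hit, , drop = FALSE]
  retained$new_rank <- seq_len(nrow(retained))
  rownames(retained) <- NULL
  structure(list(retained = retained,
                 removed_ids = sort(r$sirna_id[hit]),
                 enriched_hexamers = ehex, enriched_heptamers = ehept,
                 mode = mode),
            class = "mask_report")
}

#' @export
print.mask_report <- function(x, ...) {
  cat("Mask report (", x$mode, "): ", length(x$removed_ids),
      " siRNA(s) removed, ", nrow(x$retained), " retained\n", sep = "")
  invisible(x)
}

#' Enrichment of a gene set in a (possibly masked) siRNA ranking
#'
#' Lifts a gene set to the siRNA level (all siRNAs targeting the listed
#' genes) and runs the pre-ranked enrichment analysis on that single set.
#' Used to ask whether known pathway genes concentrate among high-scoring
#' siRNAs, before and after enriched-seed masking.
#'
#' @param ranked Score table (`sirna_id`, `score`) or named score vector.
#' @param library siRNA library mapping siRNAs to genes.
#' @param genes Character vector of gene ids; genes absent from the
#'   library are skipped with a warning.
#' @param n_perm,p_weight,rng_seed Passed to [gsea_preranked()].
#' @return One-row `gsea_result` data frame for the gene set.
#' @export
known_gene_enrichment <- function(ranked, library, genes, n_perm = 1000L,
                                  p_weight = 1, rng_seed = NULL) {
  library <- validate_library(library)
  genes <- unique(as.character(genes))
  absent <- setdiff(genes, library$gene_id)
  if (length(absent)) {
    warning("gene(s) absent from the library skipped: ",
            paste(absent, collapse = ", "), call. = FALSE)
    genes <- setdiff(genes, absent)
  }
  members <- library$sirna_id[library$gene_id %in% genes]
  v <- as_ranked(ranked)
  members <- intersect(members, names(v))
  if (!length(members)) stop("gene set maps to no ranked siRNAs", call. = FALSE)
  if (length(members) >= length(v)) {
    stop("gene set covers the whole ranked universe", call. = FALSE)
  }
  gsea_preranked(v, stats::setNames(list(members), "known_genes"),
                 n_perm = n_perm, p_weight = p_weight,
                 min_size = min(2L, length(members)), rng_seed = rng_seed)
}
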