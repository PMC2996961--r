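#' Configuration for the full analysis pipeline
#'
#' @param library siRNA library: path to a TSV or a data frame.
#' @param measurements Measurement table: path (TSV/CSV) or data frame.
#' @param out_dir Output directory (created if missing).
#' @param mirna_fasta Optional mature-miRNA FASTA path for the seed/miRNA
#'   matching stage.
#' @param known_genes Optional known-gene set (character vector or path to
#'   a one-gene-per-line file) re-tested before and after masking.
#' @param k Top-k cut for the seed multiplicity test (default 20).
#' @param n_iter Iterations of the sampling multiplicity null (default 5000).
#' @param n_perm Permutations of the enrichment null (default 1000).
#' @param p_weight Enrichment hit-weighting exponent (default 1).
#' @param min_size Minimum seed-set size for the enrichment stage (default 5).
#' @param fwer_threshold FWER cut-off for enriched seeds (default 0.05).
#' @param seed_lengths Seed lengths analysed (default 6 and 7).
#' @param mask_mode `"seed_position"` or `"substring"`.
#' @param match_mode Orientation mode for miRNA matching (default `"both"`).
#' @param viability_fraction Viability filter fraction (default 0.2).
#' @param scale_within `"replicate"` or `"plate"` (see [score_replicate()]).
#' @param rng_seed Master RNG seed for the stochastic stages (default 1).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(library, measurements, out_dir,
                            mirna_fasta = NULL, known_genes = NULL,
                            k = 20L, n_iter = 5000L, n_perm = 1000L,
                            p_weight = 1, min_size = 5L,
                            fwer_threshold = 0.05, seed_lengths = c(6L, 7L),
                            mask_mode = "seed_position", match_mode = "both",
                            viability_fraction = 0.2,
                            scale_within = "replicate", rng_seed = 1L) {
  if (fwer_threshold <= 0 || fwer_threshold > 1) {
    stop("fwer_threshold must be in (0, 1]", call. = FALSE)
  }
  structure(list(library = library, measurements = measurements,
                 out_dir = out_dir, mirna_fasta = mirna_fasta,
                 known_genes = known_genes, k = as.integer(k),
                 n_iter = as.integer(n_iter), n_perm = as.integer(n_perm),
                 p_weight = p_weight, min_size = as.integer(min_size),
                 fwer_threshold = fwer_threshold,
                 seed_lengths = as.integer(seed_lengths),
                 mask_mode = mask_mode, match_mode = match_mode,
                 viability_fraction = viability_fraction,
                 scale_within = scale_within,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  do.call(pipeline_config, yaml::read_yaml(path))
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full seed off-target analysis pipeline
#'
#' Chains every stage: screen scoring, seed extraction, top-k multiplicity
#' test, seed-set enrichment analysis, enriched-seed masking with known-gene
#' re-test, and miRNA matching. All stage tables are written as TSV to
#' `out_dir`, a machine-readable summary as `summary.json`, and a run log
#' as `pipeline.log`. A stage failure aborts with an error naming the
#' stage; outputs of completed stages are preserved.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  log <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    writeLines(line, log_con)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  log("seedscreen ", as.character(utils::packageVersion("seedscreen")),
      ", rng_seed = ", config$rng_seed)
  local_seed(config$rng_seed)

  library <- stage("inputs", {
    if (is.character(config$library)) read_sirna_library(config$library)
    else validate_library(config$library)
  })
  measurements <- stage("inputs", {
    if (is.character(config$measurements)) {
      read_measurements(config$measurements, library)
    } else {
      validate_measurements(config$measurements, library)
    }
  })

  scores <- stage("score", score_screen(library, measurements,
                                        config$viability_fraction,
                                        config$scale_within))
  .write_tsv(scores, file.path(config$out_dir, "scores.tsv"))
  wells <- attr(scores, "wells")
  qc <- stage("score", {
    out <- list()
    for (r in sort(unique(wells$replicate))) {
      w <- wells[wells$replicate == r, ]
      pos <- w$normalized[w$role == "pos_ctrl"]
      neg <- w$normalized[w$role == "neg_ctrl"]
      out[[paste0("zprime_rep", r)]] <-
        if (length(pos) >= 2L && length(neg) >= 2L) zprime(pos, neg) else NA_real_
    }
    out
  })
  log("scored ", sum(!is.na(scores$score)), "/", nrow(scores), " siRNAs; ",
      paste(names(qc), format(unlist(qc), digits = 3), collapse = ", "))

  ranked <- scores[!is.na(scores$score), c("sirna_id", "score")]
  ranked_ids <- ranked$sirna_id

  guides <- stats::setNames(library$guide_seq, library$sirna_id)
  per_len <- list()
  for (len in config$seed_lengths) {
    key <- paste0("len", len)
    seeds <- stage("seeds", extract_seed(guides, len))
    idx <- stage("seeds", build_seed_index(library, len))
    .write_tsv(data.frame(seed = idx$seed, length = len, size = idx$size,
                          sirna_ids = vapply(idx$sirna_ids, paste,
                                             "", collapse = ",")),
               file.path(config$out_dir, sprintf("seed_index_%dmer.tsv", len)))

    mult <- stage("topk_test",
                  top_k_seed_multiplicity(ranked_ids, seeds, config$k))
    null_rep <- stage("topk_test",
                      sample_null(unname(seeds), config$k, config$n_iter,
                                  statistic = "n_repeated"))
    p_rep <- empirical_p(null_rep, mult$n_repeated)
    null_max <- stage("topk_test",
                      sample_null(unname(seeds), config$k, config$n_iter,
                                  statistic = "max_count"))
    p_max <- empirical_p(null_max, mult$max_count)
    log(len, "-mer top-", config$k, ": n_repeated = ", mult$n_repeated,
        " (", p_rep$label, "), max_count = ", mult$max_count,
        " (", p_max$label, ")")

    res <- stage("gsea", suppressWarnings(
      gsea_preranked(ranked, idx, n_perm = config$n_perm,
                     p_weight = config$p_weight,
                     min_size = config$min_size)))
    .write_tsv(res, file.path(config$out_dir,
                              sprintf("enrichment_%dmer.tsv", len)))
    enr <- select_enriched(res, config$fwer_threshold)
    log(len, "-mer enrichment: ", nrow(enr), " seed(s) at FWER <= ",
        config$fwer_threshold)
    per_len[[key]] <- list(
      length = len,
      multiplicity = list(n_repeated = mult$n_repeated,
                          max_count = mult$max_count,
                          p_n_repeated = p_rep$p,
                          p_n_repeated_label = p_rep$label,
                          p_max_count = p_max$p,
                          p_max_count_label = p_max$label),
      n_sets_tested = nrow(res),
      enriched_seeds = enr$name,
      enriched_nes = enr$nes)
  }

  ehex <- if (6L %in% config$seed_lengths) per_len$len6$enriched_seeds else character(0)
  ehept <- if (7L %in% config$seed_lengths) per_len$len7$enriched_seeds else character(0)
  mask <- stage("mask", mask_enriched(ranked, library, ehex, ehept,
                                      mode = config$mask_mode))
  .write_tsv(data.frame(sirna_id = mask$retained$sirna_id,
                        gene_id = library$gene_id[match(mask$retained$sirna_id,
                                                        library$sirna_id)],
                        score = mask$retained$score,
                        new_rank = mask$retained$new_rank),
             file.path(config$out_dir, "masked_ranking.tsv"))
  log("masking removed ", length(mask$removed_ids), " siRNA(s)")

  known <- NULL
  if (!is.null(config$known_genes)) {
    genes <- if (is.character(config$known_genes) &&
                 length(config$known_genes) == 1L &&
                 file.exists(config$known_genes)) {
      readLines(config$known_genes)
    } else {
      as.character(config$known_genes)
    }
    before <- stage("rerank_test",
                    known_gene_enrichment(ranked, library, genes,
                                          n_perm = config$n_perm,
                                          p_weight = config$p_weight))
    after <- stage("rerank_test",
                   known_gene_enrichment(mask$retained, library, genes,
                                         n_perm = config$n_perm,
                                         p_weight = config$p_weight))
    known <- list(genes = genes,
                  before = list(es = before$es, nes = before$nes,
                                p_nominal = before$p_nominal),
                  after = list(es = after$es, nes = after$nes,
                               p_nominal = after$p_nominal))
    log("known-gene enrichment p: ", format(before$p_nominal, digits = 3),
        " -> ", format(after$p_nominal, digits = 3), " after masking")
  }

  matches <- NULL
  if (!is.null(config$mirna_fasta)) {
    mir <- stage("mirna", read_mature_fasta(config$mirna_fasta))
    tabs <- list()
    for (len in config$seed_lengths) {
      enr <- per_len[[paste0("len", len)]]$enriched_seeds
      if (length(enr)) {
        tab <- stage("mirna", suppressWarnings(
          match_seeds(enr, mir, seed_length = len, mode = config$match_mode)))
        if (nrow(tab)) tab$length <- len
        tabs[[as.character(len)]] <- tab
      }
    }
    matches <- do.call(rbind, tabs[lengths(tabs) > 0])
    if (is.null(matches) || !nrow(matches)) {
      matches <- data.frame(seed = character(0), mirna = character(0),
                            orientation = character(0), length = integer(0))
    }
    rownames(matches) <- NULL
    .write_tsv(matches, file.path(config$out_dir, "mirna_matches.tsv"))
    log("miRNA matching: ", nrow(matches), " pair(s)")
  }

  summary <- list(
    n_sirnas = nrow(library),
    n_scored = sum(!is.na(scores$score)),
    qc = qc,
    seeds = per_len,
    n_masked = length(mask$removed_ids),
    known_gene = known,
    mirna_matches = matches,
    parameters = list(k = config$k, n_iter = config$n_iter,
                      n_perm = config$n_perm, p_weight = config$p_weight,
                      min_size = config$min_size,
                      fwer_threshold = config$fwer_threshold,
                      seed_lengths = config$seed_lengths,
                      mask_mode = config$mask_mode,
                      match_mode = config$match_mode,
                      viability_fraction = config$viability_fraction,
                      rng_seed = config$rng_seed))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  log("pipeline complete")
  invisible(summary)
}
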