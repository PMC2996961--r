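#' Extract the seed of a guide sequence
#'
#' The seed is the stretch of `length` nucleotides starting at position
#' `start` (1-based) of the guide strand read 5'->3': positions 2-7 for
#' the hexamer seed and 2-8 for the heptamer seed under the defaults.
#' U is mapped to T so RNA- and DNA-written sequences agree.
#'
#' @param guide_seq Character vector of guide sequences (names, if present,
#'   are used to identify offenders in error messages).
#' @param length Seed length (6 = hexamer, 7 = heptamer).
#' @param start 1-based start position of the seed (default 2).
#' @return Character vector of seeds (names preserved).
#' @export
extract_seed <- function(guide_seq, length = 6L, start = 2L) {
  if (!is.numeric(length) || length < 1L) stop("length must be >= 1", call. = FALSE)
  if (!is.numeric(start) || start < 1L) stop("start must be >= 1", call. = FALSE)
  ids <- names(guide_seq)
  x <- norm_dna(guide_seq, ids = ids, what = "guide sequence")
  need <- start + length - 1L
  short <- nchar(x) < need
  if (any(short)) {
    lab <- if (!is.null(ids)) ids[short] else x[short]
    stop("guide sequence too short for a ", length, "-mer seed at position ",
         start, ": ", paste(utils::head(lab, 5L), collapse = ", "),
         call. = FALSE)
  }
  out <- substr(x, start, need)
  names(out) <- ids
  out
}

#' Index a library by seed
#'
#' Partitions the siRNAs of a library by their seed of the given length:
#' the per-seed member lists are the "gene sets" used by the enrichment
#' analysis, and the per-seed sizes sum to the library size.
#'
#' @param library siRNA library data frame (`sirna_id`, `gene_id`,
#'   `guide_seq`).
#' @param length Seed length (6 or 7 typically).
#' @param start 1-based seed start (default 2).
#' @return A data frame of class `seed_index` with columns `seed`, `size`
#'   and a list column `sirna_ids` (members sorted by id), ordered by
#'   decreasing size then seed. Seed length/start are attached as
#'   attributes.
#' @export
build_seed_index <- function(library, length = 6L, start = 2L) {
  library <- validate_library(library)
  if (!nrow(library)) {
    idx <- data.frame(seed = character(0), size = integer(0))
    idx$sirna_ids <- list()
  } else {
    seeds <- extract_seed(stats::setNames(library$guide_seq, library$sirna_id),
                          length, start)
    sp <- lapply(split(library$sirna_id, seeds), sort)
    idx <- data.frame(seed = names(sp), size = unname(lengths(sp)))
    idx$sirna_ids <- unname(sp)
    idx <- idx[order(-idx$size, idx$seed), , drop = FALSE]
    rownames(idx) <- NULL
  }
  attr(idx, "seed_length") <- as.integer(length)
  attr(idx, "seed_start") <- as.integer(start)
  class(idx) <- c("seed_index", "data.frame")
  idx
}

#' Seed multiplicity among the top-k siRNAs
#'
#' Counts how often each seed occurs among the `k` highest-ranked siRNAs
#' and summarises the repetition structure: `n_repeated` is the number of
#' distinct seeds occurring at least twice, `max_count` the largest
#' multiplicity.
#'
#' @param ranked_ids siRNA ids in rank order (rank 1 first).
#' @param seeds Seeds, either named by `sirna_id` or positionally parallel
#'   to `ranked_ids`.
#' @param k How many top siRNAs to consider.
#' @return A list of class `seed_multiplicity`: `k`, `counts` (named
#'   integer vector, decreasing, ties by seed), `n_repeated`, `max_count`.
#' @export
top_k_seed_multiplicity <- function(ranked_ids, seeds, k) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0) {
    stop("k must be a positive integer", call. = FALSE)
  }
  if (k > length(ranked_ids)) {
    stop("k exceeds the number of ranked siRNAs", call. = FALSE)
  }
  top <- ranked_ids[seq_len(k)]
  if (!is.null(names(seeds))) {
    if (!all(top %in% names(seeds))) {
      stop("no seed available for: ",
           paste(utils::head(setdiff(top, names(seeds)), 5L), collapse = ", "),
           call. = FALSE)
    }
    s <- unname(seeds[top])
  } else {
    if (length(seeds) != length(ranked_ids)) {
      stop("unnamed seeds must be parallel to ranked_ids", call. = FALSE)
    }
    s <- seeds[seq_len(k)]
  }
  tb <- table(s)
  counts <- as.integer(tb)
  names(counts) <- names(tb)
  counts <- counts[order(-counts, names(counts))]
  structure(list(k = as.integer(k), counts = counts,
                 n_repeated = sum(counts >= 2L),
                 max_count = max(counts)),
            class = "seed_multiplicity")
}

#' @export
print.seed_multiplicity <- function(x, ...) {
  cat("Seed multiplicity among top", x$k, "siRNAs:",
      x$n_repeated, "seed(s) repeated, max count", x$max_count, "\n")
  rep_counts <- x$counts[x$counts >= 2L]
  if (length(rep_counts)) {
    cat(paste0("  ", names(rep_counts), " x", rep_counts, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Replace the seed of a sequence
#'
#' Writes `new_seed` into the seed position of `sequence`, leaving every
#' other position unchanged (the operation used to transplant a candidate
#' seed into an otherwise inert carrier siRNA).
#'
#' @param sequence Sequence(s) to modify.
#' @param new_seed Replacement seed.
#' @param start 1-based seed start (default 2).
#' @param lengths Allowed replacement lengths (default 6 and 7).
#' @return The modified sequence(s).
#' @export
swap_seed <- function(sequence, new_seed, start = 2L, lengths = c(6L, 7L)) {
  s <- norm_dna(sequence, what = "sequence")
  ns <- norm_dna(new_seed, what = "replacement seed")
  if (length(ns) != 1L) stop("new_seed must be a single seed", call. = FALSE)
  len <- nchar(ns)
  if (!len %in% lengths) {
    stop("replacement seed must have length ", paste(lengths, collapse = " or "),
         ", got ", len, call. = FALSE)
  }
  if (any(nchar(s) < start + len - 1L)) {
    stop("sequence too short to hold the replacement seed", call. = FALSE)
  }
  substr(s, start, start + len - 1L) <- ns
  names(s) <- names(sequence)
  s
}

#' Reverse complement
#'
#' DNA-alphabet reverse complement (U is normalised to T first).
#'
#' @param x Character vector of sequences.
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  x <- norm_dna(x, what = "sequence")
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}
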