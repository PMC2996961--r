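#' Read mature miRNA sequences from a miRBase-style FASTA
#'
#' Headers are expected to begin with the miRNA name token (e.g.
#' `>hsa-miR-145 MIMAT0000437 ...`); an accession, when present as a
#' second token, is kept. Sequences are normalised to uppercase RNA
#' (T is mapped to U).
#'
#' @param path FASTA file path.
#' @param human_only Keep only records whose name starts with `hsa-`
#'   (default TRUE).
#' @return A data frame with `name`, `accession` (NA when absent) and
#'   `mature_seq` columns.
#' @export
read_mature_fasta <- function(path, human_only = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  if (!length(seqs)) stop("no FASTA records in ", path, call. = FALSE)
  header <- names(seqs)
  name <- sub("\\s.*$", "", header)
  accession <- ifelse(grepl("\\s", header),
                      sub("^\\S+\\s+(\\S+).*$", "\\1", header), NA_character_)
  seq <- toupper(as.character(seqs))
  if (any(nchar(seq) == 0L)) {
    stop("FASTA record(s) without sequence: ",
         paste(name[nchar(seq) == 0L], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(name)) {
    stop("duplicate miRNA names in ", path, ": ",
         paste(unique(name[duplicated(name)]), collapse = ", "), call. = FALSE)
  }
  seq <- chartr("T", "U", seq)
  bad <- grepl("[^ACGU]", seq)
  if (any(bad)) {
    stop("illegal character in mature sequence of: ",
         paste(name[bad], collapse = ", "), call. = FALSE)
  }
  if (human_only) {
    keep <- startsWith(name, "hsa-")
    if (!any(keep)) stop("no human (hsa-) records in ", path, call. = FALSE)
    name <- name[keep]
    accession <- accession[keep]
    seq <- seq[keep]
  }
  short <- nchar(seq) < 8L
  if (any(short)) {
    stop("mature sequence shorter than 8 nt: ",
         paste(name[short], collapse = ", "), call. = FALSE)
  }
  data.frame(name = name, accession = accession, mature_seq = unname(seq),
             row.names = NULL)
}

#' Seed of a mature miRNA
#'
#' Positions 2 to `seed_length + 1` of the mature sequence, returned in
#' the DNA alphabet (U mapped to T) so miRNA seeds and siRNA seeds
#' compare directly.
#'
#' @param mature_seq Mature miRNA sequence(s), RNA or DNA alphabet.
#' @param seed_length Seed length (default 6).
#' @return Character vector of seeds.
#' @export
mirna_seed <- function(mature_seq, seed_length = 6L) {
  extract_seed(mature_seq, length = seed_length, start = 2L)
}

#' Match enriched screen seeds against miRNA seeds
#'
#' A pair (enriched seed, miRNA) is emitted when the enriched seed equals
#' the miRNA seed (`identical` orientation) or its reverse complement
#' (`revcomp`). Which orientation is meaningful depends on the strand
#' convention of the screen's library table -- seeds read from guide
#' strands align with miRNA seeds under identity, seeds printed in
#' target-site orientation align under reverse complement -- so the
#' default reports both, labelled.
#'
#' @param enriched_seeds Character vector of enriched seeds (all of length
#'   `seed_length`).
#' @param mirnas Data frame from [read_mature_fasta()].
#' @param seed_length Seed length to compare at (default 6).
#' @param mode `"both"` (default), `"identical"` or `"revcomp"`.
#' @return Data frame with columns `seed`, `mirna`, `orientation`; unique
#'   rows, ordered by seed, miRNA, orientation.
#' @export
match_seeds <- function(enriched_seeds, mirnas, seed_length = 6L,
                        mode = c("both", "identical", "revcomp")) {
  mode <- match.arg(mode)
  empty <- data.frame(seed = character(0), mirna = character(0),
                      orientation = character(0))
  if (!length(enriched_seeds)) return(empty)
  es <- unique(norm_dna(enriched_seeds, what = "enriched seed"))
  if (any(nchar(es) != seed_length)) {
    stop("enriched seeds must all have length ", seed_length, call. = FALSE)
  }
  if (!all(c("name", "mature_seq") %in% names(mirnas))) {
    stop("mirnas must be a data frame from read_mature_fasta()", call. = FALSE)
  }
  usable <- nchar(mirnas$mature_seq) >= seed_length + 1L
  if (any(!usable)) {
    warning("mature sequence too short for a ", seed_length, "-mer seed, skipped: ",
            paste(mirnas$name[!usable], collapse = ", "), call. = FALSE)
  }
  mir <- mirnas[usable, , drop = FALSE]
  mseed <- mirna_seed(mir$mature_seq, seed_length)
  out <- empty
  if (mode %in% c("both", "identical")) {
    hit <- outer(es, mseed, "==")
    ij <- which(hit, arr.ind = TRUE)
    if (nrow(ij)) {
      out <- rbind(out, data.frame(seed = es[ij[, 1L]],
                                   mirna = mir$name[ij[, 2L]],
                                   orientation = "identical"))
    }
  }
  if (mode %in% c("both", "revcomp")) {
    hit <- outer(es, revcomp(mseed), "==")
    ij <- which(hit, arr.ind = TRUE)
    if (nrow(ij)) {
      out <- rbind(out, data.frame(seed = es[ij[, 1L]],
                                   mirna = mir$name[ij[, 2L]],
                                   orientation = "revcomp"))
    }
  }
  out <- unique(out)
  out <- out[order(out$seed, out$mirna, out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  out
}
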