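# Rule system turning confirmation-assay evidence into a four-way gene
# status. Evidence per siRNA: did the phenotype reproduce in the secondary
# assay, how much target mRNA remained after knockdown (lower = stronger),
# was target expression detectable, and was the siRNA the original screen
# siRNA.

.gene_statuses <- c("Hit", "OffTarget", "Unconfirmed", "FalsePositive")

#' Classify one gene from confirmation-assay evidence
#'
#' Encodes the confirmation rules of a two-stage screen follow-up:
#'
#' * **FalsePositive** -- the screen siRNA's phenotype does not reproduce
#'   in the secondary assay.
#' * **Hit** -- at least two phenotype-positive siRNAs show measured
#'   knockdown and every one of them knocks down more strongly (lower
#'   fraction of mRNA remaining, by more than `kd_tol`) than every
#'   phenotype-negative siRNA. Special case: when expression is
#'   undetectable for every siRNA, three or more phenotype-positive
#'   siRNAs suffice.
#' * **OffTarget** -- the phenotype reproduces but some phenotype-negative
#'   siRNA knocks down at least as strongly as a phenotype-positive one
#'   (within `kd_tol`), or the phenotype-positive siRNAs show no
#'   measurable knockdown at all: the phenotype cannot be attributed to
#'   loss of the intended target.
#' * **Unconfirmed** -- the phenotype reproduces but the corroborating
#'   siRNAs neither phenocopy nor knock down as strongly; the evidence is
#'   inconclusive.
#'
#' @param evidence Data frame with one row per tested siRNA: `sirna_id`,
#'   `gene_id`, `phenotype_significant` (logical), `knockdown_fraction`
#'   (fraction of target mRNA remaining, in `[0,1]`, `NA` when
#'   unmeasured), `expression_detectable` (logical),
#'   `was_screen_sirna` (logical).
#' @param kd_tol Absolute tolerance on knockdown-fraction comparisons
#'   (default 0.05), so that qPCR-level noise does not decide a call. A
#'   fraction remaining above `1 - kd_tol` counts as no knockdown.
#' @return A list of class `gene_status`: `gene_id`, `status` (one of
#'   `Hit`, `OffTarget`, `Unconfirmed`, `FalsePositive`) and a one-line
#'   `rationale`.
#' @export
classify_gene <- function(evidence, kd_tol = 0.05) {
  ev <- validate_evidence(evidence)
  gene <- unique(ev$gene_id)
  if (length(gene) != 1L) {
    stop("classify_gene() expects evidence for a single gene; got: ",
         paste(gene, collapse = ", "), call. = FALSE)
  }
  ev <- ev[order(ev$sirna_id), , drop = FALSE]   # row order never matters
  screen <- ev$was_screen_sirna
  if (!any(screen)) stop("no screen siRNA identified for gene ", gene, call. = FALSE)
  status <- function(s, why) {
    structure(list(gene_id = gene, status = s, rationale = why),
              class = "gene_status")
  }
  if (!any(ev$phenotype_significant[screen])) {
    return(status("FalsePositive",
                  "screen siRNA phenotype not reproduced in the secondary assay"))
  }
  pos <- ev$phenotype_significant
  n_pos <- sum(pos)
  if (!any(ev$expression_detectable)) {
    if (n_pos >= 3L) {
      return(status("Hit", paste0("expression undetectable; ", n_pos,
                                  " independent siRNAs phenocopy")))
    }
    return(status("Unconfirmed",
                  "expression undetectable and fewer than 3 phenotype-positive siRNAs"))
  }
  kd <- ev$knockdown_fraction
  pos_kd <- kd[pos & !is.na(kd)]
  neg_kd <- kd[!pos & !is.na(kd)]
  no_kd_cut <- 1 - kd_tol
  eff_pos <- pos_kd[pos_kd < no_kd_cut]
  if (n_pos >= 2L && length(eff_pos) >= 2L &&
      (!length(neg_kd) || max(pos_kd) < min(neg_kd) - kd_tol)) {
    return(status("Hit", paste0(length(eff_pos),
                                " phenotype-positive siRNAs knock down more ",
                                "strongly than any phenotype-negative siRNA")))
  }
  if (length(neg_kd) && length(pos_kd) &&
      min(neg_kd) <= max(pos_kd) + kd_tol) {
    return(status("OffTarget",
                  "a phenotype-negative siRNA knocks down at least as strongly as a phenotype-positive one"))
  }
  if (length(pos_kd) && !length(eff_pos)) {
    return(status("OffTarget",
                  "phenotype-positive siRNAs show no measurable knockdown"))
  }
  status("Unconfirmed",
         "corroborating siRNAs neither phenocopy nor knock down as strongly")
}

#' Classify several genes at once
#'
#' @param evidence Evidence rows for any number of genes (see
#'   [classify_gene()]).
#' @param kd_tol Passed to [classify_gene()].
#' @return Data frame with `gene_id`, `status`, `rationale`, one row per
#'   gene, ordered by `gene_id`.
#' @export
classify_genes <- function(evidence, kd_tol = 0.05) {
  ev <- validate_evidence(evidence)
  out <- lapply(split(ev, ev$gene_id), classify_gene, kd_tol = kd_tol)
  data.frame(gene_id = vapply(out, `[[`, "", "gene_id"),
             status = vapply(out, `[[`, "", "status"),
             rationale = vapply(out, `[[`, "", "rationale"),
             row.names = NULL)
}

validate_evidence <- function(evidence) {
  need <- c("sirna_id", "gene_id", "phenotype_significant",
            "knockdown_fraction", "expression_detectable", "was_screen_sirna")
  miss <- setdiff(need, names(evidence))
  if (length(miss)) {
    stop("evidence is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ev <- evidence[, need, drop = FALSE]
  if (!nrow(ev)) stop("no evidence rows", call. = FALSE)
  ev$sirna_id <- as.character(ev$sirna_id)
  ev$gene_id <- as.character(ev$gene_id)
  kd <- ev$knockdown_fraction
  if (any(!is.na(kd) & (kd < 0 | kd > 1))) {
    stop("knockdown_fraction must lie in [0, 1] when measured", call. = FALSE)
  }
  ev <- unique(ev)
  if (anyDuplicated(ev$sirna_id)) {
    dup <- unique(ev$sirna_id[duplicated(ev$sirna_id)])
    stop("contradictory duplicate evidence rows for: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  ev
}

#' @export
print.gene_status <- function(x, ...) {
  cat(x$gene_id, ": ", x$status, " (", x$rationale, ")\n", sep = "")
  invisible(x)
}
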