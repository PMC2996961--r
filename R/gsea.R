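# Pre-ranked set-enrichment engine: weighted running-sum enrichment score,
# size-matched permutation null, NES normalisation and max-NES FWER.

# Normalise a ranking (data frame or named numeric) to a named numeric
# vector sorted by decreasing score, ties broken by id.
as_ranked <- function(ranked) {
  if (is.data.frame(ranked)) {
    idcol <- intersect(c("item_id", "sirna_id"), names(ranked))
    if (!length(idcol) || !"score" %in% names(ranked)) {
      stop("ranked data frame needs an 'item_id' (or 'sirna_id') and a 'score' column",
           call. = FALSE)
    }
    v <- stats::setNames(as.numeric(ranked$score),
                         as.character(ranked[[idcol[1L]]]))
  } else {
    v <- ranked
  }
  if (is.null(names(v)) || any(names(v) == "")) {
    stop("ranked scores must be named by item id", call. = FALSE)
  }
  if (anyDuplicated(names(v))) {
    stop("duplicate item ids in ranked list", call. = FALSE)
  }
  if (anyNA(v)) {
    message(sum(is.na(v)), " item(s) with missing score dropped from the ranking")
    v <- v[!is.na(v)]
  }
  if (!length(v)) stop("empty ranked list", call. = FALSE)
  v[order(-v, names(v))]
}

# Coerce sets (named list, or a seed_index data frame) to a named list of
# character vectors.
as_item_sets <- function(sets) {
  if (is.data.frame(sets)) {
    if (!all(c("seed", "sirna_ids") %in% names(sets))) {
      stop("set data frame needs 'seed' and 'sirna_ids' columns", call. = FALSE)
    }
    sets <- stats::setNames(sets$sirna_ids, sets$seed)
  }
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    stop("sets must be a named list of item id vectors", call. = FALSE)
  }
  lapply(sets, as.character)
}

# Enrichment score from sorted member ranks only (O(set size)); `w` is
# |score|^p over the full ranked list. The running sum attains its
# extremes immediately after a hit (maxima) or just before one (minima),
# so only those 2n values need to be examined.
.es_from_ranks <- function(ranks, w, N) {
  n <- length(ranks)
  wi <- w[ranks]
  denom <- sum(wi)
  if (denom > 0) {
    cw <- cumsum(wi) / denom
    step <- wi / denom
  } else {                      # all member scores zero: unweighted fallback
    cw <- seq_len(n) / n
    step <- rep.int(1 / n, n)
  }
  d <- 1 / (N - n)
  P <- cw - (ranks - seq_len(n)) * d   # running sum just after each hit
  Q <- P - step                        # running sum just before each hit
  .es_pick(max(P), min(Q))
}

# Signed maximum deviation with a deterministic sign convention: when the
# positive and negative extremes tie in magnitude (to within floating
# point), the positive one is reported.
.es_pick <- function(mx, mn) {
  if (mx >= -mn - 1e-12) mx else mn
}

#' Running-sum enrichment score of a set in a ranked list
#'
#' Walks the ranked list from top to bottom keeping a running sum: meeting
#' a set member ("hit") adds its weight
#' \eqn{|s|^{p} / \sum_{members} |s|^{p}}, meeting a non-member subtracts
#' \eqn{1/(N - n)}. The enrichment score is the signed maximum deviation
#' of the running sum from zero: near +1 when the members concentrate at
#' the top of the list, near -1 when they concentrate at the bottom.
#' `p_weight = 0` gives the classic unweighted Kolmogorov-Smirnov-like
#' statistic; `p_weight = 1` (default) weights hits by their score
#' magnitude.
#'
#' @param ranked Ranked list: a data frame with `item_id` (or `sirna_id`)
#'   and `score` columns, or a named numeric vector. Sorted internally by
#'   decreasing score, ties by id.
#' @param members Item ids forming the set. Must be a non-empty strict
#'   subset of the ranked universe.
#' @param p_weight Hit-weighting exponent (default 1).
#' @return A list: `es`, the full `running` sum profile, `hits` (member
#'   positions in the ranking), `n` (set size), `N` (universe size).
#' @export
enrichment_score <- function(ranked, members, p_weight = 1) {
  v <- as_ranked(ranked)
  N <- length(v)
  members <- unique(as.character(members))
  hit <- names(v) %in% members
  n <- sum(hit)
  if (n == 0L) stop("set has no members in the ranked universe", call. = FALSE)
  if (n == N) {
    stop("set equals the ranked universe; enrichment is undefined", call. = FALSE)
  }
  w <- abs(v)^p_weight
  denom <- sum(w[hit])
  inc <- numeric(N)
  if (denom > 0) {
    inc[hit] <- w[hit] / denom
  } else {
    inc[hit] <- 1 / n
  }
  inc[!hit] <- -1 / (N - n)
  running <- cumsum(inc)
  list(es = .es_pick(max(running), min(running)), running = unname(running),
       hits = which(hit), n = n, N = N)
}

#' Pre-ranked enrichment analysis with permutation NES and FWER
#'
#' Computes the enrichment score of every set, builds a null per set from
#' `n_perm` random member sets of equal size drawn from the universe,
#' normalises (NES = ES divided by the mean of same-sign null ES), and
#' corrects family-wide: the FWER p of a set is the fraction of
#' permutations in which the maximum same-sign null NES across *all* sets
#' is at least as extreme as the set's NES.
#'
#' @param ranked Ranked list (see [enrichment_score()]).
#' @param sets Named list of item-id vectors, or a [build_seed_index()]
#'   result.
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param p_weight Hit-weighting exponent (default 1).
#' @param min_size Sets with fewer members in the universe are dropped
#'   with a warning (default 5).
#' @param rng_seed Optional integer seed for reproducible permutations.
#' @return A data frame of class `gsea_result`, one row per retained set:
#'   `name`, `size`, `es`, `nes`, `p_nominal` (add-one, same-sign tail),
#'   `fwer_p`, ordered by decreasing NES.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000L, p_weight = 1,
                           min_size = 5L, rng_seed = NULL) {
  v <- as_ranked(ranked)
  N <- length(v)
  sets <- as_item_sets(sets)
  if (n_perm < 100L) stop("n_perm must be at least 100", call. = FALSE)
  memb <- lapply(sets, function(s) which(names(v) %in% unique(s)))
  sizes <- lengths(memb)
  drop <- sizes < min_size | sizes >= N
  if (any(drop)) {
    warning(sum(drop), " set(s) dropped (fewer than ", min_size,
            " members in the universe, or spanning it): ",
            paste(utils::head(names(sets)[drop], 5L), collapse = ", "),
            call. = FALSE)
  }
  memb <- memb[!drop]
  sizes <- sizes[!drop]
  empty <- data.frame(name = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0),
                      p_nominal = numeric(0), fwer_p = numeric(0))
  class(empty) <- c("gsea_result", "data.frame")
  if (!length(memb)) return(empty)
  local_seed(rng_seed)
  w <- abs(v)^p_weight
  obs <- vapply(memb, function(ix) .es_from_ranks(sort.int(ix), w, N),
                numeric(1))
  n_sets <- length(memb)
  nullm <- matrix(0, n_perm, n_sets)
  for (j in seq_len(n_sets)) {
    n <- sizes[j]
    for (i in seq_len(n_perm)) {
      nullm[i, j] <- .es_from_ranks(sort.int(sample.int(N, n)), w, N)
    }
  }
  nes <- numeric(n_sets)
  p_nominal <- numeric(n_sets)
  null_nes <- matrix(NA_real_, n_perm, n_sets)
  for (j in seq_len(n_sets)) {
    x <- nullm[, j]
    pos <- x > 0
    neg <- x < 0
    mpos <- if (any(pos)) mean(x[pos]) else NA_real_
    mneg <- if (any(neg)) mean(abs(x[neg])) else NA_real_
    null_nes[pos, j] <- x[pos] / mpos
    null_nes[neg, j] <- x[neg] / mneg
    null_nes[!pos & !neg, j] <- 0
    if (obs[j] > 0) {
      nes[j] <- if (is.na(mpos)) NA_real_ else obs[j] / mpos
      p_nominal[j] <- (1 + sum(x >= obs[j])) / (1 + sum(pos))
    } else if (obs[j] < 0) {
      nes[j] <- if (is.na(mneg)) NA_real_ else obs[j] / mneg
      p_nominal[j] <- (1 + sum(x <= obs[j])) / (1 + sum(neg))
    } else {
      nes[j] <- 0
      p_nominal[j] <- 1
    }
  }
  # family-wide correction from the per-permutation extremes over all sets
  pos_nes <- null_nes
  pos_nes[is.na(pos_nes) | pos_nes <= 0] <- -Inf
  max_pos <- apply(pos_nes, 1L, max)
  neg_nes <- null_nes
  neg_nes[is.na(neg_nes) | neg_nes >= 0] <- Inf
  min_neg <- apply(neg_nes, 1L, min)
  # add-one convention, as for the nominal p: the observed ranking counts
  # as one more "permutation", making the rank test exact at its level
  fwer_p <- vapply(seq_len(n_sets), function(j) {
    if (is.na(nes[j])) return(NA_real_)
    if (nes[j] > 0) (1 + sum(max_pos >= nes[j])) / (1 + n_perm)
    else if (nes[j] < 0) (1 + sum(min_neg <= nes[j])) / (1 + n_perm)
    else 1
  }, numeric(1))
  out <- data.frame(name = names(memb), size = as.integer(sizes), es = obs,
                    nes = nes, p_nominal = p_nominal, fwer_p = fwer_p,
                    row.names = NULL)
  out <- out[order(-out$nes, out$name, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' Select enriched sets at an FWER threshold
#'
#' Keeps the sets enriched towards the *top* of the ranked list
#' (`nes > 0`) whose family-wide corrected p-value does not exceed the
#' threshold, sorted by decreasing NES.
#'
#' @param results A data frame with at least `nes` and `fwer_p` columns
#'   ([gsea_preranked()] output, or a table of published results).
#' @param fwer_threshold FWER cut-off (default 0.05).
#' @return The filtered, NES-sorted rows.
#' @export
select_enriched <- function(results, fwer_threshold = 0.05) {
  if (!all(c("nes", "fwer_p") %in% names(results))) {
    stop("results need 'nes' and 'fwer_p' columns", call. = FALSE)
  }
  keep <- !is.na(results$nes) & !is.na(results$fwer_p) &
    results$nes > 0 & results$fwer_p <= fwer_threshold
  out <- results[keep, , drop = FALSE]
  out <- out[order(-out$nes), , drop = FALSE]
  rownames(out) <- NULL
  out
}
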