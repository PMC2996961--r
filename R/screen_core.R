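#' Per-well survival ratios from pre/post fluorescence
#'
#' Survival is the post-treatment fluorescence divided by the pre-treatment
#' fluorescence of the same well. Wells lacking one of the two readings, or
#' with a pre-treatment reading of zero, are flagged invalid with a reason
#' rather than silently becoming `NaN`.
#'
#' @param measurements Measurement table (see [read_measurements()]).
#' @return A data frame with one row per (plate, well, replicate):
#'   `plate`, `well`, `replicate`, `role`, `sirna_id`, `pre`, `post`,
#'   `survival` (`NA` when invalid), `valid`, `reason`.
#' @export
compute_survival <- function(measurements) {
  m <- validate_measurements(measurements)
  key <- paste(m$plate, m$well, m$replicate, m$phase, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate (plate, well, replicate, phase) measurement: plate ",
         m$plate[dup][1L], " well ", m$well[dup][1L], " replicate ",
         m$replicate[dup][1L], " phase ", m$phase[dup][1L], call. = FALSE)
  }
  wkey <- paste(m$plate, m$well, m$replicate, sep = "\r")
  info <- m[!duplicated(wkey), c("plate", "well", "replicate", "role", "sirna_id")]
  ikey <- wkey[!duplicated(wkey)]
  # role/sirna_id must agree between the pre and post rows of a well
  id0 <- ifelse(is.na(m$sirna_id), "", m$sirna_id)
  cons <- tapply(paste(m$role, id0, sep = "\r"), wkey,
                 function(v) length(unique(v)) == 1L)
  if (!all(cons)) {
    stop("role/sirna_id differ between phases for well key: ",
         gsub("\r", "/", names(cons)[!cons][1L]), call. = FALSE)
  }
  pre <- m$fluorescence[m$phase == "pre"][match(ikey, wkey[m$phase == "pre"])]
  post <- m$fluorescence[m$phase == "post"][match(ikey, wkey[m$phase == "post"])]
  out <- info
  out$pre <- pre
  out$post <- post
  out$survival <- NA_real_
  out$valid <- FALSE
  out$reason <- NA_character_
  no_pre <- is.na(out$pre)
  no_post <- is.na(out$post)
  zero <- !no_pre & out$pre == 0
  ok <- !no_pre & !no_post & out$pre > 0
  out$survival[ok] <- out$post[ok] / out$pre[ok]
  out$valid[ok] <- TRUE
  out$reason[no_post] <- "missing post-treatment reading"
  out$reason[no_pre] <- "missing pre-treatment reading"
  out$reason[zero] <- "pre-treatment fluorescence is zero"
  if (any(!out$valid)) {
    message(sum(!out$valid), " well(s) flagged invalid (",
            paste(unique(out$reason[!out$valid]), collapse = "; "), ")")
  }
  rownames(out) <- NULL
  out
}

#' Remove the least viable sample wells
#'
#' Drops, per replicate, the `floor(fraction * n)` sample wells with the
#' lowest pre-treatment fluorescence across the whole screen (not per
#' plate), so that wells with too few cells before treatment do not
#' contribute unstable survival ratios. The cut is rank-based and
#' deterministic: ties on pre-treatment fluorescence are broken by plate
#' then well identifier. Control wells are never removed. Sample wells with
#' no pre-treatment reading cannot be ranked and are excluded from the
#' pool (they are already invalid).
#'
#' @param survival Survival table from [compute_survival()].
#' @param fraction Fraction of sample wells to remove per replicate,
#'   in `[0, 1)`. Default 0.2.
#' @return The survival table with the removed sample wells dropped; the
#'   removed rows are attached as `attr(, "removed")`.
#' @export
filter_low_viability <- function(survival, fraction = 0.2) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction >= 1) {
    stop("fraction must be a single number in [0, 1)", call. = FALSE)
  }
  keep <- rep(TRUE, nrow(survival))
  for (r in unique(survival$replicate)) {
    idx <- which(survival$replicate == r & survival$role == "sample" &
                 !is.na(survival$pre))
    n_remove <- floor(fraction * length(idx))
    if (n_remove > 0L) {
      o <- idx[order(survival$pre[idx], survival$plate[idx],
                     survival$well[idx])]
      keep[o[seq_len(n_remove)]] <- FALSE
    }
  }
  out <- survival[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- survival[!keep, , drop = FALSE]
  out
}

#' Robust z scores for one replicate
#'
#' Log-transforms the survival ratio, centres each plate at its median
#' (computed over sample wells), and converts to a robust z score
#' \deqn{z = (x - \mathrm{median}(x)) / (1.4826 \cdot \mathrm{MAD}(x))}
#' where the median and MAD are taken over all surviving sample wells of
#' the replicate (or per plate with `scale_within = "plate"`). Control
#' wells receive z scores computed with the sample-derived location and
#' scale but never contribute to them. Higher z means more resistant to
#' treatment. If the MAD is zero the z scores of the affected wells are
#' set to missing with a warning (never infinite).
#'
#' @param survival (Filtered) survival table, see [filter_low_viability()].
#' @param replicate Which replicate to score.
#' @param scale_within `"replicate"` (default) estimates median/MAD once
#'   per replicate; `"plate"` estimates them per plate.
#' @return The wells of the replicate with `log_survival`, `normalized`
#'   and `z` columns added.
#' @export
score_replicate <- function(survival, replicate,
                            scale_within = c("replicate", "plate")) {
  scale_within <- match.arg(scale_within)
  d <- survival[survival$replicate == replicate & survival$valid, , drop = FALSE]
  if (!nrow(d)) stop("no valid wells for replicate ", replicate, call. = FALSE)
  samp <- d$role == "sample"
  plate_n <- table(d$plate[samp])
  if (!length(plate_n) || any(plate_n < 3L)) {
    stop("each plate needs at least 3 surviving sample wells in replicate ",
         replicate, call. = FALSE)
  }
  d$log_survival <- log(d$survival)
  pm <- tapply(d$log_survival[samp], d$plate[samp], stats::median)
  d$normalized <- d$log_survival - unname(pm[d$plate])
  d$z <- NA_real_
  if (scale_within == "replicate") {
    ctr <- stats::median(d$normalized[samp])
    sc <- stats::mad(d$normalized[samp])       # 1.4826 * raw MAD
    if (sc == 0) {
      warning("median absolute deviation is zero for replicate ", replicate,
              "; z scores set to missing", call. = FALSE)
    } else {
      d$z <- (d$normalized - ctr) / sc
    }
  } else {
    for (p in names(pm)) {
      on_plate <- d$plate == p
      ctr <- stats::median(d$normalized[on_plate & samp])
      sc <- stats::mad(d$normalized[on_plate & samp])
      if (sc == 0) {
        warning("median absolute deviation is zero on plate ", p,
                " (replicate ", replicate, "); z scores set to missing",
                call. = FALSE)
      } else {
        d$z[on_plate] <- (d$normalized[on_plate] - ctr) / sc
      }
    }
  }
  rownames(d) <- NULL
  d
}

#' Summarise replicate z scores into per-siRNA screen scores
#'
#' The screen score of an siRNA is the minimum of its replicate z scores:
#' a conservative summary that requires both replicates to support
#' resistance. If any replicate z is missing (filtered well, invalid well,
#' or a zero-MAD replicate) the siRNA's score is missing and it is
#' excluded from ranking. Ranking is descending by score, rank 1 being the
#' most resistant siRNA; ties are broken by `sirna_id`.
#'
#' @param scored Row-bound output of [score_replicate()] across
#'   replicates (sample wells are selected internally).
#' @return A data frame with one row per siRNA: `sirna_id`, one `z_rep<k>`
#'   column per replicate, `score` and `rank` (`NA` when the score is
#'   missing), ordered by rank.
#' @export
summarize_min_replicate <- function(scored) {
  s <- scored[scored$role == "sample" & !is.na(scored$sirna_id), , drop = FALSE]
  reps <- sort(unique(scored$replicate))
  if (!nrow(s)) {
    out <- data.frame(sirna_id = character(0))
    for (r in reps) out[[paste0("z_rep", r)]] <- numeric(0)
    out$score <- numeric(0)
    out$rank <- integer(0)
    return(out)
  }
  ids <- sort(unique(s$sirna_id))
  zmat <- matrix(NA_real_, length(ids), length(reps),
                 dimnames = list(ids, paste0("z_rep", reps)))
  zmat[cbind(match(s$sirna_id, ids), match(s$replicate, reps))] <- s$z
  score <- zmat[, 1L]
  if (ncol(zmat) > 1L) {
    for (j in 2:ncol(zmat)) score <- pmin(score, zmat[, j])  # NA propagates
  }
  out <- data.frame(sirna_id = ids, zmat, score = unname(score),
                    row.names = NULL, check.names = FALSE)
  ok <- !is.na(out$score)
  out$rank <- NA_integer_
  ord <- order(-out$score[ok], out$sirna_id[ok])
  out$rank[which(ok)[ord]] <- seq_len(sum(ok))
  if (any(!ok)) {
    message(sum(!ok), " siRNA(s) excluded from ranking (missing replicate z)")
  }
  out <- out[order(out$rank, out$sirna_id, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Z' (Z-prime) factor of control separation
#'
#' \deqn{Z' = 1 - 3 (\sigma_{pos} + \sigma_{neg}) / |\mu_{pos} - \mu_{neg}|}
#' A scale-free quality measure of an assay: values above zero indicate
#' essentially non-overlapping control distributions, 1 is perfect
#' separation.
#'
#' @param pos,neg Numeric measurements for the positive and negative
#'   controls (each at least two values).
#' @return The Z' factor.
#' @export
zprime <- function(pos, neg) {
  pos <- as.numeric(pos)
  neg <- as.numeric(neg)
  if (length(pos) < 2L || length(neg) < 2L) {
    stop("each control group needs at least two values", call. = FALSE)
  }
  mp <- mean(pos)
  mn <- mean(neg)
  if (mp == mn) stop("control means are equal; Z' is undefined", call. = FALSE)
  1 - 3 * (stats::sd(pos) + stats::sd(neg)) / abs(mp - mn)
}

#' Score a whole screen
#'
#' Convenience chain: survival ratios, viability filter, per-replicate
#' robust z, min-over-replicates summary, gene annotation.
#'
#' @param library siRNA library (validated data frame or path).
#' @param measurements Measurement table (data frame or path).
#' @param viability_fraction Fraction of sample wells removed per replicate
#'   by the viability filter (default 0.2).
#' @param scale_within Passed to [score_replicate()].
#' @return Per-siRNA score table (`sirna_id`, `gene_id`, `z_rep*`, `score`,
#'   `rank`). The per-well scored rows are attached as `attr(, "wells")`
#'   (used e.g. for control-based quality metrics).
#' @export
score_screen <- function(library, measurements, viability_fraction = 0.2,
                         scale_within = c("replicate", "plate")) {
  scale_within <- match.arg(scale_within)
  if (is.character(library)) library <- read_sirna_library(library)
  library <- validate_library(library)
  if (is.character(measurements)) {
    measurements <- read_measurements(measurements, library)
  } else {
    measurements <- validate_measurements(measurements, library)
  }
  surv <- compute_survival(measurements)
  filt <- filter_low_viability(surv, viability_fraction)
  reps <- sort(unique(filt$replicate[filt$valid]))
  scored <- do.call(rbind, lapply(reps, function(r) {
    score_replicate(filt, r, scale_within)
  }))
  tab <- summarize_min_replicate(scored)
  # every library siRNA appears in the output; those without a complete set
  # of replicate scores carry NA score and rank
  absent <- setdiff(library$sirna_id, tab$sirna_id)
  if (length(absent)) {
    extra <- tab[rep(NA_integer_, length(absent)), , drop = FALSE]
    extra$sirna_id <- absent
    tab <- rbind(tab, extra)
  }
  tab <- data.frame(sirna_id = tab$sirna_id,
                    gene_id = library$gene_id[match(tab$sirna_id, library$sirna_id)],
                    tab[, setdiff(names(tab), "sirna_id"), drop = FALSE],
                    check.names = FALSE)
  tab <- tab[order(tab$rank, tab$sirna_id, na.last = TRUE), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "wells") <- scored
  tab
}
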