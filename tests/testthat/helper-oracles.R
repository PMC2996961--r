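# Independent oracles and fixture builders used across the test files.

# Brute-force running-sum enrichment score: plain loop, no shortcuts.
# `scores` must already be in rank order (descending); `member_pos` are
# positions of the set members in that order.
es_brute <- function(scores, member_pos, p_weight = 1) {
  N <- length(scores)
  n <- length(member_pos)
  denom <- 0
  for (i in member_pos) denom <- denom + abs(scores[i])^p_weight
  run <- 0
  mx <- 0
  mn <- 0
  for (i in seq_len(N)) {
    if (i %in% member_pos) {
      run <- run + (if (denom > 0) abs(scores[i])^p_weight / denom else 1 / n)
    } else {
      run <- run - 1 / (N - n)
    }
    if (run > mx) mx <- run
    if (run < mn) mn <- run
  }
  # same sign convention as the implementation under test: a tie in
  # magnitude reports the positive extreme
  if (mx >= -mn - 1e-12) mx else mn
}

# Direct, unvectorised re-implementation of the scoring pipeline for tiny
# screens: survival ratio, bottom-fraction viability cut on pre-treatment
# fluorescence, log, plate-median centring, median/MAD z over the
# replicate's sample wells, min over replicates.
naive_screen_scores <- function(library, measurements, fraction = 0.2) {
  reps <- sort(unique(measurements$replicate))
  z_by_rep <- list()
  for (r in reps) {
    m <- measurements[measurements$replicate == r, ]
    wells <- unique(m[m$role != "empty", c("plate", "well", "role", "sirna_id")])
    pre <- post <- numeric(nrow(wells))
    for (i in seq_len(nrow(wells))) {
      sel <- m$plate == wells$plate[i] & m$well == wells$well[i]
      pre[i] <- m$fluorescence[sel & m$phase == "pre"]
      post[i] <- m$fluorescence[sel & m$phase == "post"]
    }
    surv <- post / pre
    is_samp <- wells$role == "sample"
    n_remove <- floor(fraction * sum(is_samp))
    ord <- order(pre[is_samp], wells$plate[is_samp], wells$well[is_samp])
    drop_idx <- which(is_samp)[ord][seq_len(n_remove)]
    keep <- setdiff(which(is_samp), drop_idx)
    x <- log(surv[keep])
    for (p in unique(wells$plate[keep])) {
      on_p <- wells$plate[keep] == p
      x[on_p] <- x[on_p] - median(x[on_p])
    }
    z <- (x - median(x)) / (1.4826 * median(abs(x - median(x))))
    z_by_rep[[as.character(r)]] <- setNames(z, wells$sirna_id[keep])
  }
  ids <- sort(unique(library$sirna_id))
  out <- setNames(rep(NA_real_, length(ids)), ids)
  for (id in ids) {
    zs <- vapply(z_by_rep, function(v) {
      if (id %in% names(v)) unname(v[id]) else NA_real_
    }, numeric(1))
    if (!anyNA(zs)) out[id] <- min(zs)
  }
  out
}

# A small deterministic two-plate screen: `n` sample wells per plate,
# `n_reps` replicates, with controls on each plate.
make_toy_screen <- function(n = 10L, n_plates = 2L, n_reps = 2L, seed = 1L) {
  withr::local_seed(seed)
  ids <- sprintf("si%03d", seq_len(n * n_plates))
  library <- data.frame(
    sirna_id = ids,
    gene_id = sprintf("gene%03d", ceiling(seq_along(ids) / 2)),
    guide_seq = vapply(seq_along(ids), function(i) {
      paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = "")
    }, ""))
  rows <- list()
  for (r in seq_len(n_reps)) {
    for (p in seq_len(n_plates)) {
      wells <- sprintf("A%02d", seq_len(n + 2L))
      roles <- c(rep("sample", n), "pos_ctrl", "neg_ctrl")
      sirna <- c(ids[(p - 1L) * n + seq_len(n)], NA, NA)
      pre <- round(runif(n + 2L, 5000, 20000), 1)
      post <- round(pre * exp(rnorm(n + 2L, c(rep(-0.5, n), 1.5, -0.5), 0.5)), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        plate = paste0("P", p), well = rep(wells, 2L),
        replicate = r, phase = rep(c("pre", "post"), each = n + 2L),
        fluorescence = c(pre, post), role = rep(roles, 2L),
        sirna_id = rep(sirna, 2L))
    }
  }
  list(library = library, measurements = do.call(rbind, rows))
}

# Minimal valid survival table for direct score_replicate tests.
make_survival <- function(log_survival, plate = "P1", replicate = 1L,
                          role = "sample") {
  n <- length(log_survival)
  data.frame(plate = plate, well = sprintf("W%02d", seq_len(n)),
             replicate = replicate, role = role,
             sirna_id = sprintf("si%02d", seq_len(n)),
             pre = 1000, post = 1000 * exp(log_survival),
             survival = exp(log_survival), valid = TRUE,
             reason = NA_character_)
}
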