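#' Configuration for a synthetic arrayed screen
#'
#' Describes a simulated duplicate arrayed siRNA screen: a library of
#' random 21-nt guides (about two siRNAs per gene), 96-well plates with a
#' fixed complement of control wells, lognormal pre-treatment
#' fluorescence, and log-survival that decomposes additively into a
#' baseline, a per-gene effect, a planted per-seed effect and Gaussian
#' noise. Effects are expressed in z-units of the sample noise, matching
#' the scale on which the pipeline scores siRNAs.
#'
#' @param n_genes Number of genes (default 500).
#' @param sirnas_per_gene siRNAs per gene (default 2).
#' @param guide_length Guide length in nt (default 21).
#' @param planted_seed_effects Named numeric vector: hexamer -> effect
#'   delta added to the log-survival of every carrier siRNA.
#' @param seed_carriers Number of siRNAs forced to carry each planted
#'   seed at positions 2-7 (scalar, recycled, or named like
#'   `planted_seed_effects`; default 30).
#' @param seed_exclude_genes Genes whose siRNAs are never used as forced
#'   carriers (models off-target seeds landing on unrelated genes).
#' @param planted_gene_effects Named numeric vector: gene_id -> effect
#'   delta added to all siRNAs targeting that gene.
#' @param noise_sd Per-well Gaussian noise SD on log-survival for sample
#'   wells (default 1).
#' @param n_replicates Number of replicates (default 2).
#' @param plate_size Wells per plate (default 96).
#' @param n_pos_wells,n_transfection_wells,n_neg_wells Control wells per
#'   plate (defaults 2, 1, 4).
#' @param pos_effect,neg_effect,transfection_effect Latent log-survival
#'   effects of the controls (defaults +3, 0, -1.5: positive controls
#'   strongly protective, the transfection control lethal on its own).
#' @param control_noise_sd Noise SD for control wells (default 0.25;
#'   reagent controls are more consistent than arbitrary library siRNAs).
#' @param baseline_log_survival Baseline log survival under treatment
#'   (default `log(0.4)`).
#' @param pre_meanlog,pre_sdlog Lognormal parameters of the pre-treatment
#'   fluorescence (defaults `log(3e4)`, 0.3).
#' @param rng_seed Default RNG seed used by the simulation functions.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500L, sirnas_per_gene = 2L,
                       guide_length = 21L,
                       planted_seed_effects = numeric(0),
                       seed_carriers = 30L,
                       seed_exclude_genes = character(0),
                       planted_gene_effects = numeric(0),
                       noise_sd = 1, n_replicates = 2L, plate_size = 96L,
                       n_pos_wells = 2L, n_transfection_wells = 1L,
                       n_neg_wells = 4L, pos_effect = 3, neg_effect = 0,
                       transfection_effect = -1.5, control_noise_sd = 0.25,
                       baseline_log_survival = log(0.4),
                       pre_meanlog = log(3e4), pre_sdlog = 0.3,
                       rng_seed = NULL) {
  cfg <- list(n_genes = as.integer(n_genes),
              sirnas_per_gene = as.integer(sirnas_per_gene),
              guide_length = as.integer(guide_length),
              planted_seed_effects = planted_seed_effects,
              seed_carriers = seed_carriers,
              seed_exclude_genes = as.character(seed_exclude_genes),
              planted_gene_effects = planted_gene_effects,
              noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
              plate_size = as.integer(plate_size),
              n_pos_wells = as.integer(n_pos_wells),
              n_transfection_wells = as.integer(n_transfection_wells),
              n_neg_wells = as.integer(n_neg_wells),
              pos_effect = pos_effect, neg_effect = neg_effect,
              transfection_effect = transfection_effect,
              control_noise_sd = control_noise_sd,
              baseline_log_survival = baseline_log_survival,
              pre_meanlog = pre_meanlog, pre_sdlog = pre_sdlog,
              rng_seed = rng_seed)
  stopifnot(cfg$n_genes >= 1L, cfg$sirnas_per_gene >= 1L,
            cfg$guide_length >= 8L, cfg$n_replicates >= 1L,
            cfg$noise_sd >= 0, cfg$control_noise_sd >= 0,
            cfg$plate_size >= cfg$n_pos_wells + cfg$n_transfection_wells +
              cfg$n_neg_wells + 1L)
  if (length(cfg$planted_seed_effects)) {
    seeds <- names(cfg$planted_seed_effects)
    if (is.null(seeds) || any(seeds == "")) {
      stop("planted_seed_effects must be named by hexamer", call. = FALSE)
    }
    seeds <- norm_dna(seeds, what = "planted seed")
    if (any(nchar(seeds) != 6L)) {
      stop("planted seeds must be hexamers", call. = FALSE)
    }
    names(cfg$planted_seed_effects) <- seeds
    if (!all(is.finite(cfg$planted_seed_effects))) {
      stop("planted seed effects must be finite", call. = FALSE)
    }
    carriers <- cfg$seed_carriers
    if (is.null(names(carriers))) {
      carriers <- stats::setNames(rep_len(as.integer(carriers), length(seeds)),
                                  seeds)
    } else {
      if (!all(seeds %in% names(carriers))) {
        stop("seed_carriers must cover every planted seed", call. = FALSE)
      }
      carriers <- stats::setNames(as.integer(carriers[seeds]), seeds)
    }
    if (any(carriers < 0L)) stop("seed_carriers must be >= 0", call. = FALSE)
    cfg$seed_carriers <- carriers
  }
  if (length(cfg$planted_gene_effects) &&
      (is.null(names(cfg$planted_gene_effects)) ||
       !all(is.finite(cfg$planted_gene_effects)))) {
    stop("planted_gene_effects must be a finite named vector", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate an siRNA library with planted seeds
#'
#' Generates random guides uniform over the DNA alphabet, forces the
#' configured number of carriers for each planted seed (writing the
#' hexamer at positions 2-7 of randomly chosen guides), and returns a
#' ground-truth table listing each siRNA's gene effect, seed effect and
#' total latent effect. Seed effects apply to every actual carrier, so
#' chance carriers (guides that received a planted hexamer by random
#' draw) are included in the truth and distinguishable via the
#' `forced_seed` column.
#'
#' @param config A [sim_config()].
#' @param rng_seed RNG seed (defaults to `config$rng_seed`).
#' @return A list: `library` (siRNA library data frame) and `truth`
#'   (`sirna_id`, `gene_id`, `forced_seed`, `hexamer`, `gene_effect`,
#'   `seed_effect`, `latent`).
#' @export
simulate_library <- function(config = sim_config(), rng_seed = config$rng_seed) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(rng_seed)
  n <- config$n_genes * config$sirnas_per_gene
  gene_id <- rep(sprintf("g%05d", seq_len(config$n_genes)),
                 each = config$sirnas_per_gene)
  sirna_id <- paste0(gene_id, "_si",
                     rep(seq_len(config$sirnas_per_gene), config$n_genes))
  L <- config$guide_length
  mat <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  guide <- do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
  forced <- rep(NA_character_, n)
  if (length(config$planted_seed_effects)) {
    carriers <- config$seed_carriers
    eligible <- which(!(gene_id %in% config$seed_exclude_genes))
    if (sum(carriers) > length(eligible)) {
      stop("requested planted carriers exceed the available library size",
           call. = FALSE)
    }
    pick <- sample(eligible, sum(carriers))
    at <- split(pick, rep(names(carriers), carriers))
    for (seed in names(at)) {
      idx <- at[[seed]]
      substr(guide[idx], 2L, 7L) <- seed
      forced[idx] <- seed
    }
  }
  hexamer <- substr(guide, 2L, 7L)
  seed_effect <- unname(config$planted_seed_effects[hexamer])
  seed_effect[is.na(seed_effect)] <- 0
  gene_effect <- unname(config$planted_gene_effects[gene_id])
  gene_effect[is.na(gene_effect)] <- 0
  if (length(config$planted_gene_effects)) {
    unknown <- setdiff(names(config$planted_gene_effects), gene_id)
    if (length(unknown)) {
      warning("planted gene effect(s) for genes not in the library: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  list(library = data.frame(sirna_id = sirna_id, gene_id = gene_id,
                            guide_seq = guide, row.names = NULL),
       truth = data.frame(sirna_id = sirna_id, gene_id = gene_id,
                          forced_seed = forced, hexamer = hexamer,
                          gene_effect = gene_effect,
                          seed_effect = seed_effect,
                          latent = gene_effect + seed_effect,
                          row.names = NULL))
}

.well_labels <- function(plate_size) {
  n_rows <- ceiling(plate_size / 12L)
  sprintf("%s%02d", rep(LETTERS[seq_len(n_rows)], each = 12L),
          rep(1:12, n_rows))[seq_len(plate_size)]
}

#' Simulate plate measurements for a library
#'
#' Fills 96-well plates in library order, appends the control wells to
#' the end of every plate, draws lognormal pre-treatment fluorescence per
#' well and replicate, and sets the post-treatment fluorescence to
#' `pre * exp(baseline + latent + noise)`, i.e. effects are additive on
#' log survival.
#'
#' @param library,truth Output of [simulate_library()].
#' @param config The same [sim_config()].
#' @param rng_seed RNG seed (`NULL` continues the current stream).
#' @return A measurement table in the schema read by
#'   [read_measurements()].
#' @export
simulate_measurements <- function(library, truth, config = sim_config(),
                                  rng_seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(rng_seed)
  n_ctrl <- config$n_pos_wells + config$n_transfection_wells + config$n_neg_wells
  spp <- config$plate_size - n_ctrl
  n <- nrow(library)
  n_plates <- ceiling(n / spp)
  wells <- .well_labels(config$plate_size)
  samp_plate <- (seq_len(n) - 1L) %/% spp + 1L
  samp_pos <- (seq_len(n) - 1L) %% spp + 1L
  ctrl_roles <- c(rep("pos_ctrl", config$n_pos_wells),
                  rep("transfection_ctrl", config$n_transfection_wells),
                  rep("neg_ctrl", config$n_neg_wells))
  ctrl_effect <- c(rep(config$pos_effect, config$n_pos_wells),
                   rep(config$transfection_effect, config$n_transfection_wells),
                   rep(config$neg_effect, config$n_neg_wells))
  layout <- rbind(
    data.frame(plate = sprintf("P%03d", samp_plate),
               well = wells[samp_pos], role = "sample",
               sirna_id = library$sirna_id,
               latent = truth$latent[match(library$sirna_id, truth$sirna_id)],
               noise_sd = config$noise_sd),
    data.frame(plate = rep(sprintf("P%03d", seq_len(n_plates)), each = n_ctrl),
               well = rep(wells[(spp + 1L):config$plate_size], n_plates),
               role = rep(ctrl_roles, n_plates),
               sirna_id = NA_character_,
               latent = rep(ctrl_effect, n_plates),
               noise_sd = config$control_noise_sd)
  )
  n_wells <- nrow(layout)
  out <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    pre <- stats::rlnorm(n_wells, config$pre_meanlog, config$pre_sdlog)
    eps <- stats::rnorm(n_wells, 0, layout$noise_sd)
    log_surv <- config$baseline_log_survival + layout$latent + eps
    post <- pre * exp(log_surv)
    out[[r]] <- data.frame(
      plate = rep(layout$plate, 2L), well = rep(layout$well, 2L),
      replicate = r, phase = rep(c("pre", "post"), each = n_wells),
      fluorescence = c(pre, post), role = rep(layout$role, 2L),
      sirna_id = rep(layout$sirna_id, 2L), row.names = NULL)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate a full screen
#'
#' @param config A [sim_config()].
#' @param rng_seed RNG seed (defaults to `config$rng_seed`); the library
#'   and the measurements are drawn from one seeded stream, so a fixed
#'   seed reproduces the whole screen byte for byte.
#' @return A list: `library`, `truth`, `measurements`, `config`.
#' @export
simulate_screen <- function(config = sim_config(), rng_seed = config$rng_seed) {
  local_seed(rng_seed)
  sim <- simulate_library(config, rng_seed = NULL)
  meas <- simulate_measurements(sim$library, sim$truth, config, rng_seed = NULL)
  list(library = sim$library, truth = sim$truth, measurements = meas,
       config = config)
}
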