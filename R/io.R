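#' Read an siRNA library table
#'
#' The library lists one row per siRNA with its intended target gene and the
#' guide (antisense) strand sequence written 5'->3'. Sequences are
#' normalised to uppercase DNA (U is mapped to T) so RNA- and DNA-written
#' tables interoperate.
#'
#' @param path Path to a tab-separated file with columns `sirna_id`,
#'   `gene_id` and `guide_seq`.
#' @return A data frame with the three columns, validated: `sirna_id`
#'   unique, sequences uppercase DNA of length >= 8.
#' @export
read_sirna_library <- function(path) {
  if (!file.exists(path)) stop("library file not found: ", path, call. = FALSE)
  validate_library(utils::read.delim(path, stringsAsFactors = FALSE))
}

validate_library <- function(library) {
  need <- c("sirna_id", "gene_id", "guide_seq")
  miss <- setdiff(need, names(library))
  if (length(miss)) {
    stop("siRNA library is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  library$sirna_id <- as.character(library$sirna_id)
  library$gene_id <- as.character(library$gene_id)
  dup <- duplicated(library$sirna_id)
  if (any(dup)) {
    stop("duplicate sirna_id in library: ",
         paste(unique(library$sirna_id[dup]), collapse = ", "), call. = FALSE)
  }
  library$guide_seq <- norm_dna(library$guide_seq, ids = library$sirna_id,
                                what = "guide_seq")
  short <- nchar(library$guide_seq) < 8L
  if (any(short)) {
    stop("guide_seq shorter than 8 nt for: ",
         paste(library$sirna_id[short], collapse = ", "), call. = FALSE)
  }
  library
}

.measurement_roles <- c("sample", "pos_ctrl", "neg_ctrl",
                        "transfection_ctrl", "empty")

#' Read a plate measurement table
#'
#' One row per (plate, well, replicate, phase) fluorescence reading.
#' `phase` is `pre` (before treatment) or `post` (after treatment); `role`
#' is one of `sample`, `pos_ctrl`, `neg_ctrl`, `transfection_ctrl`,
#' `empty`. Sample wells must carry a `sirna_id`; control wells may leave
#' it empty.
#'
#' @param path Path to a TSV (or CSV, by file extension) file.
#' @param library Optional validated library; if supplied, every sample
#'   `sirna_id` must be present in it.
#' @return Validated measurement data frame.
#' @export
read_measurements <- function(path, library = NULL) {
  if (!file.exists(path)) stop("measurement file not found: ", path, call. = FALSE)
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) utils::read.csv
            else utils::read.delim
  validate_measurements(reader(path, stringsAsFactors = FALSE), library)
}

validate_measurements <- function(measurements, library = NULL) {
  need <- c("plate", "well", "replicate", "phase", "fluorescence", "role")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) {
    stop("measurement table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  m <- measurements
  if (!"sirna_id" %in% names(m)) m$sirna_id <- NA_character_
  m$plate <- as.character(m$plate)
  m$well <- as.character(m$well)
  m$replicate <- as.integer(m$replicate)
  m$sirna_id <- as.character(m$sirna_id)
  m$sirna_id[!is.na(m$sirna_id) & m$sirna_id == ""] <- NA_character_
  if (any(is.na(m$replicate) | m$replicate < 1L)) {
    stop("replicate must be an integer >= 1", call. = FALSE)
  }
  if (!all(m$phase %in% c("pre", "post"))) {
    stop("phase must be 'pre' or 'post'", call. = FALSE)
  }
  if (!all(m$role %in% .measurement_roles)) {
    stop("role must be one of: ", paste(.measurement_roles, collapse = ", "),
         call. = FALSE)
  }
  m$fluorescence <- as.numeric(m$fluorescence)
  if (any(!is.na(m$fluorescence) & m$fluorescence < 0)) {
    stop("fluorescence must be non-negative", call. = FALSE)
  }
  no_id <- m$role == "sample" & is.na(m$sirna_id)
  if (any(no_id)) {
    stop("sample wells without sirna_id: e.g. plate ",
         m$plate[no_id][1L], " well ", m$well[no_id][1L], call. = FALSE)
  }
  if (!is.null(library)) {
    unknown <- setdiff(m$sirna_id[m$role == "sample"], library$sirna_id)
    if (length(unknown)) {
      stop("sample sirna_id not present in the library: ",
           paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
    }
  }
  m
}

#' Write a score table to TSV
#'
#' @param scores A score table from [score_screen()] or
#'   [summarize_min_replicate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
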