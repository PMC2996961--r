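# internal helpers shared across modules

# Uppercase, map U->T, and validate a DNA/RNA string vector.
# `ids` are used to name offenders in error messages.
norm_dna <- function(x, ids = NULL, what = "sequence") {
  x <- chartr("u", "U", as.character(x))
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- is.na(x) | grepl("[^ACGT]", x)
  if (any(bad)) {
    lab <- if (!is.null(ids)) ids[bad] else x[bad]
    stop("illegal character in ", what, " for: ",
         paste(utils::head(lab, 5L), collapse = ", "),
         if (sum(bad) > 5L) sprintf(" (and %d more)", sum(bad) - 5L),
         call. = FALSE)
  }
  x
}

# Seed the RNG for the remainder of the calling function, restoring the
# previous state on exit. NULL means "use the current RNG stream".
local_seed <- function(rng_seed, envir = parent.frame()) {
  if (is.null(rng_seed)) return(invisible(NULL))
  stopifnot(is.numeric(rng_seed), length(rng_seed) == 1L, is.finite(rng_seed))
  withr::local_seed(as.integer(rng_seed), .local_envir = envir)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
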