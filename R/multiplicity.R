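#' Sampling null for top-k seed multiplicity
#'
#' Draws `k` siRNAs at random from the library (without replacement by
#' default, which preserves the library's seed composition), counts how
#' often each seed occurs among the draw, and records a repetition
#' statistic. Repeating this `n_iter` times yields the null distribution
#' against which the multiplicity observed among the actual top-k siRNAs
#' is compared.
#'
#' @param seeds Character vector with one seed per library siRNA.
#' @param k Sample size per iteration (default 20).
#' @param n_iter Number of iterations (default 5000).
#' @param statistic Which statistic to record: `n_repeated` (number of
#'   seeds occurring >= 2 times), `max_count` (largest multiplicity), or
#'   `n_with_count_ge_m` (number of seeds occurring >= `m` times).
#' @param m Threshold for `n_with_count_ge_m` (default 2).
#' @param replace Sample siRNAs with replacement instead (default FALSE).
#' @param rng_seed Optional integer seed; fixed seed gives bit-identical
#'   samples across runs.
#' @return Object of class `multiplicity_null` with the recorded `samples`.
#' @export
sample_null <- function(seeds, k = 20L, n_iter = 5000L,
                        statistic = c("n_repeated", "max_count",
                                      "n_with_count_ge_m"),
                        m = 2L, replace = FALSE, rng_seed = NULL) {
  statistic <- match.arg(statistic)
  seeds <- as.character(seeds)
  n <- length(seeds)
  if (!replace && k > n) stop("k exceeds the library size", call. = FALSE)
  if (n < 1L) stop("empty seed library", call. = FALSE)
  if (n_iter < 1L) stop("n_iter must be >= 1", call. = FALSE)
  local_seed(rng_seed)
  samples <- integer(n_iter)
  for (i in seq_len(n_iter)) {
    s <- seeds[sample.int(n, k, replace = replace)]
    cnt <- rle(sort(s))$lengths
    samples[i] <- switch(statistic,
                         n_repeated = sum(cnt >= 2L),
                         max_count = max(cnt),
                         n_with_count_ge_m = sum(cnt >= m))
  }
  structure(list(statistic = statistic, k = as.integer(k),
                 m = if (statistic == "n_with_count_ge_m") as.integer(m) else NA_integer_,
                 n_iter = as.integer(n_iter), replace = replace,
                 rng_seed = rng_seed, samples = samples),
            class = "multiplicity_null")
}

#' Empirical p-value against a sampling null
#'
#' Add-one permutation p-value
#' \deqn{p = (\#\{samples \ge observed\} + 1) / (n_{iter} + 1)}
#' which never reports exactly zero. When no sample reaches the observed
#' value the `label` states the resolution bound of the null (e.g.
#' `"P < 0.0002"` at 5000 iterations).
#'
#' @param null A `multiplicity_null` from [sample_null()].
#' @param observed Observed value of the statistic (non-negative integer).
#' @return A list: `p` (numeric), `n_ge`, `n_iter`, `label` (reporting
#'   string).
#' @export
empirical_p <- function(null, observed) {
  if (!inherits(null, "multiplicity_null")) {
    stop("null must come from sample_null()", call. = FALSE)
  }
  if (!length(null$samples)) stop("empty null distribution", call. = FALSE)
  if (!is.numeric(observed) || length(observed) != 1L || observed < 0) {
    stop("observed must be a single non-negative number", call. = FALSE)
  }
  n_ge <- sum(null$samples >= observed)
  p <- (n_ge + 1) / (null$n_iter + 1)
  label <- if (n_ge == 0L) {
    sprintf("P < %s", format(1 / null$n_iter, scientific = FALSE, trim = TRUE))
  } else {
    sprintf("P = %.4g", p)
  }
  list(p = p, n_ge = n_ge, n_iter = null$n_iter, label = label)
}
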