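#' Percentile bootstrap confidence intervals for state expectancies
#'
#' Nonparametric bootstrap of the entire estimation pipeline: persons are
#' resampled with replacement at the person level, each drawn person
#' contributing their complete trajectory (which preserves the longitudinal
#' structure of the data), and the full pipeline — records, model fit, group
#' profiles, prediction, optional mortality matching, expectancies — is
#' re-run on every resample. Intervals are empirical percentiles (default
#' 2.5th and 97.5th); the point estimate is the full-sample run, not the
#' bootstrap mean. Replicates in which a stratum or origin state is empty are
#' dropped and counted; more than 5% dropped is an error. Results are
#' deterministic given the seed and invariant to replicate execution order
#' (the resample index matrix is drawn up front).
#'
#' @inheritParams pipeline_expectancies
#' @param B Number of bootstrap replications (default 1000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @param verbose Print progress every 50 replicates.
#' @return Tibble with one row per group cell and, for each expectancy
#'   (`employment`, `joblessness`, `retirement`, `total`), the point estimate
#'   plus `_lower` / `_upper` percentile bounds. Attributes: `B_used`,
#'   `n_dropped`.
#' @export
bootstrap_expectancies <- function(panel, spec = model_spec(), step = 1,
                                   groups = c("gender", "parity"),
                                   lifetable = NULL, B = 1000, seed = 1,
                                   level = 0.95, verbose = FALSE,
                                   min_age = -Inf, max_age = Inf) {
  if (B < 2) stop("B must be at least 2", call. = FALSE)
  panel <- restrict_panel(panel, min_age, max_age)
  prep <- prepare_pipeline(panel, spec, step, groups, lifetable)
  point <- engine_run(prep)

  n <- length(prep$persons)
  set.seed(seed)
  draws <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)

  qty <- c("employment", "joblessness", "retirement", "total")
  ncell <- nrow(point)
  reps <- array(NA_real_, dim = c(B, ncell, length(qty)))
  dropped <- 0L
  for (b in seq_len(B)) {
    res <- tryCatch(engine_run(prep, draw = draws[b, ]), error = function(e) NULL)
    if (is.null(res) || nrow(res) != ncell) {
      dropped <- dropped + 1L
    } else {
      reps[b, , ] <- as.matrix(res[qty])
    }
    if (verbose && b %% 50 == 0) {
      message(sprintf("bootstrap replicate %d/%d (%d dropped)", b, B, dropped))
    }
  }
  if (dropped > 0.05 * B) {
    stop(sprintf("bootstrap failed: %d of %d replicates dropped (> 5%%)",
                 dropped, B), call. = FALSE)
  }
  alpha <- (1 - level) / 2
  out <- point
  for (k in seq_along(qty)) {
    lo <- apply(reps[, , k, drop = FALSE], 2, stats::quantile,
                probs = alpha, na.rm = TRUE)
    hi <- apply(reps[, , k, drop = FALSE], 2, stats::quantile,
                probs = 1 - alpha, na.rm = TRUE)
    out[[paste0(qty[k], "_lower")]] <- as.numeric(lo)
    out[[paste0(qty[k], "_upper")]] <- as.numeric(hi)
  }
  attr(out, "B_used") <- B - dropped
  attr(out, "n_dropped") <- dropped
  out
}
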