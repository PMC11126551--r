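#' Labor-force state space
#'
#' The analysis uses four mutually exclusive states: three transient
#' labor-force states (`employed`, `jobless`, `retired`) and one absorbing
#' state (`dead`). `wl_states()` returns all four in canonical order;
#' `wl_transient_states()` returns the three transient ones.
#'
#' @return Character vector of state labels.
#' @export
wl_states <- function() c("employed", "jobless", "retired", "dead")

#' @rdname wl_states
#' @export
wl_transient_states <- function() c("employed", "jobless", "retired")

# canonical covariate codings (reference level first)
wl_education_levels <- function() c("low", "medium", "high")
wl_parity_levels <- function() c("0", "1", "2", "3+")
wl_marital_levels <- function() c("married", "single", "divorced", "widowed")
wl_gender_levels <- function() c("woman", "man")

# validate that `x` takes values only in `levels`; returns x as character
check_levels <- function(x, levels, what) {
  x <- as.character(x)
  bad <- setdiff(unique(x), levels)
  if (length(bad) > 0) {
    stop(sprintf(
      "invalid %s value(s): %s (allowed: %s)",
      what, paste(bad, collapse = ", "), paste(levels, collapse = ", ")
    ), call. = FALSE)
  }
  x
}

# probability vector named by `levels`, summing to 1 within 1e-12
check_distribution <- function(p, levels, what) {
  if (is.null(names(p)) || !setequal(names(p), levels)) {
    stop(sprintf(
      "'%s' must be a named probability vector over {%s}",
      what, paste(levels, collapse = ", ")
    ), call. = FALSE)
  }
  p <- p[levels]
  if (any(p < 0)) stop(sprintf("'%s' has negative probabilities", what), call. = FALSE)
  if (abs(sum(p) - 1) > 1e-12) {
    stop(sprintf("'%s' must sum to 1 (got %.15f)", what, sum(p)), call. = FALSE)
  }
  p
}
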