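#' Restricted cubic spline basis for age
#'
#' Truncated-power parameterization of the natural (restricted) cubic spline:
#' with K knots \eqn{t_1 < \dots < t_K} the basis has K-1 columns, the first
#' being the identity (age in years) and the remaining K-2 the nonlinear terms
#' \deqn{C_j(x) = [(x-t_j)_+^3 - (x-t_{K-1})_+^3 (t_K-t_j)/(t_K-t_{K-1})
#'                + (x-t_K)_+^3 (t_{K-1}-t_j)/(t_K-t_{K-1})] / (t_K-t_1)^2,}
#' which are identically zero at and below the first knot and make the fitted
#' function linear beyond both boundary knots (second derivative zero outside
#' the knot span). The \eqn{(t_K-t_1)^2} divisor keeps the nonlinear columns on
#' roughly the scale of the linear one.
#'
#' @param x Numeric vector of ages (years).
#' @param knots Numeric vector of at least 3 strictly increasing knot
#'   locations (years).
#' @return Numeric matrix with `length(x)` rows and `length(knots) - 1`
#'   columns, named `age1`, `age2`, ...
#' @export
rcs_basis <- function(x, knots) {
  if (length(knots) < 3) {
    stop("rcs_basis() needs at least 3 knots", call. = FALSE)
  }
  knots <- as.numeric(knots)
  if (is.unsorted(knots, strictly = TRUE)) {
    stop("knots must be strictly increasing (no duplicates)", call. = FALSE)
  }
  K <- length(knots)
  tau <- (knots[K] - knots[1])^2
  pos3 <- function(u) pmax(u, 0)^3
  B <- matrix(0, length(x), K - 1)
  B[, 1] <- x
  for (j in seq_len(K - 2)) {
    B[, j + 1] <- (pos3(x - knots[j]) -
      pos3(x - knots[K - 1]) * (knots[K] - knots[j]) / (knots[K] - knots[K - 1]) +
      pos3(x - knots[K]) * (knots[K - 1] - knots[j]) / (knots[K] - knots[K - 1])) / tau
  }
  colnames(B) <- paste0("age", seq_len(K - 1))
  B
}

#' Default spline knots from observed origin ages
#'
#' Places knots at the 0.05, 0.275, 0.5, 0.725 and 0.95 quantiles of the
#' observed origin ages (5 knots), collapsing to fewer knots if ties leave
#' fewer than 5 distinct quantiles; falls back to 3 equally spaced knots over
#' the age range when the data are too concentrated.
#'
#' @param ages Numeric vector of origin ages observed in the data.
#' @return Numeric vector of knot locations.
#' @export
default_knots <- function(ages) {
  qs <- stats::quantile(ages, probs = c(0.05, 0.275, 0.5, 0.725, 0.95),
                        names = FALSE, type = 7)
  k <- unique(qs)
  if (length(k) >= 3) return(k)
  r <- range(ages)
  if (diff(r) <= 0) stop("cannot place spline knots: ages are constant", call. = FALSE)
  seq(r[1], r[2], length.out = 3)
}
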