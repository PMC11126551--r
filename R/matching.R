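#' Match chain mortality to an external period life table
#'
#' Adjusts the state-specific death probabilities of a transition array so
#' that the population survival curve implied by the chain reproduces an
#' external life table, while preserving the relative mortality structure
#' across states. Sequentially in age a, the current alive-state distribution
#' \eqn{\pi(a)} is computed under the already-adjusted earlier ages, a single
#' factor \eqn{c(a) \ge 0} is found (bisection to 1e-12) solving
#' \deqn{\sum_i \pi_i(a)\,\min(1, c(a) q_i(a)) = q_{lt}(a),}
#' the adjusted death probabilities are \eqn{q'_i(a) = \min(1, c(a) q_i(a))},
#' and each row's transient probabilities are rescaled by
#' \eqn{(1 - q'_i)/(1 - q_i)}. Because the scaling is proportional, the
#' state-specific mortality ordering is preserved and the relationship between
#' the status expectancies is essentially unchanged.
#'
#' @param P A [transition_array()].
#' @param lt Life table as returned by [read_lifetable()] (or a data frame
#'   with columns `age`, `qx` at the chain's step) covering all origin ages.
#' @param radix Initial distribution over transient states at the baseline age.
#' @param additive Fallback for ages where the model's mortality is zero in
#'   every state but the life table requires deaths: when `TRUE`, a uniform
#'   additive shift \eqn{q'_i = q_i + \delta(a)} is used at such ages instead
#'   of erroring (off by default).
#' @return Adjusted [transition_array()] whose implied population survival
#'   equals the life table's at every modelled age.
#' @export
match_mortality <- function(P, lt, radix, additive = FALSE) {
  radix <- normalize_radix(radix)
  ages <- attr(P, "ages")
  step <- attr(P, "step")
  idx <- match(ages, lt$age)
  if (anyNA(idx)) {
    stop(sprintf("life table missing ages: %s",
                 paste(ages[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  qlt <- lt$qx[idx]
  Q <- unclass(P)
  trans <- wl_transient_states()
  pi_a <- radix # conditional-on-alive distribution
  for (a in seq_along(ages)) {
    q <- Q[a, , "dead"]
    target <- qlt[a]
    if (target < 0 || target > 1) {
      stop(sprintf("life-table qx out of [0,1] at age %s", ages[a]), call. = FALSE)
    }
    if (target == 0) {
      qp <- rep(0, 3)
    } else if (all(q <= 0)) {
      if (!additive) {
        stop(sprintf(
          "cannot match at age %s: model mortality is zero but life table requires qx = %g",
          ages[a], target
        ), call. = FALSE)
      }
      qp <- rep(target, 3) # uniform additive shift: sum_i pi_i (q_i + delta) = q_lt
    } else {
      f <- function(cc) sum(pi_a * pmin(1, cc * q)) - target
      hi <- 1
      while (f(hi) < 0 && hi < 1e15) hi <- hi * 2
      if (f(hi) < 0) {
        stop(sprintf("life-table qx = %g unattainable at age %s", target, ages[a]),
             call. = FALSE)
      }
      lo <- 0
      while (hi - lo > 1e-12 * max(1, hi)) {
        mid <- (lo + hi) / 2
        if (f(mid) < 0) lo <- mid else hi <- mid
      }
      cc <- hi
      qp <- pmin(1, cc * q)
    }
    scale <- ifelse(q >= 1, 0, (1 - qp) / (1 - q))
    Q[a, , trans] <- Q[a, , trans] * scale
    Q[a, , "dead"] <- qp
    # advance conditional alive distribution
    if (a < length(ages)) {
      nxt <- as.vector(pi_a %*% Q[a, , trans])
      s <- sum(nxt)
      if (s <= 0) {
        stop(sprintf("population extinct after age %s during matching", ages[a]),
             call. = FALSE)
      }
      pi_a <- nxt / s
    }
  }
  transition_array(Q, ages, step)
}

#' Censored temporary life expectancy from a life table
#'
#' Expected years lived between the first modelled age and the censoring age
#' under the life table alone, using the same occupancy convention as the
#' chain (a person alive at exact age a contributes `step` years for
#' `[a, a + step)`; no fractional-year correction).
#'
#' @param lt Life table (`age`, `qx` at the given step).
#' @param ages Origin ages of the window.
#' @param step Step in years.
#' @return Temporary life expectancy in years.
#' @export
lifetable_expectancy <- function(lt, ages, step) {
  idx <- match(ages, lt$age)
  if (anyNA(idx)) stop("life table does not cover the requested ages", call. = FALSE)
  qx <- lt$qx[idx]
  surv <- cumprod(c(1, 1 - qx[-length(qx)]))
  step * sum(surv)
}
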