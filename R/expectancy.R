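#' Transition-probability array
#'
#' Constructor/validator for the age-specific transition probabilities of the
#' discrete-time multistate model: a 3-dimensional array `P[a, i, j]` over
#' origin ages `a` (baseline to censoring age minus one step), transient
#' origin states `i` (employed, jobless, retired) and destination states `j`
#' (the same three plus dead). Every row must be a probability distribution.
#'
#' @param P Numeric array `[n_ages, 3, 4]`.
#' @param ages Origin ages (years), one per slice of `P`.
#' @param step Step length in years (1 or 2).
#' @return Array of class `wl_transitions` with `ages` and `step` attributes.
#' @export
transition_array <- function(P, ages, step) {
  P <- unclass(P)
  if (length(dim(P)) != 3 || dim(P)[2] != 3 || dim(P)[3] != 4) {
    stop("P must be an [n_ages, 3, 4] array", call. = FALSE)
  }
  if (dim(P)[1] != length(ages)) {
    stop("length(ages) must match dim(P)[1]", call. = FALSE)
  }
  if (!step %in% c(1, 2)) stop("step must be 1 or 2", call. = FALSE)
  if (any(!is.finite(P)) || any(P < -1e-12) || any(P > 1 + 1e-12)) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  rs <- apply(P, c(1, 2), sum)
  if (any(abs(rs - 1) > 1e-8)) {
    stop("every transition row must sum to 1", call. = FALSE)
  }
  dimnames(P) <- list(as.character(ages), wl_transient_states(), wl_states())
  structure(P, ages = as.numeric(ages), step = step, class = "wl_transitions")
}

#' Age-expanded absorbing chain
#'
#' Expands the age-specific transition matrices into the transient-to-transient
#' matrix U of an absorbing Markov chain whose composite states are
#' (age, labor-force state), ordered age-major. Transitions go only from age a
#' to age a + step (block superdiagonal); rows of the final age block are zero,
#' i.e. everyone is absorbed after the last occupancy point (censoring).
#'
#' @param P A [transition_array()].
#' @return List with `U` (square matrix, 3 x n_ages), `labels` (composite
#'   state names) and the `ages`/`step` of the chain.
#' @export
build_chain <- function(P) {
  ages <- attr(P, "ages")
  step <- attr(P, "step")
  A <- length(ages)
  states <- wl_transient_states()
  n <- 3L * A
  U <- matrix(0, n, n)
  if (A > 1) {
    for (a in seq_len(A - 1)) {
      ri <- (a - 1) * 3 + 1:3
      ci <- a * 3 + 1:3
      U[ri, ci] <- P[a, , states]
    }
  }
  labels <- as.vector(outer(states, ages, function(s, a) paste0("age", a, "_", s)))
  dimnames(U) <- list(labels, labels)
  list(U = U, labels = labels, ages = ages, step = step)
}

#' State expectancies via the fundamental matrix
#'
#' Computes the expected number of years spent in each transient state between
#' the baseline age and the censoring age from the fundamental matrix
#' N = (I - U)^{-1} of the age-expanded absorbing chain: the radix-weighted
#' row of N gives expected visits to each (age, state) composite state, and a
#' visit contributes `step` years. The three state expectancies sum to the
#' total residual life expectancy over the window.
#'
#' @param P A [transition_array()].
#' @param radix Initial distribution over the transient states at the baseline
#'   age (named or in employed/jobless/retired order; must sum to 1).
#' @return A one-row [tibble::tibble] with columns `employment`, `joblessness`,
#'   `retirement`, `total` (years).
#' @export
fundamental_expectancies <- function(P, radix) {
  radix <- normalize_radix(radix)
  ch <- build_chain(P)
  A <- length(ch$ages)
  n <- 3L * A
  Nmat <- solve(diag(n) - ch$U)
  start <- c(radix, rep(0, n - 3))
  visits <- as.vector(start %*% Nmat)
  occ <- matrix(visits, nrow = A, ncol = 3, byrow = TRUE)
  exp_years <- ch$step * colSums(occ)
  tibble::tibble(
    employment = exp_years[1],
    joblessness = exp_years[2],
    retirement = exp_years[3],
    total = sum(exp_years)
  )
}

#' Forward state occupancies
#'
#' Independent oracle for [fundamental_expectancies()]: iterates the
#' occupancy vector forward, \eqn{\pi(a + step) = \pi(a) P(a)} restricted to
#' the transient states, starting from the radix at the baseline age.
#'
#' @inheritParams fundamental_expectancies
#' @return Matrix `[n_ages, 3]` of occupancy probabilities at each origin age
#'   (rows sum to the probability of being alive at that age).
#' @export
occupancy_forward <- function(P, radix) {
  radix <- normalize_radix(radix)
  ages <- attr(P, "ages")
  A <- length(ages)
  occ <- matrix(0, A, 3, dimnames = list(as.character(ages), wl_transient_states()))
  pi_a <- radix
  occ[1, ] <- pi_a
  if (A > 1) {
    for (a in seq_len(A - 1)) {
      pi_a <- as.vector(pi_a %*% P[a, , wl_transient_states()])
      occ[a + 1, ] <- pi_a
    }
  }
  occ
}

#' Zero out structural transition cells
#'
#' Optional hard-constraint mask for transitions held to be structurally
#' impossible: the named origin -> destination cells are set to zero at every
#' age and each affected row is renormalized to sum to one. By default no
#' mask is applied, since individuals may move back and forth between all
#' transient states.
#'
#' @param P A [transition_array()].
#' @param cells List of `c(origin, destination)` character pairs.
#' @return Masked [transition_array()].
#' @export
mask_cells <- function(P, cells) {
  Q <- unclass(P)
  for (cl in cells) {
    o <- match(cl[1], wl_transient_states())
    d <- match(cl[2], wl_states())
    if (is.na(o) || is.na(d)) {
      stop(sprintf("invalid mask cell: %s -> %s", cl[1], cl[2]), call. = FALSE)
    }
    Q[, o, d] <- 0
  }
  for (o in 1:3) {
    rsum <- rowSums(matrix(Q[, o, ], ncol = 4))
    if (any(rsum <= 0)) {
      stop("mask removes all mass from a transition row", call. = FALSE)
    }
    Q[, o, ] <- Q[, o, ] / rsum
  }
  transition_array(Q, attr(P, "ages"), attr(P, "step"))
}

normalize_radix <- function(radix) {
  states <- wl_transient_states()
  if (!is.null(names(radix))) {
    if (!setequal(names(radix), states)) {
      stop("radix must be named by the transient states", call. = FALSE)
    }
    radix <- radix[states]
  }
  if (length(radix) != 3 || any(radix < 0) || abs(sum(radix) - 1) > 1e-8) {
    stop("radix must be a probability vector over the three transient states",
         call. = FALSE)
  }
  as.numeric(radix / sum(radix))
}
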