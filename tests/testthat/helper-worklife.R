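# Shared fixtures and independent oracles for the test suite.

# Random valid transition array (Dirichlet rows). `death` scales mortality;
# death = 0 gives a zero-mortality chain.
random_transitions <- function(ages = 40:74, step = 1, death = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- length(ages)
  P <- array(0, dim = c(A, 3, 4))
  for (a in seq_len(A)) {
    for (o in 1:3) {
      g <- stats::rgamma(4, shape = c(4, 2, 2, 0.3))
      g[4] <- g[4] * death
      P[a, o, ] <- g / sum(g)
    }
  }
  transition_array(P, ages, step)
}

# Monte-Carlo trajectory oracle: mean years per state from n simulated
# trajectories of the chain (independent of the fundamental-matrix path).
# Returns list(mean = named vector, se = named vector).
mc_expectancies <- function(P, radix, n = 100000, seed = 1) {
  set.seed(seed)
  ages <- attr(P, "ages")
  step <- attr(P, "step")
  A <- length(ages)
  state <- sample.int(3, n, replace = TRUE, prob = radix)
  years <- matrix(0, n, 3)
  for (a in seq_len(A)) {
    alive <- state <= 3
    idx <- which(alive)
    years[cbind(idx, state[idx])] <- years[cbind(idx, state[idx])] + step
    if (a == A) break
    probs <- matrix(0, length(idx), 4)
    for (j in 1:4) probs[, j] <- P[cbind(rep(a, length(idx)), state[idx], rep(j, length(idx)))]
    cum <- probs
    cum[, 2] <- cum[, 1] + probs[, 2]
    cum[, 3] <- cum[, 2] + probs[, 3]
    u <- stats::runif(length(idx))
    nxt <- 1L + (u > cum[, 1]) + (u > cum[, 2]) + (u > cum[, 3])
    state[idx] <- nxt
  }
  tot <- rowSums(years)
  m <- c(colMeans(years), total = mean(tot))
  se <- c(apply(years, 2, stats::sd), stats::sd(tot)) / sqrt(n)
  names(m) <- names(se) <- c("employment", "joblessness", "retirement", "total")
  list(mean = m, se = se)
}

# deterministic simple chain: stay in `state` with prob p, else die
stay_or_die <- function(p, state = "employed", ages = 40:74, step = 1) {
  A <- length(ages)
  P <- array(0, dim = c(A, 3, 4))
  si <- match(state, wl_transient_states())
  for (o in 1:3) {
    P[, o, o] <- p
    P[, o, 4] <- 1 - p
  }
  P[, si, si] <- p
  transition_array(P, ages, step)
}

# hand-built tiny panel
tiny_panel <- function(df) {
  defaults <- list(gender = "woman", parity = "0", education = "low",
                   marital = "married", extra = "native")
  for (nm in names(defaults)) {
    if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  }
  tibble::as_tibble(df)
}

# truth set with all covariate and interaction effects zeroed (only
# intercept, origin and age terms active) — a correctly specified target for
# reduced-covariate model fits
covariate_free_truth <- function(knots = c(45, 55, 65)) {
  tr <- default_truth(knots = knots)
  for (g in names(tr$coefficients)) {
    m <- tr$coefficients[[g]]
    keep <- rownames(m) %in% c("(Intercept)", "origin_jobless", "origin_retired",
                               paste0("age", seq_len(length(knots) - 1)))
    m[!keep, ] <- 0
    tr$coefficients[[g]] <- m
  }
  tr
}

# synthetic Gompertz-like period life table over an age range
synthetic_lifetable <- function(ages = 40:75, a = 2e-4, b = 0.085) {
  tibble::tibble(age = ages, qx = pmin(0.6, a * exp(b * (ages - 40))))
}

# random chain whose mortality mis-states the life table by a bounded factor
# (the regime mortality matching is meant to correct): death probabilities
# are the life table's qx times a state-specific gradient and a random
# misstatement factor in [0.5, 2]
misstated_mortality_transitions <- function(lt, seed, ages = 40:74, step = 1) {
  set.seed(seed)
  A <- length(ages)
  qlt <- lt$qx[match(ages, lt$age)]
  grad <- c(0.8, 1.0, 1.3) # employed / jobless / retired mortality gradient
  mis <- stats::runif(A, 0.5, 2)
  P <- array(0, dim = c(A, 3, 4))
  for (a in seq_len(A)) {
    for (o in 1:3) {
      q <- min(0.9, qlt[a] * grad[o] * mis[a])
      g <- stats::rgamma(3, shape = c(4, 2, 2))
      P[a, o, 1:3] <- (1 - q) * g / sum(g)
      P[a, o, 4] <- q
    }
  }
  transition_array(P, ages, step)
}
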