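test_that("age-expanded chain has the right shape and censoring structure", {
  P <- random_transitions(seed = 1)
  ch <- build_chain(P)
  expect_equal(dim(ch$U), c(105, 105))
  # strictly block-superdiagonal: entries only in (age a, age a+1) blocks
  mask <- matrix(FALSE, 105, 105)
  for (a in 1:34) mask[(a - 1) * 3 + 1:3, a * 3 + 1:3] <- TRUE
  expect_true(all(ch$U[!mask] == 0))
  # final age block absorbs: its rows are all zero
  expect_true(all(ch$U[103:105, ] == 0))

  # zero-mortality chain: every non-final block row sums to 1
  P0 <- random_transitions(death = 0, seed = 2)
  U0 <- build_chain(P0)$U
  expect_equal(unname(rowSums(U0)[1:102]), rep(1, 102), tolerance = 1e-12)

  # U is nilpotent: U^(#ages) = 0, so the spectral radius is < 1
  M <- ch$U
  for (k in 1:6) M <- M %*% M # U^64, and 64 > 35
  expect_equal(max(abs(M)), 0)
})

test_that("closed-form chains give known expectancies", {
  # absorbing employment, no death
  P <- stay_or_die(1)
  e <- fundamental_expectancies(P, c(employed = 1, jobless = 0, retired = 0))
  expect_equal(e$employment, 35)
  expect_equal(e$joblessness, 0)
  expect_equal(e$retirement, 0)
  expect_equal(e$total, 35)

  # stay employed w.p. 0.9, else die: geometric series
  P <- stay_or_die(0.9)
  e <- fundamental_expectancies(P, c(employed = 1, jobless = 0, retired = 0))
  expect_equal(e$employment, sum(0.9^(0:34)), tolerance = 1e-12)

  # symmetric employed <-> jobless switching, no death
  A <- 35
  Ps <- array(0, dim = c(A, 3, 4))
  Ps[, 1, 1] <- 0.5; Ps[, 1, 2] <- 0.5
  Ps[, 2, 1] <- 0.5; Ps[, 2, 2] <- 0.5
  Ps[, 3, 3] <- 1
  Ps <- transition_array(Ps, 40:74, 1)
  e <- fundamental_expectancies(Ps, c(employed = 1, jobless = 0, retired = 0))
  expect_equal(e$employment, 18)
  expect_equal(e$joblessness, 17)

  # biennial zero-mortality window: 18 occupancy points x 2 years
  Pb <- stay_or_die(1, ages = seq(40, 74, by = 2), step = 2)
  e <- fundamental_expectancies(Pb, c(employed = 1, jobless = 0, retired = 0))
  expect_equal(e$total, 36)
})

test_that("forward occupancy is an exact oracle for the fundamental matrix", {
  for (s in 1:10) {
    P <- random_transitions(seed = s)
    radix <- c(0.7, 0.25, 0.05)
    e <- fundamental_expectancies(P, radix)
    occ <- occupancy_forward(P, radix)
    expect_equal(
      unname(unlist(e[c("employment", "joblessness", "retirement")])),
      unname(colSums(occ)),
      tolerance = 1e-10
    )
    expect_equal(e$total, sum(occ), tolerance = 1e-10)
  }
})

test_that("occupancy starts at the radix and mass decays under mortality", {
  P <- random_transitions(seed = 3)
  radix <- c(0.6, 0.3, 0.1)
  occ <- occupancy_forward(P, radix)
  expect_equal(unname(occ[1, ]), radix)
  expect_true(all(diff(rowSums(occ)) < 0))
})

test_that("expectancies are conserved and bounded", {
  for (s in 1:10) {
    P <- random_transitions(seed = 100 + s)
    e <- fundamental_expectancies(P, c(1 / 3, 1 / 3, 1 / 3))
    expect_equal(e$employment + e$joblessness + e$retirement, e$total,
                 tolerance = 1e-10)
    expect_lte(e$total, 35 + 1e-10)
    expect_true(all(unlist(e) >= 0))
  }
})

test_that("raising mortality never increases total life expectancy", {
  set.seed(42)
  for (s in 1:10) {
    P <- random_transitions(seed = 200 + s)
    Q <- unclass(P)
    # push extra mass into death, rescaling transient probabilities
    extra <- matrix(runif(35 * 3, 0, 0.2), 35, 3)
    for (o in 1:3) {
      q <- Q[, o, 4]
      qp <- pmin(1, q + extra[, o] * (1 - q))
      scale <- ifelse(q < 1, (1 - qp) / (1 - q), 0)
      Q[, o, 1:3] <- Q[, o, 1:3] * scale
      Q[, o, 4] <- qp
    }
    Q <- transition_array(Q, 40:74, 1)
    r <- c(0.5, 0.3, 0.2)
    expect_lte(fundamental_expectancies(Q, r)$total,
               fundamental_expectancies(P, r)$total + 1e-10)
  }
})

test_that("structural-zero mask zeroes cells and renormalizes", {
  P <- random_transitions(seed = 7)
  Pm <- mask_cells(P, list(c("retired", "employed"), c("retired", "jobless")))
  expect_true(all(unclass(Pm)[, 3, 1:2] == 0))
  expect_equal(apply(unclass(Pm), c(1, 2), sum),
               matrix(1, 35, 3, dimnames = dimnames(unclass(Pm))[1:2]),
               tolerance = 1e-12)
  expect_error(mask_cells(P, list(c("retired", "nowhere"))), "invalid mask cell")
})

test_that("window decomposition of expectancies is exact", {
  # expectancy over the full window = expectancy over the early window
  # + occupancy-weighted continuation from the cut age
  P <- random_transitions(seed = 11)
  radix <- c(0.8, 0.15, 0.05)
  cut <- 11 # age 50
  full <- fundamental_expectancies(P, radix)
  early <- fundamental_expectancies(
    transition_array(unclass(P)[1:(cut - 1), , , drop = FALSE], 40:49, 1), radix
  )
  occ <- occupancy_forward(P, radix)
  late <- sapply(1:3, function(s) {
    r <- c(0, 0, 0); r[s] <- 1
    unlist(fundamental_expectancies(
      transition_array(unclass(P)[cut:35, , , drop = FALSE], 50:74, 1), r
    )[c("employment", "joblessness", "retirement")])
  })
  alive <- sum(occ[cut, ])
  cont <- as.vector(late %*% (occ[cut, ] / alive)) * alive
  expect_equal(
    unname(unlist(full[c("employment", "joblessness", "retirement")])),
    unname(unlist(early[c("employment", "joblessness", "retirement")])) + cont,
    tolerance = 1e-10
  )
})
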