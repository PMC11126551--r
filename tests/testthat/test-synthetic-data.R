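test_that("identical config and seed give identical panels", {
  cfg <- generator_config(n_persons = 200, seed = 123)
  expect_identical(generate_panel(cfg), generate_panel(cfg))
  cfg2 <- generator_config(n_persons = 200, seed = 124)
  expect_false(identical(generate_panel(cfg), generate_panel(cfg2)))
})

test_that("invalid configurations are rejected with the offending field", {
  expect_error(generator_config(100, step = 3), "step")
  expect_error(generator_config(100, censor_age = 40), "censor_age")
  expect_error(
    generator_config(100, state_labels = c("employed", "jobless", "dead", "x")),
    "state_labels"
  )
  cd <- default_covariate_distributions()
  cd$marital["married"] <- 0.7 # no longer sums to 1
  expect_error(generator_config(100, covariate_distributions = cd), "marital")
  expect_error(
    generator_config(100, initial_state = c(employed = 0.8, jobless = 0.1, retired = 0.05)),
    "initial_state"
  )
})

test_that("generated panels satisfy the panel invariants", {
  set.seed(99)
  for (i in 1:4) {
    step <- sample(c(1, 2), 1)
    cfg <- generator_config(
      n_persons = 150, step = step, seed = 1000 + i,
      baseline_age = 40
    )
    pan <- generate_panel(cfg)
    expect_true(all(pan$age >= cfg$baseline_age & pan$age <= cfg$censor_age))
    by_person <- split(pan, pan$person_id)
    for (p in by_person) {
      expect_true(all(diff(p$age) == step))
      d <- which(p$state == "dead")
      if (length(d) > 0) expect_equal(d, nrow(p)) # death is terminal & last
    }
  }
})

test_that("zero-coefficient truth yields uniform destination draws", {
  cfg <- generator_config(
    n_persons = 50000, baseline_age = 40, censor_age = 42, step = 1,
    truth = default_truth(zero = TRUE), seed = 77
  )
  pan <- generate_panel(cfg)
  rec <- build_transition_records(pan, 1)
  first <- rec[rec$age == 40, ]
  freq <- table(factor(first$dest, levels = wl_states())) / nrow(first)
  se3 <- 3 * sqrt(0.25 * 0.75 / nrow(first))
  expect_true(all(abs(freq - 0.25) < se3))
})

test_that("empirical transition frequencies converge to the truth model", {
  # degenerate covariates: a single pattern, so cells aggregate cleanly
  cd <- list(
    gender = c(woman = 1, man = 0),
    parity = c("0" = 0, "1" = 0, "2" = 1, "3+" = 0),
    education = c(low = 0, medium = 1, high = 0),
    marital = c(married = 1, single = 0, divorced = 0, widowed = 0),
    extra = c(native = 1, foreign = 0)
  )
  cfg <- generator_config(n_persons = 50000, covariate_distributions = cd, seed = 31)
  pan <- generate_panel(cfg)
  rec <- build_transition_records(pan, 1)
  prof <- covariate_profile(education = "medium", parity = "2")
  spec <- model_spec(knots = cfg$truth$knots)
  P <- worklife:::truth_transitions(cfg$truth$coefficients$woman, prof,
                                    40:74, cfg$truth$knots, spec, 1)
  checked <- 0L
  ok3 <- 0L
  for (a in 40:74) {
    for (o in wl_transient_states()) {
      sub <- rec[rec$age == a & rec$origin == o, ]
      n <- nrow(sub)
      if (n < 200) next
      phat <- table(factor(sub$dest, levels = wl_states())) / n
      ptru <- P[as.character(a), o, ]
      se <- sqrt(pmax(ptru * (1 - ptru), 1e-12) / n)
      z <- abs(phat - ptru) / pmax(se, 1e-12)
      checked <- checked + 4L
      ok3 <- ok3 + sum(z < 3)
      expect_true(all(z < 4.5))
    }
  }
  expect_gt(checked, 100)
  expect_gt(ok3 / checked, 0.98)
})

test_that("truth expectancies match closed forms and Monte Carlo", {
  # force everyone to stay employed: huge negative intercepts elsewhere
  tr <- default_truth()
  for (g in c("woman", "man")) {
    tr$coefficients[[g]][] <- 0
    tr$coefficients[[g]]["(Intercept)", ] <- -100
  }
  cfg <- generator_config(n_persons = 10, truth = tr, seed = 1,
                          initial_state = c(employed = 1, jobless = 0, retired = 0))
  e <- truth_expectancies(cfg, gender = "woman")
  expect_equal(e$employment, 35, tolerance = 1e-8)
  expect_equal(e$total, 35, tolerance = 1e-8)

  # stay employed w.p. 0.9, else die
  tr2 <- tr
  for (g in c("woman", "man")) {
    tr2$coefficients[[g]]["(Intercept)", ] <- c(-100, -100, log(1 / 9))
  }
  cfg2 <- generator_config(n_persons = 10, truth = tr2, seed = 1,
                           initial_state = c(employed = 1, jobless = 0, retired = 0))
  e2 <- truth_expectancies(cfg2, gender = "woman")
  expect_equal(e2$employment, sum(0.9^(0:34)), tolerance = 1e-9)

  # biennial zero-mortality: 36 years total
  cfg3 <- generator_config(n_persons = 10, truth = tr, step = 2, seed = 1,
                           initial_state = c(employed = 1, jobless = 0, retired = 0))
  e3 <- truth_expectancies(cfg3, gender = "woman")
  expect_equal(e3$total, 36, tolerance = 1e-8)

  # Monte-Carlo equivalence at the default truth
  cfg4 <- generator_config(n_persons = 10, seed = 1)
  prof <- covariate_profile(education = "medium", parity = "2")
  spec <- model_spec(knots = cfg4$truth$knots)
  P <- worklife:::truth_transitions(cfg4$truth$coefficients$man, prof,
                                    40:74, cfg4$truth$knots, spec, 1)
  et <- truth_expectancies(cfg4, profile = prof, gender = "man")
  mc <- mc_expectancies(P, cfg4$initial_state, n = 100000, seed = 5)
  for (q in c("employment", "joblessness", "retirement", "total")) {
    expect_lt(abs(et[[q]] - mc$mean[[q]]), 3 * mc$se[[q]])
  }
})

test_that("thinning emulates biennial observation of annual trajectories", {
  cfg <- generator_config(n_persons = 300, seed = 55)
  pan <- generate_panel(cfg)
  th <- thin_panel(pan, every = 2)
  expect_true(all(th$age %% 2 == 0))
  expect_true(all(diff(range(th$age)) <= 36))
  # deaths are retained, moved to the next observation wave
  expect_equal(
    sort(unique(pan$person_id[pan$state == "dead"])),
    sort(unique(th$person_id[th$state == "dead"]))
  )
  by_person <- split(th, th$person_id)
  for (p in by_person) {
    expect_true(all(diff(p$age) == 2))
    d <- which(p$state == "dead")
    if (length(d) > 0) expect_equal(d, nrow(p))
  }
})
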