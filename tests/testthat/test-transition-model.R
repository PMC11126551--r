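# independent log-likelihood evaluation at given coefficients
ll_at <- function(X, Y, beta) {
  eta <- cbind(0, X %*% beta) # reference destination first
  sum(Y * (eta - log(rowSums(exp(eta)))))
}

test_that("intercept-only MLE reproduces observed destination frequencies", {
  X <- matrix(1, 4, 1, dimnames = list(NULL, "(Intercept)"))
  Y <- diag(4) * c(5000, 3000, 1500, 500)
  colnames(Y) <- wl_states()
  fit <- worklife:::multinom_newton(X, Y)
  P <- worklife:::softmax_probs(matrix(1, 1, 1), fit$coefficients, wl_states())
  expect_equal(as.numeric(P), c(0.5, 0.3, 0.15, 0.05), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("fitted coefficients recover the simulation truth within 3 SE", {
  cfg <- generator_config(n_persons = 1600, seed = 202)
  pan <- generate_panel(cfg)
  rec <- build_transition_records(pan, 1)
  expect_gt(nrow(rec), 45000)
  fit <- fit_transition_model(rec, model_spec(knots = cfg$truth$knots), se = TRUE)
  hits <- 0L
  terms <- 0L
  for (g in c("woman", "man")) {
    est <- fit$fits[[g]]$coefficients
    se <- fit$fits[[g]]$se
    tru <- cfg$truth$coefficients[[g]][rownames(est), colnames(est)]
    use <- is.finite(se) & se > 0
    hits <- hits + sum(abs(est - tru)[use] < 3 * se[use])
    terms <- terms + sum(use)
  }
  expect_gt(terms, 100)
  expect_gte(hits / terms, 0.95)
  # MLE property: likelihood at the MLE dominates likelihood at the truth
  for (g in c("woman", "man")) {
    spec <- model_spec(knots = cfg$truth$knots)
    agg <- worklife:::aggregate_records(rec[rec$gender == g, ], spec, cfg$truth$knots)
    Y <- agg$Y[, c("employed", "jobless", "retired", "dead")]
    tru <- cfg$truth$coefficients[[g]]
    expect_gte(ll_at(agg$X, Y, fit$fits[[g]]$coefficients[rownames(tru), ]) + 1e-6,
               ll_at(agg$X, Y, tru))
  }
})

test_that("a never-observed destination gets vanishing probability", {
  set.seed(4)
  n <- 400
  rec <- tiny_panel(data.frame(
    person_id = seq_len(n), time = 1,
    age = sample(40:70, n, replace = TRUE),
    state = "employed"
  ))
  rec$origin <- sample(c("employed", "jobless", "retired"), n, replace = TRUE)
  rec$dest <- sample(c("employed", "jobless", "dead"), n, replace = TRUE,
                     prob = c(0.6, 0.3, 0.1)) # never "retired"
  rec$gender <- "woman"
  fit <- fit_transition_model(
    tibble::as_tibble(rec),
    model_spec(knots = c(45, 55, 65), covariates = character(0))
  )
  prof <- covariate_profile()
  P <- predict_matrix(fit, prof, "woman", 40:70, 1)
  expect_lt(max(unclass(P)[, , "retired"]), 1e-6)
})

test_that("an empty origin state in a stratum is an error", {
  rec <- tiny_panel(data.frame(
    person_id = 1:50, time = 1, age = 45, state = "employed"
  ))
  rec$origin <- "employed"
  rec$dest <- "jobless"
  expect_error(
    fit_transition_model(tibble::as_tibble(rec),
                         model_spec(knots = c(41, 45, 49))),
    "jobless, retired"
  )
})

test_that("zero coefficients predict uniform transitions and rows sum to one", {
  spec <- model_spec(knots = c(45, 55, 65))
  prof <- covariate_profile(education = c(low = 0.3, medium = 0.4, high = 0.3),
                            parity = c("0" = 0.2, "1" = 0.2, "2" = 0.4, "3+" = 0.2),
                            marital = c(married = 0.6, single = 0.2,
                                        divorced = 0.15, widowed = 0.05))
  tr <- default_truth(zero = TRUE)
  P0 <- worklife:::predict_from_coef(tr$coefficients$woman, prof, 40:74,
                                     spec, tr$knots, 1)
  expect_equal(unname(unclass(P0)), array(0.25, dim = c(35, 3, 4)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # row normalization for random coefficient draws
  set.seed(12)
  for (i in 1:10) {
    co <- tr$coefficients$woman
    co[] <- rnorm(length(co), sd = 0.5)
    P <- worklife:::predict_from_coef(co, prof, 40:74, spec, tr$knots, 1)
    expect_lt(max(abs(apply(unclass(P), c(1, 2), sum) - 1)), 1e-10)
  }
})

test_that("population and group profiles follow the sample proportions", {
  rec <- tiny_panel(data.frame(
    person_id = 1:100, time = 1, age = 45, state = "employed",
    marital = rep(c("married", "single", "divorced", "widowed"),
                  c(60, 15, 19, 6)),
    parity = rep(c("0", "1", "2", "3+"), 25)
  ))
  rec$origin <- "employed"; rec$dest <- "employed"
  prof <- population_profile(tibble::as_tibble(rec))
  expect_equal(unname(prof$marital),
               c(0.60, 0.15, 0.19, 0.06))
  # group profile: parity indicator set to one
  g2 <- population_profile(tibble::as_tibble(rec), parity = "2")
  expect_equal(unname(g2$parity), c(0, 0, 1, 0))
  expect_equal(unname(colSums(g2$edu_parity)), c(0, 0, 1, 0))
  # degenerate: all married
  rec$marital <- "married"
  pm <- population_profile(tibble::as_tibble(rec))
  expect_equal(unname(pm$marital), c(1, 0, 0, 0))
  expect_error(population_profile(tibble::as_tibble(rec), education = "high"),
               "education=high")
})

test_that("gender-stratified fits equal a pooled fully interacted fit", {
  cfg <- generator_config(n_persons = 500, seed = 303)
  pan <- generate_panel(cfg)
  rec <- build_transition_records(pan, 1)
  spec <- model_spec(knots = cfg$truth$knots,
                     covariates = c("education", "parity"), interaction = FALSE)
  fit <- fit_transition_model(rec, spec)
  # pooled design: block column structure [X * 1(woman), X * 1(man)]
  agg_w <- worklife:::aggregate_records(rec[rec$gender == "woman", ], spec, cfg$truth$knots)
  agg_m <- worklife:::aggregate_records(rec[rec$gender == "man", ], spec, cfg$truth$knots)
  zero_w <- matrix(0, nrow(agg_w$X), ncol(agg_w$X))
  zero_m <- matrix(0, nrow(agg_m$X), ncol(agg_m$X))
  Xp <- rbind(cbind(agg_w$X, zero_w), cbind(zero_m, agg_m$X))
  colnames(Xp) <- c(paste0("w:", colnames(agg_w$X)), paste0("m:", colnames(agg_m$X)))
  Yp <- rbind(agg_w$Y, agg_m$Y)
  pooled <- worklife:::multinom_newton(Xp, Yp)
  expect_equal(pooled$loglik,
               fit$fits$woman$loglik + fit$fits$man$loglik, tolerance = 1e-6)
  # compare on the probability scale (flat likelihood directions can leave
  # individual coefficients less tightly pinned than the fit itself)
  pw <- pooled$coefficients[seq_len(ncol(agg_w$X)), ]
  probs_pooled <- worklife:::softmax_probs(agg_w$X, pw, wl_states())
  probs_strat <- worklife:::softmax_probs(agg_w$X, fit$fits$woman$coefficients,
                                          wl_states())
  expect_lt(max(abs(probs_pooled - probs_strat)), 1e-5)
})

test_that("fit agrees with nnet::multinom as an independent oracle", {
  cfg <- generator_config(n_persons = 800, seed = 404)
  pan <- generate_panel(cfg)
  rec <- build_transition_records(pan, 1)
  rec <- rec[rec$gender == "man", ]
  spec <- model_spec(knots = cfg$truth$knots,
                     covariates = c("education", "marital"), interaction = FALSE)
  fit <- fit_transition_model(rec, spec)
  agg <- worklife:::aggregate_records(rec, spec, cfg$truth$knots)
  npat <- nrow(agg$Y)
  dat <- as.data.frame(agg$X[, -1])[rep(seq_len(npat), 4), ]
  dat$dest <- factor(rep(wl_states(), each = npat), levels = wl_states())
  dat$w <- as.vector(agg$Y)
  dat <- dat[dat$w > 0, ]
  nn <- nnet::multinom(dest ~ ., data = dat[setdiff(names(dat), "w")],
                       weights = dat$w, trace = FALSE, maxit = 500, reltol = 1e-12)
  ll_nn <- -nn$deviance / 2
  expect_equal(fit$fits$man$loglik, ll_nn, tolerance = 1e-6)
  # predicted probabilities agree on the observed patterns
  pn <- predict(nn, newdata = as.data.frame(agg$X[, -1]), type = "probs")
  pm <- worklife:::softmax_probs(agg$X, fit$fits$man$coefficients, wl_states())
  expect_lt(max(abs(pn - pm[, colnames(pn)])), 1e-5)
})
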