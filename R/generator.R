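#' Default covariate marginals for synthetic panels
#'
#' Marginal distributions of the person-level covariates used by the
#' generator, on the order of magnitude of register/panel samples of people
#' aged 40+: roughly balanced gender, a parity distribution concentrated at
#' two children, a three-level education split, a married majority, and a
#' small minority level of the extra (country-specific) covariate.
#'
#' @return Named list of named probability vectors
#'   (`gender`, `parity`, `education`, `marital`, `extra`).
#' @export
default_covariate_distributions <- function() {
  list(
    gender = c(woman = 0.53, man = 0.47),
    parity = c("0" = 0.19, "1" = 0.17, "2" = 0.36, "3+" = 0.28),
    education = c(low = 0.31, medium = 0.38, high = 0.31),
    marital = c(married = 0.60, single = 0.18, divorced = 0.17, widowed = 0.05),
    extra = c(native = 0.97, foreign = 0.03)
  )
}

#' Ground-truth multinomial-logit coefficients
#'
#' A coefficient set for the generator's true transition model, one matrix per
#' gender, rows = linear-predictor terms (same expansion as the fitted model,
#' see [model_spec()]), columns = non-reference destinations
#' (jobless, retired, dead; reference = employed). The defaults encode
#' plausible labor-market dynamics: strong state persistence, retirement and
#' mortality risks rising with age (with a mild nonlinearity through the
#' spline), an education gradient, and parity effects that differ by gender.
#'
#' @param knots Spline knots (years) of the true age effect.
#' @param extra_levels Levels of the extra covariate.
#' @param zero Logical; if `TRUE`, return all-zero coefficients (every
#'   transition probability 1/4), useful for sampling checks.
#' @return List with `knots`, `extra_levels` and `coefficients` (named list
#'   `woman`/`man` of term x destination matrices).
#' @export
default_truth <- function(knots = c(45, 55, 65),
                          extra_levels = c("native", "foreign"),
                          zero = FALSE) {
  spec <- model_spec(knots = knots, extra_levels = extra_levels)
  terms <- colnames(build_design(
    data.frame(age = knots[1], origin = "employed", education = "low",
               parity = "0", marital = "married", extra = extra_levels[1]),
    spec, knots
  ))
  dest <- c("jobless", "retired", "dead")
  empty <- matrix(0, length(terms), length(dest),
                  dimnames = list(terms, dest))
  if (zero) {
    return(list(knots = knots, extra_levels = extra_levels,
                coefficients = list(woman = empty, man = empty)))
  }
  base <- empty
  set_term <- function(m, term, values) {
    m[term, names(values)] <- values
    m
  }
  base <- set_term(base, "(Intercept)", c(jobless = -3.0, retired = -13.0, dead = -10.0))
  base <- set_term(base, "origin_jobless", c(jobless = 4.5, retired = 0.5, dead = 0.3))
  base <- set_term(base, "origin_retired", c(jobless = 0.5, retired = 6.0, dead = 0.4))
  base <- set_term(base, "age1", c(jobless = 0.010, retired = 0.180, dead = 0.095))
  base <- set_term(base, "age2", c(jobless = 0.005, retired = 0.020, dead = 0.010))
  base <- set_term(base, "edu_medium", c(jobless = -0.25, retired = -0.05, dead = -0.10))
  base <- set_term(base, "edu_high", c(jobless = -0.50, retired = -0.10, dead = -0.25))
  base <- set_term(base, "parity_1", c(jobless = -0.10, retired = -0.05, dead = -0.05))
  base <- set_term(base, "parity_2", c(jobless = -0.20, retired = -0.05, dead = -0.10))
  base <- set_term(base, "parity_3plus", c(jobless = -0.05, retired = 0.00, dead = -0.05))
  base <- set_term(base, "marital_single", c(jobless = 0.20, retired = 0.05, dead = 0.15))
  base <- set_term(base, "marital_divorced", c(jobless = 0.10, retired = 0.00, dead = 0.10))
  base <- set_term(base, "marital_widowed", c(jobless = 0.15, retired = 0.10, dead = 0.10))
  if ("extra_foreign" %in% terms) {
    base <- set_term(base, "extra_foreign", c(jobless = 0.30, retired = -0.10, dead = 0.05))
  }
  woman <- base
  woman <- set_term(woman, "(Intercept)", c(jobless = -2.7, retired = -13.0, dead = -10.3))
  woman <- set_term(woman, "parity_3plus", c(jobless = 0.25, retired = 0.05, dead = -0.05))
  woman <- set_term(woman, "edu_high:parity_3plus", c(jobless = -0.30))
  woman <- set_term(woman, "edu_medium:parity_2", c(jobless = -0.15))
  man <- base
  man <- set_term(man, "edu_medium:parity_2", c(jobless = -0.10))
  list(knots = knots, extra_levels = extra_levels,
       coefficients = list(woman = woman, man = man))
}

#' Generator configuration
#'
#' Validated configuration for [generate_panel()]: sample size, observation
#' design (annual with censoring at 75, or biennial with censoring at 76),
#' covariate marginals, initial-state distribution at the baseline age, and
#' the ground-truth transition model.
#'
#' @param n_persons Number of persons.
#' @param baseline_age First observed age (years).
#' @param censor_age Age at/after which observation stops; defaults to
#'   `baseline_age + 35` for annual and `baseline_age + 36` for biennial
#'   designs.
#' @param step Observation spacing in years (1 or 2).
#' @param state_labels Must be exactly the four analysis states.
#' @param covariate_distributions As [default_covariate_distributions()].
#' @param initial_state Distribution over transient states at the baseline
#'   age. The default (employed 0.75, jobless 0.20, retired 0.05) is an
#'   explicit convention: expectancies are undefined without a baseline mix.
#' @param truth Ground-truth model as [default_truth()].
#' @param seed Integer master seed; panels are byte-identical given
#'   (config, seed).
#' @return Object of class `wl_generator_config`.
#' @export
generator_config <- function(n_persons,
                             baseline_age = 40,
                             censor_age = NULL,
                             step = 1,
                             state_labels = wl_states(),
                             covariate_distributions = default_covariate_distributions(),
                             initial_state = c(employed = 0.75, jobless = 0.20, retired = 0.05),
                             truth = default_truth(),
                             seed = 1L) {
  if (!step %in% c(1, 2)) stop("config error in 'step': must be 1 or 2", call. = FALSE)
  if (is.null(censor_age)) censor_age <- baseline_age + 34 + step
  if (censor_age <= baseline_age) {
    stop("config error in 'censor_age': must exceed baseline_age", call. = FALSE)
  }
  if (length(state_labels) != 4 || !setequal(state_labels, wl_states())) {
    stop("config error in 'state_labels': must be exactly employed, jobless, retired, dead",
         call. = FALSE)
  }
  req <- list(gender = wl_gender_levels(), parity = wl_parity_levels(),
              education = wl_education_levels(), marital = wl_marital_levels(),
              extra = truth$extra_levels)
  for (nm in names(req)) {
    if (is.null(covariate_distributions[[nm]])) {
      stop(sprintf("config error in 'covariate_distributions': missing '%s'", nm),
           call. = FALSE)
    }
    covariate_distributions[[nm]] <-
      check_distribution(covariate_distributions[[nm]], req[[nm]],
                         paste0("covariate_distributions$", nm))
  }
  initial_state <- check_distribution(initial_state, wl_transient_states(),
                                      "initial_state")
  if (n_persons < 1) stop("config error in 'n_persons': must be >= 1", call. = FALSE)
  structure(
    list(n_persons = as.integer(n_persons), baseline_age = baseline_age,
         censor_age = censor_age, step = step,
         covariate_distributions = covariate_distributions,
         initial_state = initial_state, truth = truth, seed = as.integer(seed)),
    class = "wl_generator_config"
  )
}

# origin ages of a config's observation design
config_ages <- function(config) {
  seq(config$baseline_age, config$censor_age - config$step, by = config$step)
}

# transition array implied by a coefficient matrix at a covariate profile
truth_transitions <- function(coef, profile, ages, knots, spec, step) {
  pd <- profile_design(profile, ages, spec, knots)
  Pm <- softmax_probs(pd$X, coef, wl_states(), ref_index = 1)
  A <- length(ages)
  P <- array(0, dim = c(A, 3, 4))
  for (o in 1:3) {
    P[, o, ] <- Pm[pd$grid$origin == wl_transient_states()[o], ]
  }
  transition_array(P, ages, step)
}

#' Generate a synthetic longitudinal panel
#'
#' Draws person-level covariates from the configured marginals (independent
#' across persons, frozen over time), an initial labor-force state at the
#' baseline age, then advances each person's state at every step by sampling
#' from the ground-truth model's transition probabilities. Observation stops
#' at the censoring age; death is absorbing, so no record follows a `dead`
#' record (the death wave itself is recorded).
#'
#' @param config A [generator_config()].
#' @return A [tibble::tibble] panel with columns `person_id`, `time`, `age`,
#'   `state`, `gender`, `parity`, `education`, `marital`, `extra`.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "wl_generator_config"))
  set.seed(config$seed)
  n <- config$n_persons
  cd <- config$covariate_distributions
  draw <- function(p) sample(names(p), n, replace = TRUE, prob = p)
  gender <- draw(cd$gender)
  parity <- draw(cd$parity)
  education <- draw(cd$education)
  marital <- draw(cd$marital)
  extra <- draw(cd$extra)

  spec <- model_spec(knots = config$truth$knots,
                     extra_levels = config$truth$extra_levels)
  ages <- config_ages(config)
  A <- length(ages)
  waves <- c(ages, config$censor_age)

  # transition probabilities per unique covariate pattern
  pat_df <- data.frame(gender = gender, education = education, parity = parity,
                       marital = marital, extra = extra, stringsAsFactors = FALSE)
  key <- do.call(paste, c(pat_df, sep = "\r"))
  upat <- !duplicated(key)
  pat_id <- match(key, key[upat])
  updf <- pat_df[upat, , drop = FALSE]
  npat <- nrow(updf)
  # PP[pattern, age, origin, dest]
  PP <- array(0, dim = c(npat, A, 3, 4))
  for (k in seq_len(npat)) {
    prof <- covariate_profile(
      education = updf$education[k], parity = updf$parity[k],
      marital = updf$marital[k],
      extra = stats::setNames(as.numeric(config$truth$extra_levels == updf$extra[k]),
                              config$truth$extra_levels),
      extra_levels = config$truth$extra_levels
    )
    PP[k, , , ] <- unclass(truth_transitions(
      config$truth$coefficients[[updf$gender[k]]], prof, ages,
      config$truth$knots, spec, config$step
    ))
  }

  states <- matrix(NA_integer_, n, A + 1)
  states[, 1] <- sample.int(3, n, replace = TRUE, prob = config$initial_state)
  alive <- rep(TRUE, n)
  for (a in seq_len(A)) {
    idx <- which(alive)
    if (length(idx) == 0) break
    # destination probabilities for each living person
    probs <- matrix(0, length(idx), 4)
    for (j in 1:4) {
      probs[, j] <- PP[cbind(pat_id[idx], a, states[idx, a], j)]
    }
    u <- stats::runif(length(idx))
    cum <- t(apply(probs, 1, cumsum))
    dest <- 1L + rowSums(u > cum[, 1:3, drop = FALSE])
    states[idx, a + 1] <- dest
    died <- dest == 4L
    alive[idx[died]] <- FALSE
  }

  obs <- !is.na(states)
  person_id <- rep(seq_len(n), times = rowSums(obs))
  flat <- which(t(obs)) # person-major order
  wave_idx <- (flat - 1L) %% (A + 1L) + 1L
  tibble::tibble(
    person_id = person_id,
    time = wave_idx,
    age = waves[wave_idx],
    state = wl_states()[states[cbind(person_id, wave_idx)]],
    gender = gender[person_id],
    parity = parity[person_id],
    education = education[person_id],
    marital = marital[person_id],
    extra = extra[person_id]
  )
}

#' Ground-truth state expectancies
#'
#' Computes expectancies directly from the generator's true transition model
#' at a covariate profile — no data, no fitting — via the fundamental matrix.
#' This is the recovery target for the full estimation pipeline.
#'
#' @param config A [generator_config()].
#' @param profile A [covariate_profile()]; defaults to the population profile
#'   implied by the config's covariate marginals.
#' @param gender Stratum whose true coefficients to use.
#' @param radix Initial-state distribution; defaults to the config's.
#' @return One-row tibble as [fundamental_expectancies()].
#' @export
truth_expectancies <- function(config, profile = NULL, gender = "woman",
                               radix = NULL) {
  stopifnot(inherits(config, "wl_generator_config"))
  gender <- match.arg(gender, wl_gender_levels())
  cd <- config$covariate_distributions
  if (is.null(profile)) {
    profile <- covariate_profile(
      education = cd$education, parity = cd$parity, marital = cd$marital,
      extra = cd$extra, extra_levels = config$truth$extra_levels
    )
  }
  if (is.null(radix)) radix <- config$initial_state
  spec <- model_spec(knots = config$truth$knots,
                     extra_levels = config$truth$extra_levels)
  P <- truth_transitions(config$truth$coefficients[[gender]], profile,
                         config_ages(config), config$truth$knots, spec,
                         config$step)
  fundamental_expectancies(P, radix)
}

#' Thin a panel to every k-th wave
#'
#' Keeps waves 1, 1+k, 1+2k, ... of each person, emulating a lower observation
#' frequency (e.g. biennial observation of annually simulated trajectories).
#' A death occurring at a dropped wave is observed at the next kept wave, as
#' in survey panels that record the year of death: the death record's age is
#' moved to the next kept observation age.
#'
#' @param panel A panel tibble.
#' @param every Keep every `every`-th wave (default 2).
#' @return Thinned panel with `time` renumbered and `age` on the kept grid.
#' @export
thin_panel <- function(panel, every = 2) {
  keep_wave <- function(t) (t - 1) %% every == 0
  first_age <- min(panel$age)
  step0 <- infer_panel_step(panel)
  out <- panel
  # move deaths at dropped waves forward to the next kept wave
  dead <- out$state == "dead" & !keep_wave(out$time)
  out$time[dead] <- out$time[dead] + (every - (out$time[dead] - 1) %% every)
  out$age[dead] <- first_age + (out$time[dead] - 1) * step0
  out <- out[keep_wave(out$time) | dead, , drop = FALSE]
  out <- out[keep_wave(out$time), , drop = FALSE]
  out$time <- (out$time - 1) %/% every + 1
  dplyr::arrange(out, .data$person_id, .data$time)
}

# observation spacing implied by a panel's age grid
infer_panel_step <- function(panel) {
  d <- diff(sort(unique(panel$age)))
  if (length(d) == 0) return(1)
  min(d)
}
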