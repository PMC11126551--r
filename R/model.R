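# aggregate transition records into unique-pattern counts for the fitter
aggregate_records <- function(records, spec, knots) {
  cols <- c("age", "origin", intersect(spec$covariates, names(records)))
  key <- do.call(paste, c(records[cols], sep = "\r"))
  first <- !duplicated(key)
  pid <- match(key, key[first])
  updf <- as.data.frame(records[first, cols, drop = FALSE])
  X <- build_design(updf, spec, knots)
  dest_id <- match(records$dest, wl_states())
  Y <- matrix(
    tabulate(pid + nrow(updf) * (dest_id - 1L), nbins = nrow(updf) * 4L),
    nrow(updf), 4
  )
  colnames(Y) <- wl_states()
  list(X = X, Y = Y, patterns = updf)
}

#' Fit gender-stratified multinomial transition models
#'
#' Maximum-likelihood multinomial logit of the destination state on the
#' origin-state indicators, the restricted-cubic-spline age basis, the
#' covariate main effects and the education x parity interaction, fitted
#' separately within each gender stratum. Records are aggregated to unique
#' covariate patterns before fitting (the likelihood is identical), which
#' makes repeated refits — as in the bootstrap — cheap. Reference destination
#' is `employed`.
#'
#' @param records Transition records from [build_transition_records()].
#' @param spec A [model_spec()].
#' @param se Compute coefficient standard errors from the inverse observed
#'   information (needed for recovery diagnostics; off by default).
#' @return Object of class `wl_fit_set`: named list of per-stratum fits, each
#'   with `coefficients` (term x destination), `loglik`, `converged`,
#'   `ridge`, `se`, `stratum`, plus shared `spec` and `knots`.
#' @export
fit_transition_model <- function(records, spec = model_spec(), se = FALSE) {
  if (nrow(records) == 0) stop("no transition records to fit", call. = FALSE)
  knots <- spec$knots
  if (is.null(knots)) knots <- default_knots(records$age)
  genders <- sort(unique(records$gender))
  fits <- lapply(genders, function(g) {
    rg <- records[records$gender == g, , drop = FALSE]
    missing_origin <- setdiff(wl_transient_states(), unique(rg$origin))
    if (length(missing_origin) > 0) {
      stop(sprintf("stratum '%s' has no records from origin state(s): %s",
                   g, paste(missing_origin, collapse = ", ")), call. = FALSE)
    }
    agg <- aggregate_records(rg, spec, knots)
    fit <- multinom_newton(agg$X, agg$Y, compute_se = se)
    fit$stratum <- g
    fit$n_records <- nrow(rg)
    fit
  })
  names(fits) <- genders
  structure(list(fits = fits, spec = spec, knots = knots), class = "wl_fit_set")
}

#' Population / group covariate profile from records
#'
#' Computes the covariate proportions over the (optionally filtered) records:
#' for population-level estimates, every categorical block is set to its
#' sample proportion; for group-specific estimates the group's own
#' indicator(s) are implicitly set to one because filtering leaves only that
#' level, and the remaining blocks take within-group proportions. The
#' education x parity interaction cells carry the observed joint proportions.
#'
#' @param records Transition records.
#' @param gender,parity,education Optional filters defining the group.
#' @param extra_levels Level order of the extra covariate (reference first).
#' @return A [covariate_profile()].
#' @export
population_profile <- function(records, gender = NULL, parity = NULL,
                               education = NULL,
                               extra_levels = c("native", "foreign")) {
  sel <- rep(TRUE, nrow(records))
  if (!is.null(gender)) sel <- sel & records$gender == gender
  if (!is.null(parity)) sel <- sel & records$parity == parity
  if (!is.null(education)) sel <- sel & records$education == education
  r <- records[sel, , drop = FALSE]
  if (nrow(r) == 0) {
    stop(sprintf("no records for group (gender=%s, parity=%s, education=%s)",
                 gender %||% "*", parity %||% "*", education %||% "*"),
         call. = FALSE)
  }
  prop <- function(x, levels) {
    p <- table(factor(x, levels = levels))
    stats::setNames(as.numeric(p) / length(x), levels)
  }
  joint <- table(factor(r$education, levels = wl_education_levels()),
                 factor(r$parity, levels = wl_parity_levels()))
  covariate_profile(
    education = prop(r$education, wl_education_levels()),
    parity = prop(r$parity, wl_parity_levels()),
    marital = prop(r$marital, wl_marital_levels()),
    extra = prop(r$extra, extra_levels),
    edu_parity = unclass(joint) / nrow(r),
    extra_levels = extra_levels
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict age-specific transition-probability matrices
#'
#' Evaluates the fitted linear predictors at a covariate profile for every
#' (origin age, origin state) and applies the softmax over the four
#' destinations, yielding a [transition_array()] whose rows sum to one.
#'
#' @param fit A `wl_fit_set` from [fit_transition_model()].
#' @param profile A [covariate_profile()].
#' @param stratum Gender stratum to predict for.
#' @param ages Origin ages (years).
#' @param step Step in years.
#' @return A [transition_array()].
#' @export
predict_matrix <- function(fit, profile, stratum, ages, step = 1) {
  stopifnot(inherits(fit, "wl_fit_set"))
  f <- fit$fits[[stratum]]
  if (is.null(f)) stop(sprintf("no fitted stratum '%s'", stratum), call. = FALSE)
  predict_from_coef(f$coefficients, profile, ages, fit$spec, fit$knots, step)
}

predict_from_coef <- function(coef, profile, ages, spec, knots, step) {
  pd <- profile_design(profile, ages, spec, knots)
  if (!identical(colnames(pd$X), rownames(coef))) {
    miss <- setdiff(rownames(coef), colnames(pd$X))
    if (length(miss) > 0) {
      stop(sprintf("profile is missing model term(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    pd$X <- pd$X[, rownames(coef), drop = FALSE]
  }
  Pm <- softmax_probs(pd$X, coef, wl_states(), ref_index = 1)
  A <- length(ages)
  P <- array(0, dim = c(A, 3, 4))
  for (o in 1:3) {
    P[, o, ] <- Pm[pd$grid$origin == wl_transient_states()[o], ]
  }
  transition_array(P, ages, step)
}
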