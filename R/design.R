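#' Transition-model specification
#'
#' Describes the linear predictor of the gender-stratified discrete-time
#' multinomial transition model: lagged origin state (categorical), a
#' restricted-cubic-spline age effect, main effects of the selected
#' covariates, and (optionally) the education-by-parity interaction.
#'
#' Reference categories are fixed: destination = employed, origin = employed,
#' education = low, parity = 0, marital = married, and the first level of the
#' extra covariate.
#'
#' @param knots Spline knot locations in years, or `NULL` to place them at
#'   quantiles of the observed origin ages at fit time (see [default_knots()]).
#' @param covariates Character subset of
#'   `c("education", "parity", "marital", "extra")` entering as main effects.
#' @param interaction Logical; include education x parity interaction terms
#'   (only when both enter as main effects).
#' @param origin_age_interaction Logical; additionally interact the origin
#'   state indicators with the age spline basis, letting the age profile
#'   differ by origin state (off by default: the minimal parameterization has
#'   origin state as a main effect only).
#' @param extra_levels Levels of the country-specific extra categorical
#'   covariate (reference first).
#' @return An object of class `wl_model_spec`.
#' @export
model_spec <- function(knots = NULL,
                       covariates = c("education", "parity", "marital", "extra"),
                       interaction = TRUE,
                       origin_age_interaction = FALSE,
                       extra_levels = c("native", "foreign")) {
  if (length(covariates) > 0) {
    covariates <- match.arg(covariates, c("education", "parity", "marital", "extra"),
                            several.ok = TRUE)
  }
  if (interaction && !all(c("education", "parity") %in% covariates)) {
    interaction <- FALSE
  }
  structure(
    list(knots = knots, covariates = covariates, interaction = interaction,
         origin_age_interaction = origin_age_interaction,
         extra_levels = extra_levels),
    class = "wl_model_spec"
  )
}

# origin-dummy x age-basis interaction columns
origin_age_cols <- function(origin_block, age_block) {
  out <- matrix(0, nrow(origin_block), 0)
  for (o in colnames(origin_block)) {
    for (a in colnames(age_block)) {
      out <- cbind(out, origin_block[, o] * age_block[, a])
      colnames(out)[ncol(out)] <- paste0(o, ":", a)
    }
  }
  out
}

# indicator columns for non-reference levels of a categorical
dummy_cols <- function(x, levels, prefix) {
  out <- vapply(levels[-1], function(l) as.numeric(x == l), numeric(length(x)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(x))
  colnames(out) <- paste0(prefix, "_", gsub("\\+", "plus", levels[-1]))
  out
}

# Design matrix for transition records (or a pattern grid). `df` needs
# columns age, origin and whichever covariates the spec includes.
build_design <- function(df, spec, knots) {
  n <- nrow(df)
  blocks <- list(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  blocks$origin <- dummy_cols(df$origin, wl_transient_states(), "origin")
  blocks$age <- rcs_basis(df$age, knots)
  if (isTRUE(spec$origin_age_interaction)) {
    blocks$oa <- origin_age_cols(blocks$origin, blocks$age)
  }
  if ("education" %in% spec$covariates) {
    blocks$edu <- dummy_cols(df$education, wl_education_levels(), "edu")
  }
  if ("parity" %in% spec$covariates) {
    blocks$par <- dummy_cols(df$parity, wl_parity_levels(), "parity")
  }
  if (spec$interaction) {
    inter <- matrix(0, n, 0)
    for (e in colnames(blocks$edu)) {
      for (p in colnames(blocks$par)) {
        col <- blocks$edu[, e] * blocks$par[, p]
        inter <- cbind(inter, col)
        colnames(inter)[ncol(inter)] <- paste0(e, ":", p)
      }
    }
    blocks$inter <- inter
  }
  if ("marital" %in% spec$covariates) {
    blocks$mar <- dummy_cols(df$marital, wl_marital_levels(), "marital")
  }
  if ("extra" %in% spec$covariates) {
    blocks$extra <- dummy_cols(df$extra, spec$extra_levels, "extra")
  }
  do.call(cbind, unname(blocks))
}

#' Covariate profile for prediction
#'
#' A profile gives, for each covariate block of the model, either the
#' population proportions of its levels (for population-level estimates) or an
#' indicator concentrated on one level (for group-specific estimates). The
#' education x parity interaction cells are carried as a joint distribution,
#' by default the observed joint (from [population_profile()]) or the outer
#' product of the margins (when constructed by hand).
#'
#' @param education,parity,marital,extra Named probability vectors over the
#'   respective level sets (each summing to 1), or a single level name as
#'   shorthand for an indicator.
#' @param edu_parity Optional education x parity joint probability matrix
#'   (rows = education levels, columns = parity levels) consistent with the
#'   margins; defaults to the outer product.
#' @param extra_levels Level set of the extra covariate.
#' @return An object of class `wl_profile`.
#' @export
covariate_profile <- function(education = c(low = 1, medium = 0, high = 0),
                              parity = c("0" = 1, "1" = 0, "2" = 0, "3+" = 0),
                              marital = c(married = 1, single = 0, divorced = 0, widowed = 0),
                              extra = NULL,
                              edu_parity = NULL,
                              extra_levels = c("native", "foreign")) {
  as_dist <- function(x, levels, what) {
    if (is.character(x) && length(x) == 1) {
      x <- stats::setNames(as.numeric(levels == x), levels)
    }
    check_distribution(x, levels, what)
  }
  education <- as_dist(education, wl_education_levels(), "education")
  parity <- as_dist(parity, wl_parity_levels(), "parity")
  marital <- as_dist(marital, wl_marital_levels(), "marital")
  if (is.null(extra)) {
    extra <- stats::setNames(c(1, rep(0, length(extra_levels) - 1)), extra_levels)
  }
  extra <- as_dist(extra, extra_levels, "extra")
  if (is.null(edu_parity)) {
    edu_parity <- outer(education, parity)
  }
  if (!all(dim(edu_parity) == c(length(education), length(parity))) ||
      abs(sum(edu_parity) - 1) > 1e-12) {
    stop("edu_parity must be a joint probability matrix over education x parity",
         call. = FALSE)
  }
  dimnames(edu_parity) <- list(names(education), names(parity))
  structure(
    list(education = education, parity = parity, marital = marital,
         extra = extra, edu_parity = edu_parity, extra_levels = extra_levels),
    class = "wl_profile"
  )
}

# Design rows for prediction: one row per (age, origin) with covariate
# columns filled from the profile (proportions, so dummies take fractional
# values for population profiles; interaction columns take joint cells).
profile_design <- function(profile, ages, spec, knots) {
  origins <- wl_transient_states()
  grid <- expand.grid(origin = origins, age = ages,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  blocks <- list(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  blocks$origin <- dummy_cols(grid$origin, origins, "origin")
  blocks$age <- rcs_basis(grid$age, knots)
  if (isTRUE(spec$origin_age_interaction)) {
    blocks$oa <- origin_age_cols(blocks$origin, blocks$age)
  }
  rep_row <- function(v, prefix) {
    m <- matrix(rep(v[-1], each = n), n)
    colnames(m) <- paste0(prefix, "_", gsub("\\+", "plus", names(v)[-1]))
    m
  }
  if ("education" %in% spec$covariates) blocks$edu <- rep_row(profile$education, "edu")
  if ("parity" %in% spec$covariates) blocks$par <- rep_row(profile$parity, "parity")
  if (spec$interaction) {
    jp <- profile$edu_parity
    inter <- matrix(0, n, 0)
    for (e in rownames(jp)[-1]) {
      for (p in colnames(jp)[-1]) {
        inter <- cbind(inter, rep(jp[e, p], n))
        colnames(inter)[ncol(inter)] <- paste0(
          "edu_", e, ":parity_", gsub("\\+", "plus", p)
        )
      }
    }
    blocks$inter <- inter
  }
  if ("marital" %in% spec$covariates) blocks$mar <- rep_row(profile$marital, "marital")
  if ("extra" %in% spec$covariates) blocks$extra <- rep_row(profile$extra, "extra")
  list(X = do.call(cbind, unname(blocks)), grid = grid)
}
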