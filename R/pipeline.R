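#' Restrict a panel to an age window (and optionally a subset of persons)
#'
#' Keeps observations with ages in `[min_age, max_age]`; robustness analyses
#' (cohort-style restrictions, older-age windows) are expressed as person
#' subsets plus age windows.
#'
#' @param panel Panel tibble.
#' @param min_age,max_age Window bounds in years (inclusive).
#' @param persons Optional vector of person ids to keep.
#' @return Restricted panel.
#' @export
restrict_panel <- function(panel, min_age = -Inf, max_age = Inf, persons = NULL) {
  out <- panel[panel$age >= min_age & panel$age <= max_age, , drop = FALSE]
  if (!is.null(persons)) out <- out[out$person_id %in% persons, , drop = FALSE]
  out
}

# Precompute everything the estimation pipeline needs so that a person
# resample only re-tabulates counts and refits. See bootstrap_expectancies().
prepare_pipeline <- function(panel, spec = model_spec(), step = 1,
                             groups = c("gender", "parity"),
                             lifetable = NULL) {
  groups <- match.arg(groups, c("gender", "parity", "education"), several.ok = TRUE)
  if (!"gender" %in% groups) groups <- c("gender", groups)
  records <- build_transition_records(panel, step)
  if (nrow(records) == 0) stop("panel yields no transition records", call. = FALSE)
  knots <- spec$knots
  if (is.null(knots)) knots <- default_knots(records$age)
  spec$knots <- knots
  ages <- seq(min(records$age), max(records$age), by = step)

  cols <- c("gender", "age", "origin",
            union(spec$covariates, setdiff(groups, "gender")))
  key <- do.call(paste, c(records[cols], sep = "\r"))
  first <- !duplicated(key)
  pat_id <- match(key, key[first])
  patterns <- as.data.frame(records[first, cols, drop = FALSE])
  npat <- nrow(patterns)
  dest_id <- match(records$dest, wl_states())
  pat_dest <- pat_id + npat * (dest_id - 1L)

  genders <- sort(unique(records$gender))
  strata <- lapply(genders, function(g) {
    rows <- which(patterns$gender == g)
    list(rows = rows, X = build_design(patterns[rows, , drop = FALSE], spec, knots))
  })
  names(strata) <- genders

  # person-level bookkeeping: record rows, baseline state, cell covariates
  persons <- sort(unique(panel$person_id))
  person_rows <- split(seq_len(nrow(records)),
                       factor(records$person_id, levels = persons))
  baseline_age <- min(panel$age)
  base <- panel[panel$age == baseline_age & panel$state != "dead", , drop = FALSE]
  person_base_state <- rep(NA_integer_, length(persons))
  person_base_state[match(base$person_id, persons)] <-
    match(base$state, wl_transient_states())
  pinfo <- panel[!duplicated(panel$person_id), , drop = FALSE]
  pinfo <- pinfo[match(persons, pinfo$person_id), , drop = FALSE]

  cells <- unique(as.data.frame(records[groups], stringsAsFactors = FALSE))
  cells <- cells[do.call(order, cells), , drop = FALSE]
  rownames(cells) <- NULL

  if (!is.null(lifetable) && !is.data.frame(lifetable) && !is.list(lifetable)) {
    stop("lifetable must be a data frame or a named list of data frames",
         call. = FALSE)
  }
  list(
    spec = spec, step = step, ages = ages, groups = groups,
    patterns = patterns, npat = npat, pat_dest = pat_dest,
    strata = strata, genders = genders,
    persons = persons, person_rows = person_rows,
    person_base_state = person_base_state,
    person_gender = pinfo$gender, person_parity = pinfo$parity,
    person_education = pinfo$education,
    cells = cells, lifetable = lifetable,
    extra_levels = spec$extra_levels
  )
}

# life table for a stratum (single table or named list by gender)
stratum_lifetable <- function(lifetable, gender) {
  if (is.null(lifetable)) return(NULL)
  if (is.data.frame(lifetable)) return(lifetable)
  lifetable[[gender]] %||% stop(
    sprintf("no life table for stratum '%s'", gender), call. = FALSE
  )
}

# One full pipeline evaluation: counts -> fits -> profiles -> predictions ->
# (matching) -> expectancies. `draw` is a vector of person indices (with
# multiplicity) or NULL for the full sample.
engine_run <- function(prep, draw = NULL, se = FALSE) {
  if (is.null(draw)) {
    rec_idx <- seq_along(prep$pat_dest)
    pidx <- seq_along(prep$persons)
  } else {
    rec_idx <- unlist(prep$person_rows[draw], use.names = FALSE)
    pidx <- draw
  }
  cnt <- tabulate(prep$pat_dest[rec_idx], nbins = prep$npat * 4L)
  Y <- matrix(cnt, prep$npat, 4)

  fits <- list()
  for (g in prep$genders) {
    st <- prep$strata[[g]]
    Yg <- Y[st$rows, , drop = FALSE]
    by_origin <- rowsum(rowSums(Yg), prep$patterns$origin[st$rows])
    present <- rownames(by_origin)[by_origin[, 1] > 0]
    missing <- setdiff(wl_transient_states(), present)
    if (length(missing) > 0) {
      stop(sprintf("stratum '%s': empty origin state(s) %s",
                   g, paste(missing, collapse = ", ")), call. = FALSE)
    }
    fit <- multinom_newton(st$X, Yg, compute_se = se)
    fit$stratum <- g
    fits[[g]] <- fit
  }

  pat_n <- rowSums(Y)
  base_state <- prep$person_base_state[pidx]
  out <- vector("list", nrow(prep$cells))
  for (ci in seq_len(nrow(prep$cells))) {
    cell <- prep$cells[ci, , drop = FALSE]
    g <- cell$gender
    in_cell <- prep$patterns$gender == g
    person_in_cell <- prep$person_gender[pidx] == g
    if ("parity" %in% names(cell)) {
      in_cell <- in_cell & prep$patterns$parity == cell$parity
      person_in_cell <- person_in_cell & prep$person_parity[pidx] == cell$parity
    }
    if ("education" %in% names(cell)) {
      in_cell <- in_cell & prep$patterns$education == cell$education
      person_in_cell <- person_in_cell & prep$person_education[pidx] == cell$education
    }
    w <- pat_n * in_cell
    if (sum(w) == 0) {
      stop(sprintf("empty group cell: %s",
                   paste(unlist(cell), collapse = "/")), call. = FALSE)
    }
    profile <- profile_from_counts(prep$patterns, w, prep$extra_levels)
    bs <- base_state[person_in_cell]
    bs <- bs[!is.na(bs)]
    if (length(bs) == 0) {
      bs <- base_state[!is.na(base_state)]
      if (length(bs) == 0) stop("no baseline-age observations for radix", call. = FALSE)
    }
    radix <- tabulate(bs, nbins = 3)
    radix <- radix / sum(radix)
    P <- predict_from_coef(fits[[g]]$coefficients, profile, prep$ages,
                           prep$spec, prep$spec$knots, prep$step)
    lt <- stratum_lifetable(prep$lifetable, g)
    if (!is.null(lt)) P <- match_mortality(P, lt, radix)
    ex <- fundamental_expectancies(P, radix)
    out[[ci]] <- dplyr::bind_cols(tibble::as_tibble(cell), ex)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "fits") <- fits
  res
}

# covariate profile from pattern-level record weights; blocks absent from the
# pattern table fall back to the reference-level indicator (they carry no
# model terms in that case)
profile_from_counts <- function(patterns, w, extra_levels) {
  total <- sum(w)
  dist_of <- function(col, levels) {
    if (!col %in% names(patterns)) return(NULL)
    p <- rowsum(w, factor(patterns[[col]], levels = levels))[, 1]
    stats::setNames(p / total, levels)
  }
  args <- list(extra_levels = extra_levels)
  args$education <- dist_of("education", wl_education_levels())
  args$parity <- dist_of("parity", wl_parity_levels())
  args$marital <- dist_of("marital", wl_marital_levels())
  args$extra <- dist_of("extra", extra_levels)
  args <- args[!vapply(args, is.null, logical(1))]
  if (all(c("education", "parity") %in% names(patterns))) {
    joint <- stats::xtabs(
      w ~ factor(patterns$education, levels = wl_education_levels()) +
        factor(patterns$parity, levels = wl_parity_levels())
    )
    args$edu_parity <- unclass(joint) / total
  }
  do.call(covariate_profile, args)
}

#' Run the estimation pipeline on a panel
#'
#' End-to-end run: build person-period transition records, fit
#' gender-stratified multinomial transition models, form group covariate
#' profiles, predict age-specific transition matrices, optionally match
#' mortality to a life table, and compute state expectancies via the
#' fundamental matrix. Group radixes default to the observed baseline-age
#' state distribution within each group.
#'
#' @param panel Panel tibble.
#' @param spec A [model_spec()].
#' @param step Observation spacing in years.
#' @param groups Grouping variables among gender/parity/education (gender is
#'   always included, as models are stratified by it).
#' @param lifetable Optional life table (tibble with `age`, `qx` at the
#'   panel's step) or named list of tables by gender; when supplied, chain
#'   mortality is matched to it before expectancies are computed.
#' @param min_age,max_age Optional age-window restriction.
#' @return Tibble with one row per group cell and columns `employment`,
#'   `joblessness`, `retirement`, `total` (years). The per-stratum fits are
#'   attached as attribute `fits`.
#' @export
pipeline_expectancies <- function(panel, spec = model_spec(), step = 1,
                                  groups = c("gender", "parity"),
                                  lifetable = NULL,
                                  min_age = -Inf, max_age = Inf) {
  panel <- restrict_panel(panel, min_age, max_age)
  prep <- prepare_pipeline(panel, spec, step, groups, lifetable)
  engine_run(prep)
}
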