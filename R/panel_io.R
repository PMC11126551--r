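#' Default raw-activity-to-state mapping
#'
#' Aggregation of raw activity categories into the four analysis states:
#' unemployed, inactive, student, permanently disabled, housekeeper and
#' "other" all count as jobless; the retired state contains only retired
#' individuals.
#'
#' @return Named character vector, raw label -> state label.
#' @export
default_state_mapping <- function() {
  c(
    employed = "employed", working = "employed",
    unemployed = "jobless", inactive = "jobless", student = "jobless",
    disabled = "jobless", housekeeper = "jobless", other = "jobless",
    retired = "retired",
    dead = "dead"
  )
}

#' Recode raw activity labels into analysis states
#'
#' @param raw_labels Character vector of raw activity categories.
#' @param mapping Named vector raw label -> state (default:
#'   [default_state_mapping()]).
#' @return Character vector of states (employed/jobless/retired/dead).
#' @export
recode_states <- function(raw_labels, mapping = default_state_mapping()) {
  raw_labels <- as.character(raw_labels)
  unmapped <- setdiff(unique(raw_labels), names(mapping))
  if (length(unmapped) > 0) {
    stop(sprintf("unmapped activity label(s): %s",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  }
  out <- unname(mapping[raw_labels])
  bad <- setdiff(unique(out), wl_states())
  if (length(bad) > 0) {
    stop(sprintf("mapping targets invalid state(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out
}

#' Read / write a panel CSV
#'
#' Panel CSVs use the exact header `person_id,time,age,state,gender,parity,
#' education,marital,extra`.
#'
#' @param path File path.
#' @return A panel tibble.
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(parity = "character"))
  need <- c("person_id", "time", "age", "state", "gender", "parity",
            "education", "marital", "extra")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop(sprintf("panel file missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  df$age <- as.numeric(df$age)
  df$person_id <- as.integer(df$person_id)
  df$time <- as.integer(df$time)
  tibble::as_tibble(df[need])
}

#' @rdname read_panel
#' @param panel Panel tibble.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build person-period transition records
#'
#' One row per adjacent observation pair (t, t + step) within a person:
#' origin state and covariates at t, destination state at t + step. Pairs
#' spanning a gap (a missing intermediate wave, i.e. an age difference other
#' than `step`) are dropped, and no row originates from the absorbing state.
#'
#' @param panel Panel tibble.
#' @param step Observation spacing in years (1 or 2); must match the panel.
#' @return Tibble of transition records with attribute `step`.
#' @export
build_transition_records <- function(panel, step = 1) {
  stopifnot(step %in% c(1, 2))
  panel <- dplyr::arrange(panel, .data$person_id, .data$time)
  same <- c(panel$person_id[-1] == panel$person_id[-nrow(panel)], FALSE)
  dage <- c(diff(panel$age), NA)
  bad <- same & dage <= 0
  if (any(bad, na.rm = TRUE)) {
    stop(sprintf("non-increasing ages within person(s): %s",
                 paste(unique(panel$person_id[which(bad)]), collapse = ", ")),
         call. = FALSE)
  }
  i <- which(same & dage == step & panel$state != "dead")
  rec <- tibble::tibble(
    person_id = panel$person_id[i],
    age = panel$age[i],
    origin = panel$state[i],
    dest = panel$state[i + 1],
    gender = panel$gender[i],
    parity = panel$parity[i],
    education = panel$education[i],
    marital = panel$marital[i],
    extra = panel$extra[i]
  )
  attr(rec, "step") <- step
  rec
}

#' Read an external period life table
#'
#' Accepts a CSV with columns `age` and either `qx` (one-year death
#' probability) or `lx` (survivors at exact age, any radix). With `lx`,
#' qx(x) = 1 - l(x+1)/l(x). For a two-year step the one-year probabilities
#' are compounded: q2(x) = 1 - (1 - qx(x))(1 - qx(x+1)).
#'
#' @param path CSV file path.
#' @param step Step in years (1 or 2).
#' @return Tibble with columns `age`, `qx` (step-length death probability at
#'   each starting age).
#' @export
read_lifetable <- function(path, step = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"age" %in% names(df)) stop("life table needs an 'age' column", call. = FALSE)
  if ("qx" %in% names(df)) {
    lt <- tibble::tibble(age = df$age, qx = df$qx)
  } else if ("lx" %in% names(df)) {
    df <- df[order(df$age), ]
    if (any(diff(df$age) != 1)) {
      stop("lx life table must have contiguous single ages", call. = FALSE)
    }
    qx <- 1 - df$lx[-1] / df$lx[-nrow(df)]
    lt <- tibble::tibble(age = df$age[-nrow(df)], qx = qx)
  } else {
    stop("life table needs a 'qx' or 'lx' column", call. = FALSE)
  }
  lifetable_at_step(lt, step)
}

#' Convert a single-year life table to a given step
#'
#' @param lt Tibble with `age`, `qx` at single years of age.
#' @param step 1 or 2.
#' @return Tibble with `age`, `qx` at the requested step.
#' @export
lifetable_at_step <- function(lt, step = 1) {
  if (any(lt$qx < 0 | lt$qx > 1)) {
    stop(sprintf("qx outside [0,1] at age(s): %s",
                 paste(lt$age[lt$qx < 0 | lt$qx > 1], collapse = ", ")),
         call. = FALSE)
  }
  if (step == 1) return(tibble::as_tibble(lt[c("age", "qx")]))
  lt <- lt[order(lt$age), ]
  i <- match(lt$age + 1, lt$age)
  ok <- !is.na(i)
  tibble::tibble(
    age = lt$age[ok],
    qx = 1 - (1 - lt$qx[ok]) * (1 - lt$qx[i[ok]])
  )
}

#' Descriptive summary of a panel
#'
#' Percentages by gender within each characteristic block (parity, education,
#' marital status, extra covariate), computed over person-records (the
#' analogue of person-years / person-waves), plus the record count per gender.
#'
#' @param panel Panel tibble.
#' @return Tibble with columns `block`, `level`, one percentage column per
#'   gender, and an `n_records` attribute-style row block `N`.
#' @export
summarize_panel <- function(panel) {
  if (nrow(panel) == 0) stop("cannot summarize an empty panel", call. = FALSE)
  blocks <- c("parity", "education", "marital", "extra")
  genders <- sort(unique(panel$gender))
  out <- list()
  ntab <- table(factor(panel$gender, levels = genders))
  out[[1]] <- tibble::tibble(block = "N", level = "records",
                             !!!stats::setNames(as.list(as.numeric(ntab)), genders))
  for (b in blocks) {
    tab <- table(factor(panel$gender, levels = genders), panel[[b]])
    pct <- prop.table(tab, margin = 1) * 100
    out[[length(out) + 1]] <- tibble::tibble(
      block = b, level = colnames(pct),
      !!!stats::setNames(lapply(genders, function(g) as.numeric(pct[g, ])), genders)
    )
  }
  dplyr::bind_rows(out)
}
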