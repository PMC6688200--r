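#' Component specifications of the NU-AGE index
#'
#' The NU-AGE index scores adherence to European food-based dietary
#' guidelines for older adults with 16 components of 0-10 points each
#' (total 0-160). Most components ramp linearly from 0 points at zero
#' intake to 10 at the recommended daily amount (weekly guidelines are
#' converted to g/day, e.g. fish 2 x 125 g/week = 36 g/day). Wholegrains,
#' low-fat meat and poultry, sodium and sweets additionally penalize high
#' intakes, ramping back down to 0 at a cohort-specific cut-off: the 100th
#' percentile (maximum) for wholegrains and meat, the 85th percentile for
#' sodium and sweets, because for those "more" is not necessarily better.
#' Vitamin D supplement use and alcohol are all-or-nothing (alcohol with
#' sex-specific limits: at most 20 g/day for men, 10 g/day for women).
#'
#' Each spec gives the knots of the piecewise-linear score:
#' `lower_zero` (score 0 at/below), `lower_full` (first reaches 10),
#' `upper_full` (last 10) and `upper_zero` (back to 0), the latter two
#' possibly a percentile rule (`"p85"`, `"p100"`).
#'
#' @return A named list of component specs (one per intake column of the
#'   component table).
#' @export
nuage_components <- function() {
  ramp_up <- function(name, full, unit = "g/day") {
    list(name = name, shape = "ramp-up", lower_zero = 0, lower_full = full,
         upper_full = NA, upper_zero = NA, unit = unit)
  }
  list(
    wholegrain_g = list(
      # bread 4-6 servings/day (140-210 g) + pasta/rice 2x80 g/week (23 g/day)
      name = "wholegrain_g", shape = "ramp-up-plateau-ramp-down",
      lower_zero = 0, lower_full = 163, upper_full = 233,
      upper_zero = "p100", unit = "g/day"),
    fruit_g = ramp_up("fruit_g", 240),
    vegetables_g = ramp_up("vegetables_g", 300),
    legumes_g = ramp_up("legumes_g", 29),          # 200 g/week
    lowfat_dairy_g = ramp_up("lowfat_dairy_g", 500),
    lowfat_cheese_g = ramp_up("lowfat_cheese_g", 30),
    fish_g = ramp_up("fish_g", 36),                # 2 x 125 g/week
    lowfat_meat_poultry_g = list(
      name = "lowfat_meat_poultry_g", shape = "ramp-up-plateau-ramp-down",
      lower_zero = 0, lower_full = 71, upper_full = 125,  # 4 x 125 g/week
      upper_zero = "p100", unit = "g/day"),
    nuts_g = ramp_up("nuts_g", 6),                 # 2 x 20 g/week
    eggs_g = ramp_up("eggs_g", 14),                # 2 eggs (100 g)/week
    olive_oil_ml = ramp_up("olive_oil_ml", 20, "ml/day"),
    fluid_ml = list(
      name = "fluid_ml", shape = "ramp-up", lower_zero = 1000,
      lower_full = 1500, upper_full = NA, upper_zero = NA, unit = "ml/day"),
    vitamin_d_supplement = list(
      name = "vitamin_d_supplement", shape = "binary", lower_zero = NA,
      lower_full = NA, upper_full = NA, upper_zero = NA, unit = "yes/no"),
    alcohol_g = list(
      name = "alcohol_g", shape = "binary-by-sex",
      limit_men = 20, limit_women = 10,
      lower_zero = NA, lower_full = NA, upper_full = NA, upper_zero = NA,
      unit = "g/day"),
    sodium_mg = list(
      # salt guideline 5 g/day = 2,000 mg sodium; plateau 1,500-2,000 mg
      name = "sodium_mg", shape = "ramp-up-plateau-ramp-down",
      lower_zero = 0, lower_full = 1500, upper_full = 2000,
      upper_zero = "p85", unit = "mg/day"),
    sweets_g = list(
      name = "sweets_g", shape = "plateau-ramp-down",
      lower_zero = NA, lower_full = NA, upper_full = 0, upper_zero = "p85",
      unit = "g/day")
  )
}

#' Convert a weekly serving guideline to grams per day
#'
#' @param servings_per_week Number of servings per week.
#' @param grams_per_serving Grams in one serving.
#' @return Grams per day, rounded to the nearest integer (as the printed
#'   NU-AGE thresholds are).
#' @examples
#' weekly_to_daily(2, 125) # fish: 36 g/day
#' weekly_to_daily(4, 125) # meat: 71 g/day
#' @export
weekly_to_daily <- function(servings_per_week, grams_per_serving) {
  stopifnot(servings_per_week >= 0, grams_per_serving >= 0)
  round(servings_per_week * grams_per_serving / 7)
}

#' Resolve cohort-percentile cut-offs for the NU-AGE index
#'
#' Four components cap their score at a data-specific intake percentile:
#' wholegrains and low-fat meat/poultry at the cohort maximum (100th
#' percentile), sodium and sweets at the 85th percentile. Percentiles use
#' linear interpolation between order statistics (`stats::quantile`
#' type 7); the 100th percentile is the cohort maximum.
#'
#' @param intakes Component-intake tibble (one row per subject; columns as
#'   in [nuage_components()]).
#' @param specs Component specs, default [nuage_components()].
#' @return Named list mapping component name to its resolved numeric
#'   cut-off.
#' @export
resolve_cutoffs <- function(intakes, specs = nuage_components()) {
  if (nrow(intakes) < 2) {
    stop("Percentile cut-offs need a cohort of at least 2 subjects",
         call. = FALSE)
  }
  out <- list()
  for (sp in specs) {
    rule <- sp$upper_zero
    if (is.character(rule) && length(rule) == 1 && grepl("^p\\d+$", rule)) {
      p <- as.numeric(sub("^p", "", rule)) / 100
      x <- intakes[[sp$name]]
      if (is.null(x)) {
        stop("Component intake column missing: ", sp$name, call. = FALSE)
      }
      out[[sp$name]] <- unname(stats::quantile(x, p, type = 7, na.rm = TRUE))
    }
  }
  out
}

#' Score a single NU-AGE component
#'
#' Piecewise-linear 0-10 scoring per the component spec: 0 at/below
#' `lower_zero`, rising linearly to 10 at `lower_full`, constant through
#' `upper_full`, and (for components with an upper penalty) falling
#' linearly back to 0 at the resolved cut-off, 0 beyond. Binary components
#' score 0 or 10; alcohol compares against the sex-specific limit. The
#' result is clipped to [0, 10].
#'
#' @param intake Numeric intake (or logical for the supplement component).
#' @param spec One element of [nuage_components()].
#' @param cutoffs Resolved cut-offs from [resolve_cutoffs()] (needed only
#'   for percentile-ruled components).
#' @param sex `"men"` or `"women"` (used by the alcohol component).
#' @param upper_ramp How the upper penalty ramp is anchored:
#'   `"cutoff"` (default) runs linearly from 10 at `upper_full` to 0 at the
#'   resolved cut-off; `"footnote_c"` uses
#'   `10 - (intake - upper_full) * 10 / upper_full`, an alternative reading
#'   of the published scoring rule (still clipped to [0, 10] and 0 at/above
#'   the cut-off).
#' @param integer_points Round the score to whole points (the continuous
#'   ramp is the default).
#' @return Score in [0, 10]; vectorized over `intake` (and `sex`).
#' @examples
#' sp <- nuage_components()$fruit_g
#' component_score(c(0, 120, 240, 400), sp)
#' @export
component_score <- function(intake, spec, cutoffs = list(),
                            sex = "men",
                            upper_ramp = c("cutoff", "footnote_c"),
                            integer_points = FALSE) {
  upper_ramp <- match.arg(upper_ramp)
  n <- length(intake)
  sex <- rep_len(sex, n)

  if (spec$shape == "binary") {
    s <- ifelse(as.logical(intake), 10, 0)
    return(finish_points(s, integer_points))
  }
  if (spec$shape == "binary-by-sex") {
    lim <- ifelse(sex == "women", spec$limit_women, spec$limit_men)
    s <- ifelse(intake <= lim, 10, 0)
    return(finish_points(s, integer_points))
  }

  uz <- spec$upper_zero
  if (is.character(uz)) {
    uz <- cutoffs[[spec$name]]
    if (is.null(uz)) {
      stop("Unresolved percentile cut-off for component ", spec$name,
           "; call resolve_cutoffs() on the cohort first", call. = FALSE)
    }
  }

  s <- numeric(n)
  if (spec$shape == "plateau-ramp-down") {
    # full points at zero intake, linear penalty to 0 at the cut-off
    s <- if (uz > spec$upper_full) {
      10 * (uz - intake) / (uz - spec$upper_full)
    } else {
      ifelse(intake <= spec$upper_full, 10, 0)
    }
  } else {
    lz <- spec$lower_zero; lf <- spec$lower_full
    up <- ifelse(intake <= lz, 0,
                 ifelse(intake >= lf, 10, 10 * (intake - lz) / (lf - lz)))
    s <- up
    if (!is.na(spec$upper_full) && !is.null(uz) && !is.na(uz)) {
      uf <- spec$upper_full
      down <- if (upper_ramp == "cutoff") {
        if (uz > uf) 10 * (uz - intake) / (uz - uf) else ifelse(intake <= uf, 10, 0)
      } else {
        10 - (intake - uf) * 10 / uf
      }
      down <- ifelse(intake >= uz, 0, down)
      s <- ifelse(intake > uf, pmin(up, down), s)
    }
  }
  finish_points(pmin(pmax(s, 0), 10), integer_points)
}

finish_points <- function(s, integer_points) {
  if (integer_points) round(s) else s
}

#' NU-AGE index totals for a cohort
#'
#' Scores all 16 components for every subject and sums them into the 0-160
#' NU-AGE index. Percentile cut-offs are resolved against the cohort being
#' scored (pass `cutoffs` to freeze them, e.g. when scoring a new subject
#' against an existing cohort's distribution).
#'
#' @param intakes Component-intake tibble: `subject_id` plus the 16 intake
#'   columns named as in [nuage_components()].
#' @param subjects Subject tibble with `subject_id` and `sex`.
#' @param specs Component specs.
#' @param cutoffs Optional pre-resolved cut-offs; default resolves against
#'   `intakes`.
#' @param upper_ramp,integer_points Passed to [component_score()].
#' @return Tibble: `subject_id`, one `pts_*` column per component, and
#'   `nuage_total`.
#' @export
nuage_index <- function(intakes, subjects, specs = nuage_components(),
                        cutoffs = NULL,
                        upper_ramp = c("cutoff", "footnote_c"),
                        integer_points = FALSE) {
  upper_ramp <- match.arg(upper_ramp)
  missing_cols <- setdiff(names(specs), names(intakes))
  if (length(missing_cols) > 0) {
    stop("Component intake column(s) missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(cutoffs)) cutoffs <- resolve_cutoffs(intakes, specs)
  sex <- subjects$sex[match(intakes$subject_id, subjects$subject_id)]
  if (anyNA(sex)) {
    stop("Subjects missing for intake row(s): ",
         paste(utils::head(intakes$subject_id[is.na(sex)], 5), collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(subject_id = intakes$subject_id)
  total <- numeric(nrow(intakes))
  for (sp in specs) {
    pts <- component_score(intakes[[sp$name]], sp, cutoffs, sex,
                           upper_ramp = upper_ramp,
                           integer_points = integer_points)
    out[[paste0("pts_", sub("_(g|ml|mg)$", "", sp$name))]] <- pts
    total <- total + pts
  }
  out$nuage_total <- total
  out
}
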