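#' Energy consumed from one diet record, in 100-kcal units
#'
#' The weight used by the individual "weighted average" score: grams eaten
#' per day times the food's energy density, divided into 100-kcal units.
#'
#' @param grams_per_day Grams of the food consumed per day.
#' @param energy_kcal_100g The food's energy density, kcal per 100 g.
#' @return Number of 100-kcal units (continuous).
#' @examples
#' energy_units(150, 240) # 3.6 units
#' @export
energy_units <- function(grams_per_day, energy_kcal_100g) {
  if (any(grams_per_day < 0, na.rm = TRUE)) {
    stop("grams_per_day must be non-negative", call. = FALSE)
  }
  grams_per_day * energy_kcal_100g / 100 / 100
}

#' Individual energy-weighted diet scores
#'
#' Converts per-food scores into one score per subject: each consumed
#' food's per-100-kcal NR and LIM scores are weighted by the number of
#' 100-kcal units the subject ate of it, summed, and divided by the
#' subject's total 100-kcal units. Foods with zero energy contribute zero
#' units and therefore drop out of both numerator and denominator. DRVs are
#' taken for each subject's own sex.
#'
#' @param records Diet records: `subject_id`, `food_id`, `grams_per_day`
#'   (already averaged over recording days).
#' @param subjects Subject table with `subject_id` and `sex`.
#' @param foods Food composition tibble.
#' @param model Model name or `score_model`.
#' @param drv DRV table.
#' @param cap_lim Cap the limit panel too? Default `FALSE`.
#' @return Tibble: `subject_id`, `model`, `nr`, `lim`, `nrf`,
#'   `energy_units`, `energy_kcal`. Subjects with zero total energy get
#'   `NA` scores.
#' @export
score_diets <- function(records, subjects, foods, model,
                        drv = default_drv_table(), cap_lim = FALSE) {
  model <- resolve_model(model)
  unmatched <- setdiff(unique(records$food_id), foods$food_id)
  if (length(unmatched) > 0) {
    stop("Diet records reference unknown food_id(s): ",
         paste(utils::head(unmatched, 5), collapse = ", "),
         if (length(unmatched) > 5) ", ..." else "", call. = FALSE)
  }
  scores_by_sex <- lapply(c(men = "men", women = "women"), function(sx) {
    score_food_table(foods, model, sex = sx, drv = drv, cap_lim = cap_lim,
                     quiet = TRUE)
  })
  energy_lu <- foods$energy_kcal_100g[match(records$food_id, foods$food_id)]
  recs <- dplyr::mutate(
    records,
    units = energy_units(.data$grams_per_day, energy_lu),
    sex = subjects$sex[match(.data$subject_id, subjects$subject_id)]
  )
  per_subject <- function(sx) {
    sc <- scores_by_sex[[sx]]
    sub <- dplyr::filter(recs, .data$sex == sx)
    idx <- match(sub$food_id, sc$food_id)
    sub$nr_f <- sc$nr[idx]
    sub$lim_f <- sc$lim[idx]
    # zero-energy foods: unscoreable but carry zero units; drop from sums
    sub <- dplyr::filter(sub, .data$units > 0)
    dplyr::summarise(
      dplyr::group_by(sub, .data$subject_id),
      nr = sum(.data$units * .data$nr_f) / sum(.data$units),
      lim = sum(.data$units * .data$lim_f) / sum(.data$units),
      energy_units = sum(.data$units),
      .groups = "drop"
    )
  }
  out <- dplyr::bind_rows(per_subject("men"), per_subject("women"))
  out <- dplyr::left_join(
    dplyr::select(subjects, "subject_id"), out, by = "subject_id")
  out$energy_units[is.na(out$energy_units)] <- 0
  tibble::tibble(
    subject_id = out$subject_id, model = model$name,
    nr = out$nr, lim = out$lim, nrf = out$nr - out$lim,
    energy_units = out$energy_units,
    energy_kcal = out$energy_units * 100
  )
}

#' Exclude subjects with implausible energy intakes
#'
#' Keeps subjects whose computed daily energy intake lies in the
#' plausibility window 500–3,500 kcal (bounds inclusive; strictly below
#' 500 or strictly above 3,500 is excluded).
#'
#' @param subjects Subject tibble with an `energy_kcal` column.
#' @param lower,upper Window bounds, kcal/day.
#' @param quiet Suppress the exclusion-count message.
#' @return The retained subjects.
#' @export
exclude_implausible <- function(subjects, lower = 500, upper = 3500,
                                quiet = FALSE) {
  keep <- subjects$energy_kcal >= lower & subjects$energy_kcal <= upper
  n_out <- sum(!keep)
  if (n_out > 0 && !quiet) {
    message("Excluded ", n_out, " subject(s) with energy outside [",
            lower, ", ", upper, "] kcal")
  }
  subjects[keep, , drop = FALSE]
}

#' Mean per-100-kcal scores by food group
#'
#' Unweighted mean and sample SD of food-level scores over the distinct
#' food items in each group, with item counts — the food-group nutrient
#' density table. Unscoreable (zero-energy) foods are omitted; groups with
#' no scoreable food are dropped with a notice.
#'
#' @param food_scores Output of [score_food_table()].
#' @param quiet Suppress the empty-group notice.
#' @return Tibble: `food_group`, `n_foods`, and mean/SD of `nr`, `lim`,
#'   `nrf`.
#' @export
food_group_means <- function(food_scores, quiet = FALSE) {
  dropped <- unique(food_scores$food_group[!food_scores$scoreable])
  dropped <- setdiff(dropped, food_scores$food_group[food_scores$scoreable])
  if (length(dropped) > 0 && !quiet) {
    message("Food group(s) with no scoreable item omitted: ",
            paste(dropped, collapse = ", "))
  }
  sc <- dplyr::filter(food_scores, .data$scoreable)
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  dplyr::summarise(
    dplyr::group_by(sc, .data$food_group),
    n_foods = dplyr::n(),
    nr_mean = mean(.data$nr), nr_sd = sd0(.data$nr),
    lim_mean = mean(.data$lim), lim_sd = sd0(.data$lim),
    nrf_mean = mean(.data$nrf), nrf_sd = sd0(.data$nrf),
    .groups = "drop"
  )
}

#' Food-group contributions to individual weighted scores
#'
#' Decomposes each subject's weighted score numerator by food group:
#' contribution of group g = sum over that group's foods of
#' (100-kcal units x food NRF) divided by the subject's total weighted sum,
#' times 100. Because NRF is signed, a group's contribution can be negative
#' or exceed 100%; contributions still sum to 100% per subject whenever the
#' total is nonzero. Subjects with a zero total are flagged `undefined`.
#'
#' @inheritParams score_diets
#' @param cohort_mean If `TRUE` (default) also return the cohort-level mean
#'   contribution per group.
#' @return A list with `per_subject` (tibble `subject_id`, `food_group`,
#'   `contribution_pct`, `undefined`) and, if requested, `cohort`
#'   (`food_group`, `mean_contribution_pct`).
#' @export
group_contributions <- function(records, subjects, foods, model,
                                drv = default_drv_table(), cap_lim = FALSE,
                                cohort_mean = TRUE) {
  model <- resolve_model(model)
  scores_by_sex <- lapply(c(men = "men", women = "women"), function(sx) {
    score_food_table(foods, model, sex = sx, drv = drv, cap_lim = cap_lim,
                     quiet = TRUE)
  })
  energy_lu <- foods$energy_kcal_100g[match(records$food_id, foods$food_id)]
  group_lu <- foods$food_group[match(records$food_id, foods$food_id)]
  recs <- dplyr::mutate(
    records,
    units = energy_units(.data$grams_per_day, energy_lu),
    food_group = group_lu,
    sex = subjects$sex[match(.data$subject_id, subjects$subject_id)]
  )
  recs$nrf_f <- NA_real_
  for (sx in c("men", "women")) {
    sel <- recs$sex == sx
    recs$nrf_f[sel] <-
      scores_by_sex[[sx]]$nrf[match(recs$food_id[sel], scores_by_sex[[sx]]$food_id)]
  }
  recs <- dplyr::filter(recs, .data$units > 0)
  by_grp <- dplyr::summarise(
    dplyr::group_by(recs, .data$subject_id, .data$food_group),
    weighted = sum(.data$units * .data$nrf_f), .groups = "drop_last")
  per_subject <- dplyr::mutate(
    by_grp,
    total = sum(.data$weighted),
    undefined = .data$total == 0,
    contribution_pct = ifelse(.data$undefined, NA_real_,
                              100 * .data$weighted / .data$total)
  )
  per_subject <- dplyr::ungroup(
    dplyr::select(per_subject, "subject_id", "food_group",
                  "contribution_pct", "undefined"))
  out <- list(per_subject = per_subject)
  if (cohort_mean) {
    out$cohort <- dplyr::summarise(
      dplyr::group_by(dplyr::filter(per_subject, !.data$undefined),
                      .data$food_group),
      mean_contribution_pct = mean(.data$contribution_pct),
      .groups = "drop")
  }
  out
}
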