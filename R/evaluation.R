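#' Spearman rank correlation between a diet score and an index
#'
#' Rank correlation with average ranks for ties (the standard Spearman
#' estimator). Constant input has no defined rank correlation and returns
#' `NA` with a warning.
#'
#' @param x,y Paired numeric vectors, length >= 3.
#' @return Correlation in [-1, 1], or `NA` for degenerate input.
#' @export
spearman <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("Spearman needs at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("Spearman undefined for constant input; returning NA")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Age- and sex-adjusted regression of an index on a diet score
#'
#' Ordinary least squares of `index = b0 + b1*score + b2*age + b3*sex`
#' (women coded 1, men 0) on complete cases. Reports the unstandardized
#' slope `beta`, the standardized slope `stb = beta * SD(score)/SD(index)`,
#' and four explained-variance summaries: adjusted and raw R-squared of the
#' score-only model (`r2_score`, `r2_score_raw`) and of the full model with
#' age and sex (`r2_model`, `r2_model_raw`). The adjusted variants are the
#' headline values; both are kept because the adjustment can reorder nested
#' models.
#'
#' @param index Outcome (e.g. NU-AGE totals).
#' @param score Diet score (e.g. E-NRF7.3 individual scores).
#' @param age Age in years.
#' @param sex `"men"`/`"women"` (or a 0/1 indicator, 1 = women). Omitted
#'   from the design if constant (e.g. within a sex stratum).
#' @param model_name Label carried into the result.
#' @return One-row tibble: `model`, `n`, `mean_score`, `sd_score`,
#'   `spearman_rho`, `beta`, `stb`, `r2_score`, `r2_model`,
#'   `r2_score_raw`, `r2_model_raw`.
#' @export
adjusted_regression <- function(index, score, age, sex, model_name = "score") {
  sex_num <- code_sex(sex)
  ok <- stats::complete.cases(index, score, age, sex_num)
  index <- index[ok]; score <- score[ok]; age <- age[ok]; sex_num <- sex_num[ok]
  n <- length(index)
  if (n < 4) stop("adjusted_regression needs at least 4 complete cases", call. = FALSE)

  covars <- list(age = age)
  if (stats::sd(sex_num) > 0) covars$sex <- sex_num
  covars <- Filter(function(v) stats::sd(v) > 0, covars)
  dat <- data.frame(index = index, score = score, covars)

  fit_full <- stats::lm(index ~ ., data = dat)
  if (fit_full$rank < ncol(dat)) {
    stop("Rank-deficient design in adjusted regression", call. = FALSE)
  }
  fit_score <- stats::lm(index ~ score, data = dat)
  # summary.lm warns on an exactly collinear ("perfect") fit; the R2 of 1 it
  # reports is what we want there
  s_full <- suppressWarnings(summary(fit_full))
  s_score <- suppressWarnings(summary(fit_score))
  beta <- unname(stats::coef(fit_full)["score"])
  tibble::tibble(
    model = model_name, n = n,
    mean_score = mean(score), sd_score = stats::sd(score),
    spearman_rho = spearman(score, index),
    beta = beta,
    stb = beta * stats::sd(score) / stats::sd(index),
    r2_score = s_score$adj.r.squared,
    r2_model = s_full$adj.r.squared,
    r2_score_raw = s_score$r.squared,
    r2_model_raw = s_full$r.squared
  )
}

code_sex <- function(sex) {
  if (is.numeric(sex)) return(as.numeric(sex))
  if (is.logical(sex)) return(as.numeric(sex))
  as.numeric(sex == "women")
}

#' Evaluate score models against the NU-AGE index
#'
#' Runs [adjusted_regression()] of the NU-AGE total on each requested
#' E-NRF variant in turn, producing the model-comparison table (one row
#' per model: mean, SD, Spearman's rho, beta, STB, score and model
#' R-squared).
#'
#' @param scores Tibble of individual scores with `subject_id`, `model`,
#'   `nrf` (long format over models), or a single model's scores.
#' @param nuage Tibble with `subject_id`, `nuage_total`.
#' @param subjects Tibble with `subject_id`, `sex`, `age`.
#' @param models Character vector of model names to evaluate; default all
#'   models present in `scores`.
#' @return Tibble with one row per model.
#' @export
evaluate_models <- function(scores, nuage, subjects, models = NULL) {
  if (is.null(models)) models <- unique(scores$model)
  idx <- nuage$nuage_total[match(subjects$subject_id, nuage$subject_id)]
  registry <- enrf_models()
  rows <- lapply(models, function(m) {
    sc <- scores[scores$model == m, ]
    # limit-only models (LIM3) are reported on the positive LIM scale
    lim_only <- m %in% names(registry) &&
      length(registry[[m]]$encourage) == 0
    v <- if (lim_only) sc$lim else sc$nrf
    s <- v[match(subjects$subject_id, sc$subject_id)]
    adjusted_regression(idx, s, subjects$age, subjects$sex, model_name = m)
  })
  dplyr::bind_rows(rows)
}

#' Sensitivity splits of the evaluation
#'
#' Re-runs the adjusted regression within strata: men vs. women (sex
#' dropped from the covariates), BMI at/below vs. above the cohort median,
#' and energy intake at/below vs. above the cohort median. Medians are
#' computed within the analyzed cohort; ties go to the lower stratum.
#' Strata with 4 or fewer subjects are skipped with a notice.
#'
#' @param scores Individual-score tibble for one model (`subject_id`,
#'   `nrf`).
#' @param nuage Tibble with `subject_id`, `nuage_total`.
#' @param subjects Tibble with `subject_id`, `sex`, `age`, `bmi`,
#'   `energy_kcal`.
#' @param model_name Label for the output.
#' @param quiet Suppress skip notices.
#' @return Tibble of [adjusted_regression()] rows with `stratifier` and
#'   `stratum` columns.
#' @export
sensitivity_splits <- function(scores, nuage, subjects, model_name = "score",
                               quiet = FALSE) {
  s <- scores$nrf[match(subjects$subject_id, scores$subject_id)]
  idx <- nuage$nuage_total[match(subjects$subject_id, nuage$subject_id)]
  med_bmi <- stats::median(subjects$bmi, na.rm = TRUE)
  med_energy <- stats::median(subjects$energy_kcal, na.rm = TRUE)
  strata <- list(
    list("sex", "men", subjects$sex == "men"),
    list("sex", "women", subjects$sex == "women"),
    list("bmi", paste0("<= ", round(med_bmi, 1)), subjects$bmi <= med_bmi),
    list("bmi", paste0("> ", round(med_bmi, 1)), subjects$bmi > med_bmi),
    list("energy", paste0("<= ", round(med_energy)), subjects$energy_kcal <= med_energy),
    list("energy", paste0("> ", round(med_energy)), subjects$energy_kcal > med_energy)
  )
  rows <- list()
  for (st in strata) {
    keep <- which(st[[3]])
    if (length(keep) <= 4) {
      if (!quiet) message("Stratum ", st[[1]], " ", st[[2]],
                          " skipped (n = ", length(keep), ")")
      next
    }
    r <- adjusted_regression(idx[keep], s[keep], subjects$age[keep],
                             subjects$sex[keep], model_name = model_name)
    r$stratifier <- st[[1]]
    r$stratum <- st[[2]]
    rows[[length(rows) + 1]] <- r
  }
  dplyr::bind_rows(rows)
}
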