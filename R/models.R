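#' Registry of E-NRF score models
#'
#' The E-NRF family was built stepwise: every positive model contains
#' protein, dietary fiber, vitamin D, folate and calcium; single candidate
#' micronutrients (zinc, iodine, vitamin E, vitamin C, selenium, vitamin
#' B12, vitamin B6, iron, magnesium, potassium) are added one at a time;
#' E-NR7 adds both magnesium and potassium, and E-NR8 additionally PUFA.
#' Each positive model has a "full" counterpart (E-NRF*n*.3) that subtracts
#' the LIM3 sub-score over the three nutrients to limit: saturated fat,
#' total mono- and disaccharides (sugar), and sodium. Together with the
#' bare LIM3 model this gives 27 registered models.
#'
#' @return A named list of score models. Each model is a list with elements
#'   `name`, `encourage`, `limit` (character vectors of canonical nutrient
#'   names) and `cap_percent` (the percent-of-DRV ceiling, default 100).
#' @examples
#' names(enrf_models())
#' enrf_models()[["E-NRF7.3"]]$encourage
#' @export
enrf_models <- function() {
  base5 <- c("protein", "fiber", "vitamin_d", "folate", "calcium")
  lim3 <- c("saturated_fat", "sugar", "sodium")
  add6 <- c(
    Zn = "zinc", I = "iodine", VitE = "vitamin_e", VitC = "vitamin_c",
    Se = "selenium", B12 = "vitamin_b12", B6 = "vitamin_b6", Fe = "iron",
    Mg = "magnesium", K = "potassium"
  )

  models <- list()
  models[["LIM3"]] <- new_score_model("LIM3", character(0), lim3)
  models[["E-NR5"]] <- new_score_model("E-NR5", base5, character(0))
  for (tag in names(add6)) {
    nm <- paste0("E-NR6-", tag)
    models[[nm]] <- new_score_model(nm, c(base5, add6[[tag]]), character(0))
  }
  models[["E-NR7"]] <- new_score_model(
    "E-NR7", c(base5, "potassium", "magnesium"), character(0))
  models[["E-NR8"]] <- new_score_model(
    "E-NR8", c(base5, "pufa", "potassium", "magnesium"), character(0))

  models[["E-NRF5.3"]] <- new_score_model("E-NRF5.3", base5, lim3)
  for (tag in names(add6)) {
    nm <- paste0("E-NRF6.3-", tag)
    models[[nm]] <- new_score_model(nm, c(base5, add6[[tag]]), lim3)
  }
  models[["E-NRF7.3"]] <- new_score_model(
    "E-NRF7.3", c(base5, "potassium", "magnesium"), lim3)
  models[["E-NRF8.3"]] <- new_score_model(
    "E-NRF8.3", c(base5, "pufa", "potassium", "magnesium"), lim3)
  models
}

#' Construct a score model
#'
#' A score model is a panel of nutrients to encourage plus a panel of
#' nutrients to limit, with a percent-of-DRV cap for the encourage side.
#' User-defined panels may use any nutrient present in the DRV table,
#' including the Table-2 nutrients that no bundled model uses (vitamin A,
#' B1, B2, copper).
#'
#' @param name Model label.
#' @param encourage Character vector of nutrients to encourage (may be
#'   empty, as in LIM3).
#' @param limit Character vector of nutrients to limit (may be empty, as in
#'   the positive-only models).
#' @param cap_percent Ceiling on each encouraged nutrient's percent of DRV
#'   per 100 kcal; default 100.
#' @return A `score_model` list.
#' @export
new_score_model <- function(name, encourage, limit, cap_percent = 100) {
  stopifnot(is.character(name), length(name) == 1, cap_percent > 0)
  encourage <- normalize_nutrient(encourage)
  limit <- normalize_nutrient(limit)
  if (length(encourage) == 0 && length(limit) == 0) {
    stop("A score model needs at least one nutrient in a panel", call. = FALSE)
  }
  structure(
    list(name = name, encourage = encourage, limit = limit,
         cap_percent = cap_percent),
    class = "score_model"
  )
}

#' Resolve a model argument to a score model object
#'
#' @param model A model name from [enrf_models()] or a `score_model` object.
#' @return A `score_model`.
#' @export
resolve_model <- function(model) {
  if (inherits(model, "score_model")) return(model)
  registry <- enrf_models()
  if (is.character(model) && length(model) == 1 && model %in% names(registry)) {
    return(registry[[model]])
  }
  stop("Unknown score model: ", paste(model, collapse = ", "),
       "; see names(enrf_models())", call. = FALSE)
}

#' @export
print.score_model <- function(x, ...) {
  cat("<score_model> ", x$name, "\n",
      "  encourage (", length(x$encourage), "): ",
      paste(x$encourage, collapse = ", "), "\n",
      "  limit (", length(x$limit), "): ",
      paste(x$limit, collapse = ", "), "\n",
      "  cap: ", x$cap_percent, "% DRV\n", sep = "")
  invisible(x)
}
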