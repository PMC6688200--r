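#' Rescale a food's nutrient vector to a 100-kcal basis
#'
#' All E-NRF scoring is done per 100 kcal of the edible portion, so a food's
#' nutrient contents per 100 g are multiplied by `100 / energy`. Foods with
#' zero energy (water, black coffee, trace-use herbs) have no defined
#' per-100-kcal composition; they raise an error here and are flagged (not
#' scored) by the table-level functions.
#'
#' @param nutrients Named numeric vector or one-row data frame of nutrient
#'   amounts per 100 g.
#' @param energy Energy density, kcal per 100 g.
#' @return Numeric vector of amounts per 100 kcal.
#' @examples
#' per100kcal(c(protein = 10, fiber = 2), energy = 200)
#' @export
per100kcal <- function(nutrients, energy) {
  stopifnot(length(energy) == 1)
  if (is.data.frame(nutrients)) nutrients <- unlist(nutrients[1, ])
  if (energy <= 0) {
    stop("per-100-kcal composition undefined for a food with energy <= 0 kcal",
         call. = FALSE)
  }
  nutrients * 100 / energy
}

#' Percent of DRV, capped
#'
#' The building block of the NR sub-score: a nutrient amount per 100 kcal is
#' expressed as a percent of its daily reference value and truncated at the
#' cap (100% by default) so that a single heavily fortified nutrient cannot
#' dominate the food's score.
#'
#' @param amount Amount of the nutrient per 100 kcal.
#' @param drv The daily reference value (same unit as `amount`), > 0.
#' @param cap Percent ceiling, > 0. Use `Inf` for uncapped.
#' @return Percent in `[0, cap]`.
#' @export
capped_percent_drv <- function(amount, drv, cap = 100) {
  if (any(drv <= 0)) stop("DRV must be positive", call. = FALSE)
  if (any(cap <= 0)) stop("cap must be positive", call. = FALSE)
  pmin(100 * amount / drv, cap)
}

# Extract the per-100-kcal amounts of `panel` from a one-row food, treating
# absent nutrient columns as 0 (sparse composition tables are the norm).
panel_amounts_100kcal <- function(food, panel) {
  energy <- food$energy_kcal_100g
  amounts <- vapply(panel, function(nu) {
    col <- paste0("nutrient_", nu)
    v <- if (col %in% names(food)) food[[col]] else NA_real_
    if (is.na(v)) 0 else v
  }, numeric(1))
  amounts * 100 / energy
}

#' Nutrient-rich (NR), LIM and NRF sub-scores of a single food
#'
#' `nr_score()` sums the capped percent-of-DRV over the model's encourage
#' panel, per 100 kcal, with all nutrients equally weighted. `lim_score()`
#' sums the (by default uncapped) percent of the maximum daily value over
#' the three nutrients to limit. `nrf_score()` returns all three values
#' with `nrf = nr - lim`.
#'
#' @param food A one-row food tibble as produced by [simulate_food_table()]
#'   or [read_food_table()]: columns `food_id`, `name`, `food_group`,
#'   `energy_kcal_100g` and `nutrient_*` amounts per 100 g.
#' @param model A model name or `score_model` (see [enrf_models()]).
#' @param sex `"men"` or `"women"`: which DRV column to use.
#' @param drv DRV table (default bundled).
#' @param cap_lim If `TRUE`, apply the same percent cap to the limit panel;
#'   the default leaves LIM uncapped.
#' @return `nr_score()`/`lim_score()`: a single number of points.
#'   `nrf_score()`: a one-row tibble `food_id`, `model`, `nr`, `lim`, `nrf`.
#' @examples
#' foods <- simulate_food_table(sim_config(seed = 1))
#' nrf_score(foods[3, ], "E-NRF7.3", sex = "men")
#' @export
nr_score <- function(food, model, sex = c("men", "women"),
                     drv = default_drv_table()) {
  sex <- match.arg(sex)
  model <- resolve_model(model)
  if (length(model$encourage) == 0) return(0)
  amounts <- panel_amounts_100kcal(food, model$encourage)
  drvs <- get_drv(model$encourage, sex, drv)
  sum(capped_percent_drv(amounts, drvs, model$cap_percent))
}

#' @rdname nr_score
#' @export
lim_score <- function(food, model = "LIM3", sex = c("men", "women"),
                      drv = default_drv_table(), cap_lim = FALSE) {
  sex <- match.arg(sex)
  model <- resolve_model(model)
  if (length(model$limit) == 0) return(0)
  amounts <- panel_amounts_100kcal(food, model$limit)
  drvs <- get_drv(model$limit, sex, drv)
  cap <- if (cap_lim) model$cap_percent else Inf
  sum(capped_percent_drv(amounts, drvs, cap))
}

#' @rdname nr_score
#' @export
nrf_score <- function(food, model, sex = c("men", "women"),
                      drv = default_drv_table(), cap_lim = FALSE) {
  sex <- match.arg(sex)
  model <- resolve_model(model)
  nr <- nr_score(food, model, sex, drv)
  lim <- lim_score(food, model, sex, drv, cap_lim = cap_lim)
  tibble::tibble(food_id = food$food_id, model = model$name,
                 nr = nr, lim = lim, nrf = nr - lim)
}

#' Score a whole food table
#'
#' Vectorized scoring of every food in a composition table, per 100 kcal.
#' Foods with zero (or missing) energy cannot be expressed per 100 kcal;
#' their score columns are `NA` and `scoreable` is `FALSE`. Missing
#' nutrient cells count as 0 (with a one-line message reporting how many).
#'
#' @param foods Food tibble (see [nr_score()] for the schema).
#' @param model Model name or `score_model`.
#' @param sex Reference sex for the DRVs; food-level tables default to
#'   `"men"`. Individual-level scoring uses each subject's own sex instead.
#' @param drv DRV table.
#' @param cap_lim Cap the limit panel too? Default `FALSE`.
#' @param quiet Suppress the missing-cell message.
#' @return A tibble: `food_id`, `food_group`, `model`, `nr`, `lim`, `nrf`,
#'   `scoreable`, in input order.
#' @export
score_food_table <- function(foods, model, sex = c("men", "women"),
                             drv = default_drv_table(), cap_lim = FALSE,
                             quiet = FALSE) {
  sex <- match.arg(sex)
  model <- resolve_model(model)
  if (nrow(foods) == 0) {
    return(tibble::tibble(food_id = character(0), food_group = character(0),
                          model = character(0), nr = numeric(0),
                          lim = numeric(0), nrf = numeric(0),
                          scoreable = logical(0)))
  }
  panel_all <- c(model$encourage, model$limit)
  cols <- paste0("nutrient_", panel_all)
  mat <- matrix(0, nrow = nrow(foods), ncol = length(panel_all),
                dimnames = list(NULL, panel_all))
  n_missing <- 0L
  for (j in seq_along(panel_all)) {
    if (cols[j] %in% names(foods)) {
      v <- foods[[cols[j]]]
      n_missing <- n_missing + sum(is.na(v))
      v[is.na(v)] <- 0
      mat[, j] <- v
    } else {
      n_missing <- n_missing + nrow(foods)
    }
  }
  if (n_missing > 0 && !quiet) {
    message(n_missing, " missing nutrient cell(s) treated as 0")
  }
  energy <- foods$energy_kcal_100g
  scoreable <- !is.na(energy) & energy > 0
  pct <- mat * NA_real_
  pct[scoreable, ] <- mat[scoreable, , drop = FALSE] * (100 / energy[scoreable])
  drv_enc <- if (length(model$encourage)) get_drv(model$encourage, sex, drv) else numeric(0)
  drv_lim <- if (length(model$limit)) get_drv(model$limit, sex, drv) else numeric(0)

  nr <- rep(0, nrow(foods))
  if (length(model$encourage)) {
    enc <- sweep(pct[, model$encourage, drop = FALSE], 2, drv_enc, "/") * 100
    enc <- pmin(enc, model$cap_percent)
    nr <- rowSums(enc)
  }
  lim <- rep(0, nrow(foods))
  if (length(model$limit)) {
    lm_ <- sweep(pct[, model$limit, drop = FALSE], 2, drv_lim, "/") * 100
    if (cap_lim) lm_ <- pmin(lm_, model$cap_percent)
    lim <- rowSums(lm_)
  }
  nr[!scoreable] <- NA_real_
  lim[!scoreable] <- NA_real_
  tibble::tibble(
    food_id = foods$food_id,
    food_group = if ("food_group" %in% names(foods)) foods$food_group else NA_character_,
    model = model$name, nr = nr, lim = lim, nrf = nr - lim,
    scoreable = scoreable
  )
}
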