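#' Dietary reference values for older adults
#'
#' The package bundles a table of daily reference values (DRVs) for the 23
#' nutrients used by the E-NRF score family: 20 nutrient-rich components to
#' encourage and 3 nutrients to limit (saturated fat, total mono- and
#' disaccharides, sodium). Values are sex-specific where the underlying
#' recommendations are (protein, fiber, and several micronutrients); entries
#' such as calcium (1,200 mg) are identical for men and women. Sources mix
#' EFSA population reference intakes, the Nordic Nutrition Recommendations,
#' Health Council of the Netherlands advice, and EFSA labeling reference
#' values for the nutrients to limit.
#'
#' The table is stored as an editable CSV (`system.file("extdata", "drv.csv",
#' package = "enrf")`) so an alternative reference system can be swapped in;
#' `read_drv_table()` validates any user-supplied file against the same
#' schema.
#'
#' @param path Path to a DRV CSV with columns `nutrient`, `unit`,
#'   `value_men`, `value_women`, `role`, `source`. Defaults to the bundled
#'   table.
#' @return A tibble with one row per nutrient.
#' @examples
#' drv <- default_drv_table()
#' get_drv("calcium", "men", drv)
#' @export
default_drv_table <- function() {
  read_drv_table(system.file("extdata", "drv.csv", package = "enrf"))
}

#' @rdname default_drv_table
#' @export
read_drv_table <- function(path) {
  if (!file.exists(path)) {
    stop("DRV file not found: ", path, call. = FALSE)
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("nutrient", "unit", "value_men", "value_women", "role", "source")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("DRV table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab$nutrient <- normalize_nutrient(tab$nutrient)
  if (anyDuplicated(tab$nutrient)) {
    stop("DRV table has duplicated nutrient entries", call. = FALSE)
  }
  if (!all(tab$role %in% c("encourage", "limit"))) {
    stop("DRV role must be 'encourage' or 'limit'", call. = FALSE)
  }
  if (any(tab$value_men <= 0) || any(tab$value_women <= 0)) {
    stop("DRV values must be strictly positive", call. = FALSE)
  }
  tibble::as_tibble(tab)
}

#' Look up a sex-specific dietary reference value
#'
#' @param nutrient Canonical nutrient name (see [normalize_nutrient()]).
#' @param sex `"men"` or `"women"`.
#' @param drv A DRV table, by default the bundled one.
#' @return The daily reference amount, in the table's unit for that nutrient.
#' @examples
#' get_drv("vitamin_d", "women")
#' @export
get_drv <- function(nutrient, sex = c("men", "women"), drv = default_drv_table()) {
  sex <- match.arg(sex)
  nutrient <- normalize_nutrient(nutrient)
  idx <- match(nutrient, drv$nutrient)
  if (anyNA(idx)) {
    stop("Unknown nutrient in DRV lookup: ",
         paste(nutrient[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  col <- if (sex == "men") "value_men" else "value_women"
  drv[[col]][idx]
}

#' Derive a DRV from an energy-percent recommendation
#'
#' Macronutrient reference values expressed as a share of energy intake
#' (protein at 18 energy percent, PUFA at 8 energy percent) are converted to
#' grams per day against a reference energy intake (2,500 kcal for men,
#' 2,000 kcal for women) using the Atwater density of the macronutrient
#' (4 kcal/g for protein and carbohydrate, 9 kcal/g for fat).
#'
#' @param energy_percent Fraction of energy (e.g. `0.18`), in (0, 1).
#' @param reference_energy Reference daily energy intake, kcal/day.
#' @param energy_density kcal per gram of the macronutrient (4 or 9).
#' @return Grams per day, rounded to 1 decimal.
#' @examples
#' drv_from_energy_percent(0.18, 2500, 4) # protein, men: 112.5 g
#' drv_from_energy_percent(0.08, 2000, 9) # PUFA, women: 17.8 g
#' @export
drv_from_energy_percent <- function(energy_percent, reference_energy, energy_density) {
  stopifnot(length(energy_percent) == 1, length(reference_energy) == 1,
            length(energy_density) == 1)
  if (energy_percent <= 0 || energy_percent >= 1) {
    stop("energy_percent must lie strictly between 0 and 1", call. = FALSE)
  }
  if (reference_energy <= 0) {
    stop("reference_energy must be positive", call. = FALSE)
  }
  if (!energy_density %in% c(4, 9)) {
    stop("energy_density must be 4 (protein/carbohydrate) or 9 (fat) kcal/g",
         call. = FALSE)
  }
  round(energy_percent * reference_energy / energy_density, 1)
}

#' Convert a salt reference value to sodium
#'
#' Salt (NaCl) recommendations in g/day are converted to mg sodium with the
#' conventional factor 2.5 g salt per g sodium.
#'
#' @param salt Salt intake or reference, g/day (non-negative).
#' @return Sodium, mg/day.
#' @examples
#' sodium_from_salt(6) # 2400 mg, the labeling reference value
#' sodium_from_salt(5) # 2000 mg, the NU-AGE guideline
#' @export
sodium_from_salt <- function(salt) {
  if (any(salt < 0)) stop("salt must be non-negative", call. = FALSE)
  salt * 1000 / 2.5
}

#' @rdname sodium_from_salt
#' @param sodium Sodium, mg/day.
#' @export
salt_from_sodium <- function(sodium) {
  if (any(sodium < 0)) stop("sodium must be non-negative", call. = FALSE)
  sodium * 2.5 / 1000
}

#' Derive a DRV from a per-1,000-kcal recommendation
#'
#' Vitamin B1 is recommended at 0.4 mg per 1,000 kcal; against the 2,500 and
#' 2,000 kcal reference intakes this gives 1.0 mg (men) and 0.8 mg (women).
#'
#' @param rate mg per 1,000 kcal (non-negative).
#' @param reference_energy Reference daily energy intake, kcal/day.
#' @return mg per day, rounded to 1 decimal.
#' @export
drv_per_1000kcal <- function(rate, reference_energy) {
  if (any(rate < 0)) stop("rate must be non-negative", call. = FALSE)
  if (any(reference_energy <= 0)) {
    stop("reference_energy must be positive", call. = FALSE)
  }
  round(rate * reference_energy / 1000, 1)
}

#' Normalize nutrient names to the canonical vocabulary
#'
#' Food composition tables label the same nutrient in many ways; internal
#' code uses one lower-case ASCII name per nutrient. Recognized synonyms
#' (e.g. `"folate equivalents"`, `"dietary fiber"`, `"total mono- and
#' disaccharides"`) map onto the canonical names; any other string is
#' lower-cased with spaces and hyphens turned into underscores.
#'
#' @param x Character vector of nutrient labels.
#' @return Character vector of canonical names.
#' @examples
#' normalize_nutrient(c("Dietary fiber", "Folate equivalents", "Na"))
#' @export
normalize_nutrient <- function(x) {
  key <- tolower(trimws(as.character(x)))
  key <- gsub("[ -]+", "_", key)
  key <- gsub("[^a-z0-9_]", "", key)
  synonyms <- c(
    dietary_fiber = "fiber", fibre = "fiber", dietary_fibre = "fiber",
    folate_equivalents = "folate", folic_acid = "folate",
    total_mono_and_disaccharides = "sugar",
    mono_and_disaccharides = "sugar", total_sugars = "sugar",
    saturated_fatty_acids = "saturated_fat", sfa = "saturated_fat",
    polyunsaturated_fatty_acids = "pufa",
    polyunsaturated_fat = "pufa",
    na = "sodium", salt = "sodium",
    ca = "calcium", k = "potassium", mg = "magnesium", fe = "iron",
    zn = "zinc", se = "selenium", i = "iodine", cu = "copper",
    thiamin = "vitamin_b1", riboflavin = "vitamin_b2",
    cobalamin = "vitamin_b12", ascorbic_acid = "vitamin_c",
    tocopherol = "vitamin_e", retinol_equivalents = "vitamin_a"
  )
  hit <- match(key, names(synonyms))
  key[!is.na(hit)] <- synonyms[hit[!is.na(hit)]]
  key
}
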