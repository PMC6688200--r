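#' Read a food-composition CSV
#'
#' Expected schema: `food_id`, `name` (optional), `food_group` (optional),
#' `energy_kcal_100g`, then one column per nutrient using canonical names
#' with a unit suffix (`protein_g`, `vitamin_d_ug`, `sodium_mg`, ...) or
#' already-prefixed `nutrient_*` columns. Unit suffixes are stripped after
#' validation; unknown nutrient columns are dropped with a warning; missing
#' cells become 0 (warned, counted). The CSV dialect is fixed: comma
#' separator, dot decimal, UTF-8, header required — files with European
#' decimal commas are rejected with an actionable message.
#'
#' @param path Path to the CSV.
#' @return Food tibble in the internal schema (`nutrient_*` per 100 g).
#' @export
read_food_table <- function(path) {
  tab <- read_strict_csv(path)
  mandatory <- c("food_id", "energy_kcal_100g")
  missing <- setdiff(mandatory, names(tab))
  if (length(missing) > 0) {
    stop("Food table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  known_units <- c("g", "mg", "ug")
  out <- tibble::tibble(food_id = as.character(tab$food_id))
  out$name <- if ("name" %in% names(tab)) tab$name else out$food_id
  out$food_group <- if ("food_group" %in% names(tab)) tab$food_group else NA_character_
  out$energy_kcal_100g <- as.numeric(tab$energy_kcal_100g)
  drv_nutrients <- default_drv_table()$nutrient
  other <- setdiff(names(tab), c("food_id", "name", "food_group", "energy_kcal_100g"))
  n_na <- 0L
  for (col in other) {
    if (grepl("^nutrient_", col)) {
      nu <- sub("^nutrient_", "", col)
    } else {
      m <- regmatches(col, regexec(paste0("^(.*)_(", paste(known_units, collapse = "|"), ")$"), col))[[1]]
      nu <- if (length(m) == 3) normalize_nutrient(m[2]) else NA_character_
    }
    if (is.na(nu) || !nu %in% drv_nutrients) {
      warning("Unknown nutrient column dropped: ", col, call. = FALSE)
      next
    }
    v <- as.numeric(tab[[col]])
    n_na <- n_na + sum(is.na(v))
    v[is.na(v)] <- 0
    out[[paste0("nutrient_", nu)]] <- v
  }
  if (n_na > 0) {
    warning(n_na, " missing nutrient cell(s) set to 0", call. = FALSE)
  }
  out
}

#' @rdname read_food_table
#' @export
read_diet_records <- function(path) {
  tab <- read_strict_csv(path)
  need <- c("subject_id", "food_id", "grams_per_day")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("Diet records missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(subject_id = as.character(tab$subject_id),
                 food_id = as.character(tab$food_id),
                 grams_per_day = as.numeric(tab$grams_per_day))
}

#' @rdname read_food_table
#' @export
read_subjects <- function(path) {
  tab <- read_strict_csv(path)
  need <- c("subject_id", "sex")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("Subject table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(tab$sex %in% c("men", "women"))) {
    stop("Subject sex must be 'men' or 'women'", call. = FALSE)
  }
  tibble::as_tibble(tab)
}

#' @rdname read_food_table
#' @export
read_component_intakes <- function(path) {
  tab <- read_strict_csv(path)
  need <- c("subject_id", names(nuage_components()))
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("Component intake table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(tab)
}

# Strict comma/dot CSV reader shared by all inputs.
read_strict_csv <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  header <- readLines(path, n = 2, encoding = "UTF-8")
  if (length(header) < 1 || !grepl(",", header[1])) {
    stop("Expected a comma-separated file with a header row: ", path,
         call. = FALSE)
  }
  if (length(header) == 2 && grepl("\"?\\d+,\\d+\"?(;|$)", header[2]) &&
      grepl(";", header[2])) {
    stop("File appears to use European decimal commas with ';' separators; ",
         "please export with ',' separators and '.' decimals: ", path,
         call. = FALSE)
  }
  # quoted fields like "100,5" would otherwise be silently read as grouped
  # numbers; inspect the raw text first
  head_lines <- readLines(path, n = 100, encoding = "UTF-8")
  if (any(grepl("\"-?[0-9]+,[0-9]+\"", head_lines[-1]))) {
    stop("File contains European decimal commas (e.g. \"100,5\"); re-export ",
         "it with '.' as the decimal mark and ',' as the separator: ", path,
         call. = FALSE)
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  dec_comma <- vapply(tab, function(col) {
    is.character(col) && any(grepl("^-?\\d+,\\d+$", col), na.rm = TRUE)
  }, logical(1))
  if (any(dec_comma)) {
    stop("Column(s) ", paste(names(tab)[dec_comma], collapse = ", "),
         " contain European decimal commas (e.g. '1,5'); re-export the file ",
         "with '.' as the decimal mark", call. = FALSE)
  }
  tab
}

#' Write a results table, rounded for reading and exact for machines
#'
#' Writes `path` with numeric columns rounded to `precision` decimals
#' (1 by default, matching the reporting convention) and a companion
#' `<path stem>_full.csv` at full precision.
#'
#' @param results Non-empty data frame.
#' @param path Output CSV path.
#' @param precision Decimals for the rounded file.
#' @return Invisibly, the path written.
#' @export
write_report <- function(results, path, precision = 1) {
  if (is.null(results) || nrow(results) == 0) {
    stop("Refusing to write an empty results table", call. = FALSE)
  }
  rounded <- results
  num <- vapply(rounded, is.numeric, logical(1))
  rounded[num] <- lapply(rounded[num], round, digits = precision)
  readr::write_csv(rounded, path, progress = FALSE)
  full_path <- sub("(\\.csv)?$", "_full.csv", path)
  readr::write_csv(results, full_path, progress = FALSE)
  invisible(path)
}
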