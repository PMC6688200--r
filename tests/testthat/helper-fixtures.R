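# Hand-built fixtures used across test files.

# One-row food tibble in the internal schema; nutrients are per 100 g.
make_food <- function(food_id = "f1", food_group = "Vegetables",
                      energy = 100, ...) {
  nutrients <- list(...)
  out <- tibble::tibble(food_id = food_id, name = food_id,
                        food_group = food_group, energy_kcal_100g = energy)
  for (nm in names(nutrients)) {
    out[[paste0("nutrient_", nm)]] <- nutrients[[nm]]
  }
  out
}

# A food whose encourage-panel nutrients sit at `frac` x DRV per 100 kcal
# (per 100 g too, since energy = 100 kcal/100 g).
food_at_drv_fraction <- function(model = "E-NRF7.3", sex = "men", frac = 1,
                                 food_id = "fx") {
  m <- resolve_model(model)
  drv <- default_drv_table()
  args <- as.list(get_drv(m$encourage, sex, drv) * frac)
  names(args) <- m$encourage
  do.call(make_food, c(list(food_id = food_id, energy = 100), args))
}

# Random small food table covering several nutrients, seeded.
random_foods <- function(n = 20, seed = 1) {
  set.seed(seed)
  nutrients <- c("protein", "fiber", "vitamin_d", "folate", "calcium",
                 "potassium", "magnesium", "pufa", "zinc", "vitamin_c",
                 "saturated_fat", "sugar", "sodium")
  out <- tibble::tibble(
    food_id = sprintf("rf%03d", seq_len(n)),
    name = sprintf("rf%03d", seq_len(n)),
    food_group = sample(food_groups(), n, replace = TRUE),
    energy_kcal_100g = stats::runif(n, 20, 600)
  )
  for (nu in nutrients) {
    out[[paste0("nutrient_", nu)]] <- stats::rlnorm(n, 0, 1)
  }
  out
}

# Component-intake rows at full and at zero adherence (see test-nuage.R).
ideal_intakes <- function(subject_id = "ideal") {
  tibble::tibble(
    subject_id = subject_id, wholegrain_g = 200, fruit_g = 300,
    vegetables_g = 350, legumes_g = 35, lowfat_dairy_g = 600,
    lowfat_cheese_g = 35, fish_g = 40, lowfat_meat_poultry_g = 100,
    nuts_g = 10, eggs_g = 20, olive_oil_ml = 25, fluid_ml = 2000,
    vitamin_d_supplement = TRUE, alcohol_g = 5, sodium_mg = 1750,
    sweets_g = 0
  )
}

zero_intakes <- function(subject_id = "zero") {
  tibble::tibble(
    subject_id = subject_id, wholegrain_g = 0, fruit_g = 0,
    vegetables_g = 0, legumes_g = 0, lowfat_dairy_g = 0,
    lowfat_cheese_g = 0, fish_g = 0, lowfat_meat_poultry_g = 0,
    nuts_g = 0, eggs_g = 0, olive_oil_ml = 0, fluid_ml = 0,
    vitamin_d_supplement = FALSE, alcohol_g = 50, sodium_mg = 0,
    sweets_g = 300
  )
}

two_subjects <- function() {
  tibble::tibble(subject_id = c("ideal", "zero"), sex = c("men", "women"),
                 age = c(75, 80), bmi = c(26, 28),
                 energy_kcal = c(2000, 1800))
}
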