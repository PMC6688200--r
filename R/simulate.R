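#' Configuration for the synthetic food-composition and cohort generator
#'
#' Defaults mimic the marginal descriptors of a Dutch elderly food-survey
#' cohort: daily energy 1,964 +/- 457 kcal truncated to the 500-3,500 kcal
#' plausibility window, about half men, ages 70-94. `quality_effect` is the
#' standardized strength with which a single latent diet-quality factor
#' shifts both food choice (toward nutrient-dense food groups) and
#' guideline adherence (wholegrain/low-fat fractions, supplement use,
#' alcohol, sodium); 0 disconnects the two sides entirely.
#'
#' @param n_subjects Number of subjects.
#' @param n_foods Number of foods (>= 23 so every group is covered).
#' @param seed Integer seed; all generation is deterministic given it.
#' @param quality_effect Latent-quality effect size (default 0.5).
#' @param energy_mean,energy_sd Daily energy distribution, kcal.
#' @param sex_ratio Fraction of men.
#' @param age_range Two ages, years.
#' @param noise_sd SD of the independent noise on the adherence fractions.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 735, n_foods = 276, seed = 1,
                       quality_effect = 0.5, energy_mean = 1964,
                       energy_sd = 457, sex_ratio = 0.5,
                       age_range = c(70, 94), noise_sd = 0.5) {
  stopifnot(n_subjects > 0, n_foods >= 23, sex_ratio >= 0, sex_ratio <= 1,
            energy_mean >= 500, energy_mean <= 3500, energy_sd > 0,
            length(age_range) == 2, noise_sd >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_foods = as.integer(n_foods), seed = as.integer(seed),
                 quality_effect = quality_effect, energy_mean = energy_mean,
                 energy_sd = energy_sd, sex_ratio = sex_ratio,
                 age_range = age_range, noise_sd = noise_sd),
            class = "sim_config")
}

#' The 23 food-group labels
#'
#' Default food-group vocabulary used by the generator and the group-level
#' summaries, mirroring the standard Dutch food-composition classification.
#'
#' @return Character vector of 23 labels.
#' @export
food_groups <- function() {
  c("Potatoes", "Alcoholic and non-alcoholic beverages", "Bread",
    "Miscellaneous foods", "Eggs", "Fruits", "Pastry and biscuits",
    "Cereals and cereal products", "Vegetables", "Savory bread spreads",
    "Cheese", "Herbs and spices", "Milk and milk products",
    "Soy products and vegetarian products", "Nuts, seeds and snacks",
    "Legumes", "Clinical formulas", "Mixed dishes", "Soups",
    "Sugar, sweets and sweet sauces", "Fats, oils and savory sauces",
    "Fish", "Meat, meat products and poultry")
}

# Group-typical profiles. `density` is kcal/100 g; nutrient columns are
# typical amounts per 100 kcal (so a food's per-100-kcal score is, by
# construction, independent of its energy-density draw). `share` is the
# group's baseline share of daily energy; `health` the direction in which
# latent diet quality shifts consumption toward (+) or away from (-) the
# group.
group_profiles <- function() {
  tibble::tribble(
    ~food_group, ~density, ~share, ~health,
    ~protein, ~fiber, ~pufa, ~vitamin_d, ~folate, ~vitamin_c, ~vitamin_e,
    ~vitamin_b6, ~vitamin_b12, ~calcium, ~iron, ~magnesium, ~potassium,
    ~zinc, ~selenium, ~iodine, ~saturated_fat, ~sugar, ~sodium,
    "Potatoes", 85, 0.055, 0.2,
    2.5, 2.5, 0.15, 0, 25, 15, 0.1, 0.35, 0, 10, 0.9, 25, 470,
    0.4, 0.5, 2, 0.1, 1, 5,
    "Alcoholic and non-alcoholic beverages", 40, 0.06, -0.5,
    0.5, 0.2, 0.05, 0, 10, 5, 0.1, 0.05, 0, 15, 0.3, 15, 150,
    0.1, 0.5, 2, 0.1, 14, 15,
    "Bread", 260, 0.17, 0,
    4, 2.5, 0.5, 0, 15, 0, 0.3, 0.05, 0, 15, 0.8, 20, 70,
    0.4, 3, 25, 0.3, 1.5, 190,
    "Miscellaneous foods", 150, 0.005, 0,
    3, 3, 0.5, 1, 30, 10, 1, 0.2, 0.3, 60, 1.5, 40, 300,
    0.7, 3, 5, 2, 8, 100,
    "Eggs", 155, 0.02, 0,
    8, 0, 1, 1.2, 30, 0, 0.8, 0.08, 0.8, 35, 1.2, 8, 85,
    0.8, 7, 12, 2, 0.2, 95,
    "Fruits", 55, 0.05, 1,
    1, 3.5, 0.1, 0, 30, 50, 0.5, 0.1, 0, 20, 0.4, 15, 320,
    0.2, 0.3, 1, 0.1, 18, 3,
    "Pastry and biscuits", 400, 0.07, -1,
    1.5, 0.6, 0.4, 0.05, 4, 0, 0.3, 0.02, 0.03, 12, 0.3, 6, 35,
    0.15, 1, 2, 2.2, 8, 70,
    "Cereals and cereal products", 350, 0.03, 0.5,
    3, 2.8, 0.4, 0, 12, 0, 0.4, 0.1, 0, 12, 1.2, 35, 100,
    0.7, 3, 2, 0.4, 4, 3,
    "Vegetables", 30, 0.04, 1,
    7, 8, 0.3, 0, 200, 90, 2.5, 0.4, 0, 130, 2.5, 55, 900,
    1.2, 2, 6, 0.2, 7, 60,
    "Savory bread spreads", 250, 0.01, 0,
    4, 1, 1, 0.2, 20, 1, 0.6, 0.08, 0.5, 15, 1.5, 10, 90,
    0.7, 2, 3, 2, 1, 300,
    "Cheese", 350, 0.055, -0.3,
    7, 0, 0.2, 0.1, 10, 0, 0.1, 0.02, 0.6, 210, 0.1, 10, 30,
    1, 2, 8, 5.3, 0.2, 230,
    "Herbs and spices", 250, 0.002, 0,
    3, 6, 0.4, 0, 40, 10, 1, 0.3, 0, 200, 8, 60, 500,
    1, 2, 2, 1, 10, 1500,
    "Milk and milk products", 60, 0.12, 0.2,
    6, 0, 0.15, 0.1, 9, 2, 0.1, 0.07, 0.7, 205, 0.05, 20, 270,
    0.7, 2, 25, 2.7, 8, 75,
    "Soy products and vegetarian products", 120, 0.005, 0.3,
    9, 3, 2, 0.2, 40, 0, 1.5, 0.1, 0.4, 150, 2, 40, 250,
    0.9, 3, 3, 1, 2, 250,
    "Nuts, seeds and snacks", 500, 0.035, 0.3,
    3.5, 1.6, 3, 0, 12, 1, 1.5, 0.07, 0, 15, 0.6, 35, 120,
    0.6, 1.5, 2, 1.3, 1.5, 90,
    "Legumes", 100, 0.012, 1,
    7.5, 7, 0.4, 0, 100, 2, 0.3, 0.15, 0, 50, 2.2, 45, 400,
    1.1, 2, 2, 0.1, 1.5, 60,
    "Clinical formulas", 100, 0.003, 0,
    5, 1.5, 0.8, 1.5, 35, 15, 2, 0.25, 0.4, 120, 2, 30, 200,
    1.5, 8, 15, 0.6, 6, 100,
    "Mixed dishes", 120, 0.025, 0,
    4, 1.5, 0.6, 0.2, 15, 5, 0.5, 0.1, 0.3, 30, 0.8, 18, 180,
    0.7, 3, 3, 1.3, 2, 250,
    "Soups", 40, 0.02, 0,
    4, 2, 0.4, 0.05, 25, 8, 0.5, 0.1, 0.1, 40, 1, 20, 350,
    0.5, 2, 3, 1, 4, 1100,
    "Sugar, sweets and sweet sauces", 390, 0.05, -1,
    0.6, 0.3, 0.1, 0, 2, 0, 0.1, 0.01, 0.01, 12, 0.3, 5, 40,
    0.1, 0.5, 1, 1.2, 18, 25,
    "Fats, oils and savory sauces", 600, 0.08, -0.5,
    0.3, 0.1, 4, 0.8, 2, 0, 2, 0.01, 0, 5, 0.1, 2, 20,
    0.05, 0.3, 1, 2.5, 1, 120,
    "Fish", 150, 0.022, 1,
    12, 0, 1.5, 4, 8, 0, 0.8, 0.2, 2, 25, 0.4, 20, 250,
    0.5, 20, 30, 0.9, 0.1, 240,
    "Meat, meat products and poultry", 200, 0.11, -0.3,
    10, 0.1, 0.6, 0.2, 4, 1, 0.2, 0.2, 0.8, 8, 0.8, 11, 170,
    1.5, 5, 2, 2.4, 0.3, 330
  )
}

#' Generate a synthetic food-composition table
#'
#' Spreads `n_foods` foods over the 23 groups with group-typical nutrient
#' profiles: each group's energy density is a single log-normal draw around
#' its typical value (foods within a group share it), while nutrient levels
#' are log-normal per food. Nutrient profiles are specified per 100 kcal
#' and converted to per-100-g amounts by the energy density, so a food's
#' per-100-kcal score carries no information about its energy density. One
#' extra beverage item is plain water (0 kcal, no nutrients) to exercise
#' the zero-energy path.
#'
#' @param config A [sim_config()].
#' @return Food tibble: `food_id`, `name`, `food_group`,
#'   `energy_kcal_100g`, `nutrient_*` columns per 100 g.
#' @export
simulate_food_table <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  prof <- group_profiles()
  groups <- food_groups()
  # round-robin so every group is covered before any gets a second food
  assign <- rep(groups, length.out = config$n_foods)
  n <- length(assign)
  gidx <- match(assign, prof$food_group)
  # energy density is drawn once per group (log-normal around the group's
  # typical value) and shared by the group's foods; nutrient content varies
  # per food. See the methods vignette for why density varies between, not
  # within, groups.
  group_density <- prof$density * exp(stats::rnorm(nrow(prof), 0, 0.15))
  energy <- group_density[gidx]
  nutrient_names <- setdiff(names(prof), c("food_group", "density", "share", "health"))
  out <- tibble::tibble(
    food_id = sprintf("F%04d", seq_len(n)),
    name = paste0(tolower(substr(assign, 1, 12)), " item ", seq_len(n)),
    food_group = assign,
    energy_kcal_100g = energy
  )
  for (nu in nutrient_names) {
    per100kcal <- prof[[nu]][gidx] * exp(stats::rnorm(n, 0, 0.4))
    out[[paste0("nutrient_", nu)]] <- per100kcal * energy / 100
  }
  # plain water appended as an extra beverage row (the zero-energy path)
  water <- out[1, ]
  water$food_id <- "F0000"
  water$name <- "water"
  water$food_group <- "Alcoholic and non-alcoholic beverages"
  water$energy_kcal_100g <- 0
  water[, grep("^nutrient_", names(out))] <- 0
  dplyr::bind_rows(out, water)
}

#' Generate a synthetic cohort with a tunable diet-quality gradient
#'
#' Each subject carries a standard-normal latent quality `q`. Energy shares
#' over the 23 food groups are tilted by `quality_effect * q` toward
#' nutrient-dense groups (vegetables, fruits, fish, legumes) and away from
#' sweets, pastry and fats; within each group three foods are chosen at
#' random and split the group's energy equally. NU-AGE component intakes
#' for vegetables, fruits, legumes, fish and eggs are the exact gram sums
#' of the corresponding diet-record groups; the remaining components
#' (wholegrain and low-fat fractions, olive oil, supplement use, alcohol,
#' sodium) are driven by `q` plus independent noise. With
#' `quality_effect = 0` the E-NRF scores and the NU-AGE index are
#' independent by construction.
#'
#' @param config A [sim_config()].
#' @param foods Food table from [simulate_food_table()] (same config).
#' @return List of tibbles: `subjects` (`subject_id`, `sex`, `age`, `bmi`,
#'   `energy_kcal`, `vitamin_d_supplement`, `quality`), `records`
#'   (`subject_id`, `food_id`, `grams_per_day`) and `components`
#'   (`subject_id` plus the 16 NU-AGE intake columns).
#' @export
simulate_cohort <- function(config = sim_config(), foods = simulate_food_table(config)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_subjects
  qe <- config$quality_effect
  nsd <- config$noise_sd
  prof <- group_profiles()

  q <- stats::rnorm(n)
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "men", "women")
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  bmi <- pmin(pmax(stats::rnorm(n, 27.4, 3.8), 16), 45)
  # truncated-normal energy via inverse CDF, deterministic and vectorized
  lo <- stats::pnorm(500, config$energy_mean, config$energy_sd)
  hi <- stats::pnorm(3500, config$energy_mean, config$energy_sd)
  energy <- stats::qnorm(stats::runif(n, lo, hi),
                         config$energy_mean, config$energy_sd)

  # energy shares over groups, tilted by latent quality
  logw <- matrix(log(prof$share), n, nrow(prof), byrow = TRUE) +
    qe * q %o% prof$health
  w <- exp(logw)
  shares <- w / rowSums(w)

  water_id <- foods$food_id[foods$name == "water"]
  rec_subject <- rec_food <- rec_grams <- rec_dens <- vector("list", nrow(prof))
  group_grams <- matrix(0, n, nrow(prof),
                        dimnames = list(NULL, prof$food_group))
  for (g in seq_len(nrow(prof))) {
    ids <- foods$food_id[foods$food_group == prof$food_group[g] &
                           !foods$food_id %in% water_id]
    dens <- foods$energy_kcal_100g[match(ids, foods$food_id)]
    k <- min(3L, length(ids))
    pick <- vapply(seq_len(n), function(i) sample.int(length(ids), k),
                   integer(k))
    pick <- matrix(pick, nrow = k)
    # grams allocated against the group's mean energy density, so group
    # gram totals do not track which particular foods were chosen
    e_food <- shares[, g] * energy / k
    sub <- rep(seq_len(n), each = k)
    fidx <- as.vector(pick)
    grams <- e_food[sub] * 100 / mean(dens)
    rec_subject[[g]] <- sub
    rec_food[[g]] <- ids[fidx]
    rec_grams[[g]] <- grams
    rec_dens[[g]] <- dens[fidx]
    group_grams[, g] <- rowsum(grams, sub)[, 1]
  }
  # rescale every subject's grams by a common factor so the realized diet
  # energy equals the drawn daily energy exactly
  sub_all <- unlist(rec_subject)
  grams_all <- unlist(rec_grams)
  dens_all <- unlist(rec_dens)
  realized <- rowsum(grams_all * dens_all / 100, sub_all)[, 1]
  cf <- energy / realized
  grams_all <- grams_all * cf[sub_all]
  group_grams <- group_grams * cf

  # water rows (zero energy, counts toward fluid)
  water_g <- exp(stats::rnorm(n, log(600), 0.3))
  subject_ids <- sprintf("S%05d", seq_len(n))
  records <- tibble::tibble(
    subject_id = subject_ids[c(sub_all, seq_len(n))],
    food_id = c(unlist(rec_food), rep(water_id, n)),
    grams_per_day = c(grams_all, water_g)
  )

  gg <- function(label) group_grams[, label]
  adherence <- function(base, slope = 2) {
    stats::plogis(base + slope * qe * q + stats::rnorm(n, 0, nsd))
  }
  supplement <- stats::runif(n) < stats::plogis(-0.8 + 2 * qe * q)

  components <- tibble::tibble(
    subject_id = subject_ids,
    wholegrain_g = adherence(0) *
      (gg("Bread") + gg("Cereals and cereal products")),
    fruit_g = gg("Fruits"),
    vegetables_g = gg("Vegetables"),
    legumes_g = gg("Legumes"),
    lowfat_dairy_g = adherence(0.5) * gg("Milk and milk products"),
    lowfat_cheese_g = adherence(-0.5) * gg("Cheese"),
    fish_g = gg("Fish"),
    lowfat_meat_poultry_g = adherence(0.5) *
      gg("Meat, meat products and poultry"),
    nuts_g = adherence(-1) * gg("Nuts, seeds and snacks"),
    eggs_g = gg("Eggs"),
    olive_oil_ml = adherence(-1) * gg("Fats, oils and savory sauces"),
    fluid_ml = water_g + gg("Alcoholic and non-alcoholic beverages") +
      gg("Milk and milk products") + gg("Soups"),
    vitamin_d_supplement = supplement,
    # sex-specific marginals (men drink markedly more in elderly surveys)
    alcohol_g = exp(stats::rnorm(n, log(ifelse(sex == "men", 13, 6.5)), 0.8) -
                      1.5 * qe * q),
    sodium_mg = energy * 1.18 * exp(stats::rnorm(n, 0, 0.2) - 0.5 * qe * q),
    sweets_g = gg("Sugar, sweets and sweet sauces") +
      gg("Pastry and biscuits")
  )

  subjects <- tibble::tibble(
    subject_id = subject_ids, sex = sex, age = age, bmi = bmi,
    energy_kcal = energy, vitamin_d_supplement = supplement, quality = q
  )
  list(subjects = subjects, records = records, components = components)
}
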