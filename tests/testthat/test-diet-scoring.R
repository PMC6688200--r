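test_that("energy units convert grams to 100-kcal units", {
  expect_equal(energy_units(200, 100), 2)
  expect_equal(energy_units(0, 450), 0)
  expect_equal(energy_units(150, 240), 3.6)
  expect_error(energy_units(-1, 100), "non-negative")
})

subjects1 <- tibble::tibble(subject_id = "s1", sex = "men", age = 75,
                            bmi = 26, energy_kcal = 2000)

test_that("a single-food diet scores exactly that food", {
  f <- make_food("f1", energy = 150, protein = 12, fiber = 3, sugar = 5)
  rec <- tibble::tibble(subject_id = "s1", food_id = "f1", grams_per_day = 300)
  ind <- score_diets(rec, subjects1, f, "E-NRF7.3")
  expect_equal(ind$nrf, nrf_score(f, "E-NRF7.3", "men")$nrf)
  expect_equal(ind$energy_kcal, 450)
})

test_that("equal-energy foods average symmetrically", {
  f <- dplyr::bind_rows(
    make_food("a", energy = 100, fiber = 35 * 0.10 / 10),  # placeholder
    make_food("b", energy = 100, fiber = 35 * 0.30 / 10)
  )
  # construct foods with known nrf 10 and 30 via fiber alone (men DRV 35 g)
  f$nutrient_fiber <- c(3.5, 10.5)
  rec <- tibble::tibble(subject_id = "s1", food_id = c("a", "b"),
                        grams_per_day = c(100, 100))
  sc <- score_food_table(f, "E-NRF7.3", "men", quiet = TRUE)
  expect_equal(sc$nrf, c(10, 30))
  ind <- score_diets(rec, subjects1, f, "E-NRF7.3")
  expect_equal(ind$nrf, 20)
})

test_that("weighted score equals the item-by-item brute-force loop", {
  foods <- random_foods(n = 30, seed = 5)
  set.seed(6)
  rec <- tibble::tibble(
    subject_id = "s1",
    food_id = sample(foods$food_id, 12),
    grams_per_day = stats::runif(12, 10, 300)
  )
  ind <- score_diets(rec, subjects1, foods, "E-NRF7.3")
  # independent loop oracle
  num_nr <- num_lim <- den <- 0
  for (i in seq_len(nrow(rec))) {
    f <- foods[foods$food_id == rec$food_id[i], ]
    u <- rec$grams_per_day[i] * f$energy_kcal_100g / 1e4
    s <- nrf_score(f, "E-NRF7.3", "men")
    num_nr <- num_nr + u * s$nr
    num_lim <- num_lim + u * s$lim
    den <- den + u
  }
  expect_equal(ind$nr, num_nr / den)
  expect_equal(ind$lim, num_lim / den)
  expect_equal(ind$nrf, (num_nr - num_lim) / den)
})

test_that("individual scores are invariant to row splitting and gram scaling", {
  foods <- random_foods(n = 10, seed = 9)
  rec <- tibble::tibble(subject_id = "s1",
                        food_id = foods$food_id[c(1, 3, 5)],
                        grams_per_day = c(120, 80, 40))
  base <- score_diets(rec, subjects1, foods, "E-NRF7.3")
  split <- dplyr::bind_rows(rec, rec)
  split$grams_per_day <- split$grams_per_day / 2
  expect_equal(score_diets(split, subjects1, foods, "E-NRF7.3")$nrf, base$nrf)
  doubled <- dplyr::mutate(rec, grams_per_day = grams_per_day * 2)
  expect_equal(score_diets(doubled, subjects1, foods, "E-NRF7.3")$nrf, base$nrf)
})

test_that("individual score lies between the extreme food scores", {
  foods <- random_foods(n = 15, seed = 12)
  set.seed(13)
  rec <- tibble::tibble(subject_id = "s1", food_id = foods$food_id,
                        grams_per_day = stats::runif(15, 5, 200))
  ind <- score_diets(rec, subjects1, foods, "E-NRF7.3")
  sc <- score_food_table(foods, "E-NRF7.3", "men", quiet = TRUE)
  expect_gte(ind$nrf, min(sc$nrf))
  expect_lte(ind$nrf, max(sc$nrf))
})

test_that("implausible energy intakes are excluded with inclusive bounds", {
  subs <- tibble::tibble(subject_id = as.character(1:5),
                         energy_kcal = c(400, 500, 2000, 3500, 3501))
  kept <- exclude_implausible(subs, quiet = TRUE)
  expect_equal(kept$subject_id, c("2", "3", "4"))
  expect_equal(nrow(exclude_implausible(subs[0, ], quiet = TRUE)), 0)
})

test_that("food-group means use sample SD over distinct items", {
  f <- dplyr::bind_rows(
    make_food("a", "Fruits", energy = 100, fiber = 3.5),
    make_food("b", "Fruits", energy = 100, fiber = 10.5),
    make_food("c", "Fish", energy = 100, fiber = 3.5),
    make_food("w", "Soups", energy = 0)
  )
  sc <- score_food_table(f, "E-NRF7.3", "men", quiet = TRUE)
  gm <- food_group_means(sc, quiet = TRUE)
  fruits <- gm[gm$food_group == "Fruits", ]
  expect_equal(fruits$n_foods, 2)
  expect_equal(fruits$nrf_mean, 20)
  expect_equal(fruits$nrf_sd, stats::sd(c(10, 30)))  # 14.14
  fish <- gm[gm$food_group == "Fish", ]
  expect_equal(fish$nrf_sd, 0)
  expect_false("Soups" %in% gm$food_group)
})

test_that("group contributions decompose the weighted score and conserve 100%", {
  foods <- random_foods(n = 20, seed = 21)
  set.seed(22)
  subs <- tibble::tibble(subject_id = c("s1", "s2"), sex = c("men", "women"),
                         age = c(71, 82), bmi = c(24, 29),
                         energy_kcal = c(1800, 2100))
  rec <- tibble::tibble(
    subject_id = rep(c("s1", "s2"), each = 8),
    food_id = c(sample(foods$food_id, 8), sample(foods$food_id, 8)),
    grams_per_day = stats::runif(16, 20, 250)
  )
  gc <- group_contributions(rec, subs, foods, "E-NRF7.3")
  sums <- tapply(gc$per_subject$contribution_pct,
                 gc$per_subject$subject_id, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  # single-group diet -> 100% for that group
  one_group <- foods$food_id[foods$food_group == foods$food_group[1]][1]
  rec1 <- tibble::tibble(subject_id = "s1", food_id = one_group,
                         grams_per_day = 100)
  gc1 <- group_contributions(rec1, subs, foods, "E-NRF7.3")
  expect_equal(gc1$per_subject$contribution_pct, 100)
})

test_that("negative group totals yield negative (documented) contributions", {
  f <- dplyr::bind_rows(
    make_food("good", "Vegetables", energy = 100, fiber = 17.5),  # nrf 50
    make_food("bad", "Sugar, sweets and sweet sauces", energy = 100,
              sugar = 18)                                         # nrf -20
  )
  subs <- tibble::tibble(subject_id = "s1", sex = "men", age = 75, bmi = 25,
                         energy_kcal = 2000)
  rec <- tibble::tibble(subject_id = "s1", food_id = c("good", "bad"),
                        grams_per_day = c(100, 100))
  gc <- group_contributions(rec, subs, f, "E-NRF7.3")
  ps <- gc$per_subject
  expect_lt(ps$contribution_pct[ps$food_group != "Vegetables"], 0)
  expect_gt(ps$contribution_pct[ps$food_group == "Vegetables"], 100)
  expect_equal(sum(ps$contribution_pct), 100)
})

test_that("unknown food ids in records raise a join error", {
  foods <- random_foods(n = 3, seed = 2)
  rec <- tibble::tibble(subject_id = "s1", food_id = "nope",
                        grams_per_day = 10)
  expect_error(score_diets(rec, subjects1, foods, "E-NRF7.3"), "nope")
})
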