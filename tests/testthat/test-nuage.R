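test_that("weekly serving guidelines convert to the printed daily grams", {
  expect_equal(weekly_to_daily(2, 80), 23)    # wholegrain pasta/rice
  expect_equal(weekly_to_daily(1, 200), 29)   # legumes, 200 g/week
  expect_equal(weekly_to_daily(2, 125), 36)   # fish
  expect_equal(weekly_to_daily(4, 125), 71)   # low-fat meat and poultry
  expect_equal(weekly_to_daily(2, 20), 6)     # nuts
  expect_equal(weekly_to_daily(2, 50), 14)    # eggs (50 g each)
})

test_that("component specs carry the published thresholds", {
  sp <- nuage_components()
  expect_length(sp, 16)
  # combined wholegrain window: bread 140-210 g/day plus 23 g/day pasta/rice
  expect_equal(sp$wholegrain_g$lower_full, 140 + 23)
  expect_equal(sp$wholegrain_g$upper_full, 210 + 23)
  expect_equal(sp$fruit_g$lower_full, 240)
  expect_equal(sp$vegetables_g$lower_full, 300)
  expect_equal(sp$legumes_g$lower_full, 29)
  expect_equal(sp$lowfat_dairy_g$lower_full, 500)
  expect_equal(sp$lowfat_cheese_g$lower_full, 30)
  expect_equal(sp$fish_g$lower_full, 36)
  expect_equal(sp$lowfat_meat_poultry_g$lower_full, 71)
  expect_equal(sp$lowfat_meat_poultry_g$upper_full, 125)
  expect_equal(sp$nuts_g$lower_full, 6)
  expect_equal(sp$eggs_g$lower_full, 14)
  expect_equal(sp$olive_oil_ml$lower_full, 20)
  expect_equal(sp$fluid_ml$lower_zero, 1000)
  expect_equal(sp$fluid_ml$lower_full, 1500)
  expect_equal(sp$alcohol_g$limit_men, 20)
  expect_equal(sp$alcohol_g$limit_women, 10)
  # salt guideline: 5 g/day of salt is 2,000 mg of sodium
  expect_equal(sodium_from_salt(5), 2000)
  expect_equal(sp$sodium_mg$lower_full, 1500)
  expect_equal(sp$sodium_mg$upper_full, 2000)
})

test_that("percentile cut-offs interpolate order statistics", {
  intakes <- tibble::tibble(
    subject_id = as.character(0:100),
    wholegrain_g = stats::runif(101, 0, 400),
    lowfat_meat_poultry_g = stats::runif(101, 0, 200),
    sodium_mg = stats::runif(101, 500, 4000),
    sweets_g = as.numeric(0:100)
  )
  cut <- resolve_cutoffs(intakes)
  expect_equal(cut$sweets_g, 85)                       # uniform grid
  expect_equal(cut$wholegrain_g, max(intakes$wholegrain_g))   # 100th pct
  expect_equal(cut$lowfat_meat_poultry_g, max(intakes$lowfat_meat_poultry_g))
  expect_equal(cut$sodium_mg,
               unname(stats::quantile(intakes$sodium_mg, 0.85, type = 7)))
  const <- dplyr::mutate(intakes, sweets_g = 42)
  expect_equal(resolve_cutoffs(const)$sweets_g, 42)
  expect_error(resolve_cutoffs(intakes[1, ]), "at least 2")
})

test_that("ramp components interpolate linearly between the knots", {
  sp <- nuage_components()
  expect_equal(component_score(c(0, 120, 240, 500), sp$fruit_g),
               c(0, 5, 10, 10))
  expect_equal(component_score(c(900, 1000, 1250, 1500, 2500), sp$fluid_ml),
               c(0, 0, 5, 10, 10))
  expect_equal(component_score(c(0, 15, 30, 60), sp$lowfat_cheese_g),
               c(0, 5, 10, 10))
})

test_that("binary components are all-or-nothing", {
  sp <- nuage_components()
  expect_equal(component_score(c(TRUE, FALSE), sp$vitamin_d_supplement),
               c(10, 0))
  expect_equal(component_score(c(20, 21), sp$alcohol_g, sex = "men"),
               c(10, 0))
  expect_equal(component_score(c(10, 11), sp$alcohol_g, sex = "women"),
               c(10, 0))
  expect_equal(component_score(c(15, 15), sp$alcohol_g,
                               sex = c("men", "women")), c(10, 0))
})

test_that("upper-penalty components ramp down to zero at the cut-off", {
  sp <- nuage_components()
  cut <- list(wholegrain_g = 433, sodium_mg = 3000, sweets_g = 200,
              lowfat_meat_poultry_g = 250)
  # wholegrain: up 0-163, plateau 163-233, down 233-433
  expect_equal(component_score(c(0, 81.5, 163, 200, 233, 333, 433, 500),
                               sp$wholegrain_g, cut),
               c(0, 5, 10, 10, 10, 5, 0, 0))
  # sodium: up to 1,500, plateau to 2,000, down to the 85th percentile
  expect_equal(component_score(c(0, 750, 1500, 1750, 2000, 2500, 3000),
                               sp$sodium_mg, cut),
               c(0, 5, 10, 10, 10, 5, 0))
  # sweets: full points only at zero intake
  expect_equal(component_score(c(0, 100, 200, 300), sp$sweets_g, cut),
               c(10, 5, 0, 0))
  # meat: up 0-71, plateau 71-125, down to the cohort maximum
  expect_equal(component_score(c(71, 125, 187.5, 250), sp$lowfat_meat_poultry_g,
                               cut), c(10, 10, 5, 0))
  expect_error(component_score(100, sp$wholegrain_g, list()), "Unresolved")
})

test_that("the selectable footnote-style upper ramp divides by the plateau end", {
  sp <- nuage_components()$lowfat_meat_poultry_g
  cut <- list(lowfat_meat_poultry_g = 250)
  # 10 - (intake - 125) * 10 / 125, clipped, zero at/above the cut-off
  expect_equal(component_score(150, sp, cut, upper_ramp = "footnote_c"),
               10 - 25 * 10 / 125)
  expect_equal(component_score(250, sp, cut, upper_ramp = "footnote_c"), 0)
})

test_that("component scores stay in [0,10] and respect monotone segments", {
  sp <- nuage_components()
  cut <- list(wholegrain_g = 400, sodium_mg = 3100,
              sweets_g = 180, lowfat_meat_poultry_g = 260)
  set.seed(3)
  for (name in names(sp)) {
    if (sp[[name]]$shape %in% c("binary", "binary-by-sex")) next
    x <- sort(stats::runif(50, 0, 3500))
    s <- component_score(x, sp[[name]], cut)
    expect_true(all(s >= 0 & s <= 10), info = name)
  }
  # ramp-up components are non-decreasing in intake
  for (name in c("fruit_g", "vegetables_g", "fish_g", "fluid_ml")) {
    x <- sort(stats::runif(50, 0, 2000))
    expect_true(!is.unsorted(component_score(x, sp[[name]], cut)), info = name)
  }
  # ramp-down tails are non-increasing
  x <- sort(stats::runif(50, 2000, 3100))
  s <- component_score(x, sp$sodium_mg, cut)
  expect_true(!is.unsorted(rev(s)), info = "sodium tail")
})

test_that("totals span 0-160 and equal the sum of component scores", {
  intakes <- dplyr::bind_rows(ideal_intakes(), zero_intakes())
  subjects <- two_subjects()
  idx <- nuage_index(intakes, subjects)
  expect_equal(idx$nuage_total[1], 160)
  expect_equal(idx$nuage_total[2], 0)
  pts <- as.matrix(idx[grep("^pts_", names(idx))])
  expect_equal(unname(rowSums(pts)), idx$nuage_total)
  expect_true(all(pts >= 0 & pts <= 10))
})

test_that("re-scoring after adding a subject only moves percentile components", {
  set.seed(14)
  n <- 40
  intakes <- tibble::tibble(
    subject_id = sprintf("p%02d", 1:n),
    wholegrain_g = stats::runif(n, 0, 300), fruit_g = stats::runif(n, 0, 400),
    vegetables_g = stats::runif(n, 0, 400), legumes_g = stats::runif(n, 0, 60),
    lowfat_dairy_g = stats::runif(n, 0, 700),
    lowfat_cheese_g = stats::runif(n, 0, 60), fish_g = stats::runif(n, 0, 80),
    lowfat_meat_poultry_g = stats::runif(n, 0, 200),
    nuts_g = stats::runif(n, 0, 20), eggs_g = stats::runif(n, 0, 40),
    olive_oil_ml = stats::runif(n, 0, 40), fluid_ml = stats::runif(n, 500, 2500),
    vitamin_d_supplement = stats::runif(n) < 0.5,
    alcohol_g = stats::runif(n, 0, 40), sodium_mg = stats::runif(n, 800, 3600),
    sweets_g = stats::runif(n, 0, 250)
  )
  subjects <- tibble::tibble(subject_id = intakes$subject_id,
                             sex = rep(c("men", "women"), n / 2))
  base <- nuage_index(intakes, subjects)
  extreme <- dplyr::mutate(
    intakes[1, ], subject_id = "new", wholegrain_g = 900, sweets_g = 900,
    sodium_mg = 9000, lowfat_meat_poultry_g = 900)
  again <- nuage_index(dplyr::bind_rows(intakes, extreme),
                       dplyr::bind_rows(subjects,
                                        tibble::tibble(subject_id = "new",
                                                       sex = "men")))
  again <- again[match(base$subject_id, again$subject_id), ]
  fixed <- setdiff(grep("^pts_", names(base), value = TRUE),
                   c("pts_wholegrain", "pts_lowfat_meat_poultry",
                     "pts_sodium", "pts_sweets"))
  for (col in fixed) expect_equal(again[[col]], base[[col]], info = col)
  expect_false(isTRUE(all.equal(again$pts_sweets, base$pts_sweets)))
})

test_that("missing component columns are reported by name", {
  intakes <- ideal_intakes()[, -3]
  expect_error(nuage_index(intakes, two_subjects()), "fruit_g")
})
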