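test_that("weighted prevalence matches hand arithmetic and the unweighted special case", {
  expect_equal(weighted_prevalence(c(TRUE, FALSE), c(1, 3))$estimate, 0.25)
  x <- c(rep(TRUE, 3), rep(FALSE, 7))
  expect_equal(weighted_prevalence(x, rep(2, 10))$estimate, 0.30)
  # missing indicators drop out of both sums
  res <- weighted_prevalence(c(TRUE, NA, FALSE), c(1, 10, 1))
  expect_equal(res$estimate, 0.5)
  expect_equal(res$n, 2L)
  expect_equal(res$n_excluded, 1L)
})

test_that("weighted prevalence equals a brute-force loop on random fixtures", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    x <- sample(c(TRUE, FALSE, NA), n, replace = TRUE, prob = c(.45, .45, .1))
    w <- runif(n, 0.2, 3)
    keep <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.8, .2))
    if (!any(keep & !is.na(x))) next
    got <- weighted_prevalence(x, w, subset = keep)
    want <- bf_prevalence(x, w, keep)
    expect_equal(got$estimate, want$estimate, tolerance = 1e-12)
    expect_equal(got$n, want$n)
  }
})

test_that("empty estimation domains raise an error rather than returning 0", {
  expect_error(weighted_prevalence(c(TRUE, FALSE), c(1, 1),
                                   subset = c(FALSE, FALSE)),
               class = "urbanpoverty_empty_domain")
  expect_error(weighted_prevalence(c(NA, NA), c(1, 1)),
               class = "urbanpoverty_empty_domain")
})

test_that("percentile ranks use the mid-distribution convention", {
  expect_equal(weighted_quantile_rank(1:10, rep(1, 10)),
               seq(0.05, 0.95, by = 0.1))
  # ties share the midpoint rank
  expect_equal(weighted_quantile_rank(c(1, 1, 2), rep(1, 3)),
               c(1 / 3, 1 / 3, 5 / 6))
  # invariant to weight rescaling
  s <- c(3, 1, 4, 1, 5, 9, 2, 6)
  w <- runif(8, 0.5, 2)
  expect_equal(weighted_quantile_rank(s, w),
               weighted_quantile_rank(s, 7 * w))
})

test_that("percentile ranks agree with the brute-force oracle and are monotone", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(4:40, 1)
    s <- sample(1:8, n, replace = TRUE) + ifelse(runif(n) < 0.5, 0, 0.5)
    s[runif(n) < 0.1] <- NA
    if (all(is.na(s))) next
    w <- runif(n, 0.3, 2)
    got <- weighted_quantile_rank(s, w)
    expect_equal(got, bf_rank(s, w), tolerance = 1e-12)
    ok <- !is.na(s)
    o <- order(s[ok])
    expect_true(all(diff(got[ok][o]) >= -1e-12))
  }
  expect_error(weighted_quantile_rank(c(NA_real_, NA_real_), c(1, 1)))
})

test_that("dataset validation enforces referential and weight invariants", {
  hh <- make_household("h1", n_members = 1L)
  p_ok <- make_person("h1", age = 30, edu = 8)
  expect_s3_class(survey_dataset(hh, p_ok), "survey_dataset")
  expect_error(survey_dataset(hh, make_person("h9", age = 30, edu = 2)),
               regexp = "h9", class = "urbanpoverty_integrity_error")
  expect_error(survey_dataset(make_household("h1", weight = 0), p_ok),
               regexp = "weights")
  expect_error(survey_dataset(make_household("h1", n_members = 3L), p_ok),
               class = "urbanpoverty_integrity_error")
})

test_that("a generated city round-trips through CSV and a column mapping", {
  cfg <- scenario_config(n_cities = 1, households_per_city = c(60, 60),
                         seed = 5)
  d <- generate_city(cfg, 1)
  dir <- withr::local_tempdir()
  write_survey(d, dir)
  # identity mapping covering the canonical schema
  asset_names <- sub("^asset_", "",
                     grep("^asset_", names(d$households), value = TRUE))
  idmap <- function(v) as.list(setNames(v, v))
  mapping <- list(
    household = list(
      columns = idmap(c("household_id", "city_id", "cluster_id", "stratum_id",
                        "weight", "n_members", "electricity", "water_source",
                        "time_to_water", "sanitation_type",
                        "sanitation_shared", "cooking_fuel", "floor_material",
                        "wall_material", "roof_material", "persons_per_room")),
      assets = as.list(setNames(paste0("asset_", asset_names), asset_names))),
    person = list(columns = idmap(c("person_id", "household_id", "age_years",
                                    "edu_years", "in_school"))))
  map_path <- file.path(dir, "mapping.yaml")
  yaml::write_yaml(mapping, map_path)
  back <- read_survey(file.path(dir, "city01_households.csv"),
                      file.path(dir, "city01_persons.csv"),
                      read_column_mapping(map_path))
  expect_equal(back$households$household_id, d$households$household_id)
  expect_equal(back$households$weight, d$households$weight)
  expect_equal(back$households$water_source, d$households$water_source)
  expect_equal(back$persons$edu_years, d$persons$edu_years)
  expect_equal(nrow(back$persons), nrow(d$persons))
})

test_that("recoded source codes flow through to the classifiers", {
  # numeric survey codes recoded to dictionary codes; code 31 means an
  # unprotected well, which must classify as unimproved water
  hh_raw <- tibble::tibble(
    hhid = c("a", "b", "c", "d", "e"), city = "x", wt = 1, nm = 1,
    elec = c(1, 1, 0, 1, 1),
    water = c("11", "31", "11", "41", "31"),
    twater = c(0, 10, 45, 5, 5),
    san = "12", shared = 0, fuel = "lpg",
    fl = "finished_cement", wa = "bricks", ro = "metal_sheet", ppr = 1)
  pp_raw <- tibble::tibble(pid = paste0(c("a", "b", "c", "d", "e"), "_p1"),
                           hhid = c("a", "b", "c", "d", "e"),
                           age = 30, edu = 8, sch = NA)
  dir <- withr::local_tempdir()
  readr::write_csv(hh_raw, file.path(dir, "hh.csv"))
  readr::write_csv(pp_raw, file.path(dir, "pp.csv"))
  mapping <- list(
    household = list(
      columns = list(household_id = "hhid", city_id = "city", weight = "wt",
                     n_members = "nm", electricity = "elec",
                     water_source = "water", time_to_water = "twater",
                     sanitation_type = "san", sanitation_shared = "shared",
                     cooking_fuel = "fuel", floor_material = "fl",
                     wall_material = "wa", roof_material = "ro",
                     persons_per_room = "ppr"),
      recodes = list(water_source = list("11" = "piped_dwelling",
                                         "31" = "unprotected_well",
                                         "41" = "protected_well"),
                     sanitation_type = list("12" = "flush_septic"))),
    person = list(columns = list(person_id = "pid", household_id = "hhid",
                                 age_years = "age", edu_years = "edu",
                                 in_school = "sch")))
  map_path <- file.path(dir, "mapping.yaml")
  yaml::write_yaml(mapping, map_path)
  ds <- read_survey(file.path(dir, "hh.csv"), file.path(dir, "pp.csv"),
                    read_column_mapping(map_path))
  out <- compute_outcomes(ds$households, ds$persons)
  # hand classification: b,e unprotected wells -> TRUE; c improved but 45 min
  # round trip -> TRUE; a piped on premises and d protected well -> FALSE
  expect_equal(out$no_improved_water, c(FALSE, TRUE, TRUE, FALSE, TRUE))

  # an unknown source code is a recode error naming the variable
  hh_bad <- hh_raw
  hh_bad$water[2] <- "99"
  readr::write_csv(hh_bad, file.path(dir, "hh_bad.csv"))
  expect_error(read_survey(file.path(dir, "hh_bad.csv"),
                           file.path(dir, "pp.csv"),
                           read_column_mapping(map_path)),
               class = "urbanpoverty_recode_error")
})
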