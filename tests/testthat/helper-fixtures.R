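# Shared fixtures and independent brute-force oracles. Oracles are written as
# plain element-by-element loops, deliberately independent of the vectorised
# implementations they check.

dict_fix <- variable_dictionary()

# One fully specified household row; override any field.
make_household <- function(id = "h1", ..., city = "cityA") {
  base <- tibble::tibble(
    household_id = id,
    city_id = city,
    cluster_id = paste0(city, "_c1"),
    stratum_id = city,
    weight = 1,
    n_members = 4L,
    electricity = TRUE,
    water_source = "piped_dwelling",
    time_to_water = 0,
    sanitation_type = "flush_sewer",
    sanitation_shared = FALSE,
    cooking_fuel = "lpg",
    floor_material = "finished_cement",
    wall_material = "bricks",
    roof_material = "metal_sheet",
    persons_per_room = 2,
    asset_radio = TRUE, asset_tv = TRUE, asset_fridge = TRUE,
    asset_phone = TRUE, asset_computer = FALSE, asset_motorcycle = FALSE,
    asset_bicycle = TRUE, asset_car = FALSE
  )
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

make_person <- function(hh_id, i = 1, age = 30, edu = 8, in_school = NA) {
  tibble::tibble(person_id = paste0(hh_id, "_p", i),
                 household_id = hh_id,
                 age_years = as.integer(age),
                 edu_years = as.integer(edu),
                 in_school = in_school)
}

# --- brute-force oracles -----------------------------------------------------

bf_prevalence <- function(x, w, subset = rep(TRUE, length(x))) {
  num <- 0; den <- 0; n <- 0L
  for (i in seq_along(x)) {
    if (isTRUE(subset[i]) && !is.na(x[i])) {
      num <- num + w[i] * as.numeric(x[i])
      den <- den + w[i]
      n <- n + 1L
    }
  }
  list(estimate = num / den, n = n)
}

bf_rank <- function(score, w) {
  total <- sum(w[!is.na(score)])
  out <- rep(NA_real_, length(score))
  for (i in seq_along(score)) {
    if (is.na(score[i])) next
    below <- 0; tied <- 0
    for (j in seq_along(score)) {
      if (is.na(score[j])) next
      if (score[j] < score[i]) below <- below + w[j]
      if (score[j] == score[i]) tied <- tied + w[j]
    }
    out[i] <- (below + tied / 2) / total
  }
  out
}

bf_agreement <- function(a, b) {
  same <- 0L; n <- 0L
  for (i in seq_along(a)) {
    if (!is.na(a[i]) && !is.na(b[i])) {
      n <- n + 1L
      if (a[i] == b[i]) same <- same + 1L
    }
  }
  same / n
}

bf_median <- function(x) median(x, na.rm = TRUE)

# Empirical Gini of a sample (mean absolute difference form), O(n log n).
empirical_gini <- function(x) {
  x <- sort(x)
  n <- length(x)
  sum((2 * seq_len(n) - n - 1) * x) / (n^2 * mean(x))
}

# A small deterministic multi-city scenario reused across tests.
small_scenario <- function(n_cities = 3, hh = c(250, 350), seed = 99) {
  generate_scenario(scenario_config(n_cities = n_cities,
                                    households_per_city = hh,
                                    seed = seed))
}

# Construct a per-city label table where every measure is a threshold on one
# shared uniform score, so agreement between measures with poor shares a and
# b is exactly 1 - |a - b|. `shares` names poor shares for pline/sds/slum.
nested_label_city <- function(city, n = 400,
                              shares = c(pline = 0.40, sds = 0.05,
                                         slum = 0.75)) {
  u <- (seq_len(n) - 0.5) / n
  out <- tibble::tibble(household_id = sprintf("%s_h%03d", city, seq_len(n)),
                        city_id = city, weight = 1, n_members = 4L,
                        wealth_score = u, wealth_rank = u,
                        poor_w30 = u <= 0.30, poor_w40 = u <= 0.40,
                        poor_w50 = u <= 0.50, poor_w60 = u <= 0.60,
                        poor_pline = u <= shares[["pline"]],
                        poor_sds = u <= shares[["sds"]],
                        poor_slum = u <= shares[["slum"]])
  for (oc in outcome_names()) out[[oc]] <- u <= 0.5
  out
}
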