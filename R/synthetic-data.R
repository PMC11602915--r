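#' Scenario configuration for the synthetic survey generator
#'
#' Defines the study conditions for a generated multi-city scenario. The
#' generator emulates the structure of DHS/MICS-style urban samples: a latent
#' household socioeconomic factor drives correlated binary asset ownership,
#' housing quality, WASH access, roster education and schooling, and the
#' city-level development covariates. Defaults describe the setting analysed
#' by the pipeline: 38 cities of 500-2,000 households each, household rosters
#' of 1-15 members, Gini indices between 0.35 and 0.65 and GDP per capita
#' between 600 and 8,000 currency units per year.
#'
#' @param n_cities Number of cities to generate.
#' @param households_per_city `[min, max]` bounds on city sample size; each
#'   city's size is drawn uniformly within them.
#' @param latent_ses_sd Standard deviation of the latent household
#'   socioeconomic factor (mean 0).
#' @param asset_loadings Named numeric vector: effect (on the logit scale) of
#'   the latent factor on ownership of each asset in the variable dictionary.
#' @param asset_intercepts Named numeric vector of logit intercepts fixing
#'   each asset's baseline prevalence.
#' @param electricity_loading,electricity_intercept Logit model for household
#'   electricity access.
#' @param wash_loading Effect of the latent factor on the logit of having
#'   improved water, improved sanitation, durable housing materials and clean
#'   cooking fuel.
#' @param roster_size_dist Probability vector over household sizes 1..15.
#' @param education_gradient Effect of the latent factor on adult completed
#'   years of education (years per latent-SD).
#' @param school_attendance_gradient Effect of the latent factor on the logit
#'   of school attendance among school-aged children.
#' @param gini_range `[min, max]` for the city Gini index, inside `[0, 1)`.
#' @param gdp_pc_range `[min, max]` for GDP per capita (currency/year).
#' @param hdi_noise_sd Standard deviation of the noise added to the latent
#'   city mean before mapping to each HDI sub-index.
#' @param seed Integer seed; fixes the full scenario bit-for-bit.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_cities = 38,
                            households_per_city = c(500, 2000),
                            latent_ses_sd = 1,
                            asset_loadings = c(radio = 0.8, tv = 1.2,
                                               fridge = 1.5, phone = 1.0,
                                               computer = 1.8,
                                               motorcycle = 0.6,
                                               bicycle = 0.3, car = 1.6),
                            asset_intercepts = c(radio = 0.2, tv = 0.0,
                                                 fridge = -0.8, phone = 0.8,
                                                 computer = -1.8,
                                                 motorcycle = -1.0,
                                                 bicycle = -0.5, car = -2.2),
                            electricity_loading = 1.5,
                            electricity_intercept = 0.5,
                            wash_loading = 1.0,
                            roster_size_dist = default_roster_dist(),
                            education_gradient = 2,
                            school_attendance_gradient = 1,
                            gini_range = c(0.35, 0.65),
                            gdp_pc_range = c(600, 8000),
                            hdi_noise_sd = 0.02,
                            seed = 20240109) {
  assert_scalar_number(n_cities, "n_cities", lower = 1)
  assert_range(households_per_city, "households_per_city", lower = 1)
  assert_scalar_number(latent_ses_sd, "latent_ses_sd", lower = 0)
  if (!is.numeric(asset_loadings) || is.null(names(asset_loadings)) ||
      anyNA(asset_loadings)) {
    abort("invalid configuration: `asset_loadings` must be a named numeric vector",
          class = "urbanpoverty_config_error")
  }
  missing_int <- setdiff(names(asset_loadings), names(asset_intercepts))
  if (length(missing_int)) {
    abort(sprintf("invalid configuration: `asset_intercepts` missing entries for: %s",
                  paste(missing_int, collapse = ", ")),
          class = "urbanpoverty_config_error")
  }
  if (!is.numeric(roster_size_dist) || length(roster_size_dist) != 15L ||
      anyNA(roster_size_dist) || any(roster_size_dist < 0) ||
      abs(sum(roster_size_dist) - 1) > 1e-8) {
    abort("invalid configuration: `roster_size_dist` must be 15 probabilities over sizes 1..15 summing to 1",
          class = "urbanpoverty_config_error")
  }
  assert_scalar_number(education_gradient, "education_gradient")
  assert_scalar_number(school_attendance_gradient, "school_attendance_gradient")
  assert_range(gini_range, "gini_range", lower = 0, upper = 1 - 1e-9)
  assert_range(gdp_pc_range, "gdp_pc_range", lower = 1e-9)
  assert_scalar_number(hdi_noise_sd, "hdi_noise_sd", lower = 0)
  assert_scalar_number(seed, "seed")
  structure(list(n_cities = as.integer(n_cities),
                 households_per_city = as.integer(households_per_city),
                 latent_ses_sd = latent_ses_sd,
                 asset_loadings = asset_loadings,
                 asset_intercepts = asset_intercepts[names(asset_loadings)],
                 electricity_loading = electricity_loading,
                 electricity_intercept = electricity_intercept,
                 wash_loading = wash_loading,
                 roster_size_dist = roster_size_dist,
                 education_gradient = education_gradient,
                 school_attendance_gradient = school_attendance_gradient,
                 gini_range = gini_range,
                 gdp_pc_range = gdp_pc_range,
                 hdi_noise_sd = hdi_noise_sd,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Default household-size distribution over 1..15 members
#'
#' A right-skewed distribution (mode 3-4, mean ~4.6) typical of urban
#' sub-Saharan household rosters: a shifted Poisson(3.6) truncated at 15.
#' @return Probability vector of length 15.
#' @export
default_roster_dist <- function() {
  p <- stats::dpois(0:14, lambda = 3.6)
  p / sum(p)
}

# Sample a categorical code from the codes of one class in a dictionary
# mapping, with fixed relative frequencies (uniform within class).
sample_code <- function(n, mapping, class) {
  codes <- codes_of(mapping, class)
  codes[sample.int(length(codes), n, replace = TRUE)]
}

#' Generate one synthetic city survey
#'
#' Draws a city of households whose observed variables are all driven by a
#' hidden standard-normal-scale latent socioeconomic factor: binary assets and
#' electricity are Bernoulli with a logit linear in the factor; water source,
#' sanitation, housing materials and cooking fuel are categorical draws whose
#' probability of the improved/durable/clean class rises with the factor;
#' roster education and school attendance follow the configured gradients.
#' Sampling weights are uniform on `[0.5, 2]` normalised to mean 1, and
#' clusters are contiguous blocks of 25 households. The hidden factor is kept
#' in the diagnostics column `latent_ses`, which is excluded from analysis
#' inputs by default and exists so tests can measure parameter recovery.
#'
#' @param config A [scenario_config()].
#' @param city_index City number, 1-based, at most `config$n_cities`.
#' @return A [survey_dataset()] whose household table carries the extra
#'   `latent_ses` column; the dataset also carries a `city_index` attribute.
#' @export
generate_city <- function(config, city_index) {
  stopifnot(inherits(config, "scenario_config"))
  if (city_index < 1 || city_index > config$n_cities) {
    abort("city_index must lie in 1..n_cities",
          class = "urbanpoverty_config_error")
  }
  dict <- variable_dictionary()
  with_local_seed(derive_seed(config$seed, city_index), {
    city_id <- sprintf("city%02d", city_index)
    bounds <- config$households_per_city
    n <- if (bounds[1] == bounds[2]) bounds[1] else
      sample(bounds[1]:bounds[2], 1L)
    z <- rnorm(n, 0, config$latent_ses_sd)

    hh <- tibble::tibble(
      household_id = sprintf("%s_h%05d", city_id, seq_len(n)),
      city_id = city_id,
      cluster_id = sprintf("%s_c%03d", city_id, (seq_len(n) - 1L) %/% 25L + 1L),
      stratum_id = city_id,
      latent_ses = z
    )
    w <- runif(n, 0.5, 2.0)
    hh$weight <- w / mean(w)

    size <- sample(1:15, n, replace = TRUE, prob = config$roster_size_dist)
    hh$n_members <- size

    for (a in names(config$asset_loadings)) {
      p <- plogis(config$asset_intercepts[[a]] + config$asset_loadings[[a]] * z)
      hh[[paste0("asset_", a)]] <- rbinom(n, 1, p) == 1L
    }
    hh$electricity <- rbinom(n, 1, plogis(config$electricity_intercept +
                                            config$electricity_loading * z)) == 1L

    wl <- config$wash_loading
    improved_water <- rbinom(n, 1, plogis(0.6 + wl * z)) == 1L
    hh$water_source <- ifelse(improved_water,
                              sample_code(n, dict$water_sources, "improved"),
                              sample_code(n, dict$water_sources, "unimproved"))
    # round-trip fetch time in minutes; on-premises piped water takes none
    hh$time_to_water <- ifelse(hh$water_source == "piped_dwelling", 0,
                               round(rlnorm(n, meanlog = 2.6 - 0.4 * z,
                                            sdlog = 0.6)))
    improved_san <- rbinom(n, 1, plogis(0.4 + wl * z)) == 1L
    no_facility <- !improved_san & rbinom(n, 1, 0.25) == 1L
    hh$sanitation_type <- ifelse(improved_san,
                                 sample_code(n, dict$sanitation_types, "improved"),
                                 ifelse(no_facility, "open_defecation",
                                        sample_code(n, dict$sanitation_types,
                                                    "unimproved")))
    hh$sanitation_shared <- ifelse(hh$sanitation_type == "open_defecation", NA,
                                   rbinom(n, 1, plogis(-0.4 - 0.8 * z)) == 1L)
    durable <- function(shift) rbinom(n, 1, plogis(shift + wl * 1.2 * z)) == 1L
    hh$floor_material <- ifelse(durable(0.5),
                                sample_code(n, dict$floor_materials, "durable"),
                                sample_code(n, dict$floor_materials, "not_durable"))
    hh$wall_material <- ifelse(durable(0.7),
                               sample_code(n, dict$wall_materials, "durable"),
                               sample_code(n, dict$wall_materials, "not_durable"))
    hh$roof_material <- ifelse(durable(1.0),
                               sample_code(n, dict$roof_materials, "durable"),
                               sample_code(n, dict$roof_materials, "not_durable"))
    hh$cooking_fuel <- ifelse(rbinom(n, 1, plogis(-1 + 1.2 * z)) == 1L,
                              sample_code(n, dict$cooking_fuels, "clean"),
                              sample_code(n, dict$cooking_fuels, "dirty"))
    rooms <- 1L + rpois(n, exp(0.3 + 0.35 * z))
    hh$persons_per_room <- size / rooms

    persons <- generate_roster(hh$household_id, size, z, config)
    out <- survey_dataset(hh, persons, city_id = city_id)
    attr(out, "city_index") <- as.integer(city_index)
    out
  })
}

# Roster members for every household: the first member is an adult head;
# remaining ages are drawn across the full range. Education rises with the
# household latent factor at `education_gradient` years per latent-SD, capped
# by what is attainable at the member's age; school attendance among ages
# 6-14 follows the attendance gradient on the logit scale.
generate_roster <- function(household_ids, sizes, z, config) {
  hh_idx <- rep(seq_along(household_ids), sizes)
  m <- length(hh_idx)
  first <- !duplicated(hh_idx)
  age <- ifelse(first, sample(18:80, m, replace = TRUE),
                sample(0:80, m, replace = TRUE))
  zi <- z[hh_idx]
  attainable <- pmax(0, pmin(age - 5L, 14L))
  edu <- round(rnorm(m, mean = 7 + config$education_gradient * zi, sd = 2))
  edu <- pmin(pmax(edu, 0L), attainable)
  school_age <- age >= 6 & age <= 14
  in_school <- rep(NA, m)
  in_school[school_age] <- rbinom(sum(school_age), 1,
                                  plogis(2.2 + config$school_attendance_gradient *
                                           zi[school_age])) == 1L
  tibble::tibble(
    person_id = paste0(household_ids[hh_idx], "_p",
                       sequence(sizes)),
    household_id = household_ids[hh_idx],
    age_years = as.integer(age),
    edu_years = as.integer(edu),
    in_school = in_school
  )
}

#' Generate the macro-level context for a generated city
#'
#' Gini and GDP per capita are drawn within the configured ranges (GDP per
#' capita monotone in the city's mean latent factor, so richer cities are
#' richer on paper too). The three HDI sub-indices are noisy monotone probit
#' transforms of the mean latent factor, each in `[0, 1]`, and the HDI is
#' their arithmetic mean. Consumption-expenditure shares of GDP are drawn in
#' realistic bands with the household share below the total share.
#'
#' @param config A [scenario_config()].
#' @param dataset A city generated by [generate_city()] (its `city_index`
#'   attribute seeds the context draw).
#' @return One-row tibble: `city_id`, `gdp_per_capita`, `gini`,
#'   `hh_consumption_share`, `total_consumption_share`, `hdi`,
#'   `health_index`, `education_index`, `income_index`, `mean_latent_ses`.
#' @export
generate_context <- function(config, dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (!nrow(dataset$households)) abort("dataset is empty")
  idx <- attr(dataset, "city_index") %||% 1L
  mz <- mean(dataset$households$latent_ses)
  with_local_seed(derive_seed(config$seed, idx, offset = 1L), {
    gini <- runif(1, config$gini_range[1], config$gini_range[2])
    gdp_span <- config$gdp_pc_range
    gdp <- gdp_span[1] + (gdp_span[2] - gdp_span[1]) *
      plogis(1.5 * mz + rnorm(1, 0, 0.5))
    hh_share <- runif(1, 50, 75)
    total_share <- min(hh_share + runif(1, 5, 20), 100)
    sub <- function(a, b) pnorm(a + b * mz + rnorm(1, 0, config$hdi_noise_sd))
    health <- sub(0.45, 0.9)
    education <- sub(0.30, 0.8)
    income <- sub(0.15, 0.85)
    tibble::tibble(city_id = dataset$city_id,
                   gdp_per_capita = gdp,
                   gini = gini,
                   hh_consumption_share = hh_share,
                   total_consumption_share = total_share,
                   hdi = (health + education + income) / 3,
                   health_index = health,
                   education_index = education,
                   income_index = income,
                   mean_latent_ses = mz)
  })
}

#' Rebuild a scenario configuration from a written manifest
#'
#' Inverse of the manifest written by [write_scenario()]: reloading the
#' manifest and regenerating yields the identical scenario, byte for byte.
#'
#' @param path Path to a `manifest.json` written by [write_scenario()].
#' @return A [scenario_config()].
#' @export
read_scenario_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  scenario_config(
    n_cities = m$n_cities,
    households_per_city = m$households_per_city,
    latent_ses_sd = m$latent_ses_sd,
    asset_loadings = unlist(m$asset_loadings),
    asset_intercepts = unlist(m$asset_intercepts),
    electricity_loading = m$electricity_loading,
    electricity_intercept = m$electricity_intercept,
    wash_loading = m$wash_loading,
    roster_size_dist = unlist(m$roster_size_dist),
    education_gradient = m$education_gradient,
    school_attendance_gradient = m$school_attendance_gradient,
    gini_range = m$gini_range,
    gdp_pc_range = m$gdp_pc_range,
    hdi_noise_sd = m$hdi_noise_sd,
    seed = m$seed)
}

#' Generate a full multi-city scenario
#'
#' @param config A [scenario_config()].
#' @return An object of class `poverty_scenario`: list with `cities` (list of
#'   [survey_dataset()]), `contexts` (tibble, one row per city) and `config`.
#' @export
generate_scenario <- function(config = scenario_config()) {
  cities <- lapply(seq_len(config$n_cities), function(i)
    generate_city(config, i))
  contexts <- dplyr::bind_rows(lapply(cities, function(d)
    generate_context(config, d)))
  structure(list(cities = cities, contexts = contexts, config = config),
            class = "poverty_scenario")
}

#' @export
print.poverty_scenario <- function(x, ...) {
  n_hh <- sum(vapply(x$cities, function(d) nrow(d$households), integer(1)))
  cat(sprintf("<poverty_scenario> %d cities, %d households (seed %d)\n",
              length(x$cities), n_hh, x$config$seed))
  invisible(x)
}

#' Write a scenario to disk as CSV tables plus a manifest
#'
#' One household CSV, one person CSV and one context CSV per city, and a
#' `manifest.json` recording the full configuration (including the seed) so a
#' run can be reproduced exactly.
#'
#' @param scenario A [generate_scenario()] result.
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in scenario$cities) {
    write_survey(d, dir)
    readr::write_csv(scenario$contexts[scenario$contexts$city_id == d$city_id, ],
                     file.path(dir, paste0(d$city_id, "_context.csv")),
                     progress = FALSE)
  }
  manifest <- file.path(dir, "manifest.json")
  cfg <- lapply(unclass(scenario$config), function(x)
    if (!is.null(names(x))) as.list(x) else x)  # keep names in JSON objects
  jsonlite::write_json(c(cfg, list(package = "urbanpoverty")),
                       manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
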