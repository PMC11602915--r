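#' Lognormal sigma implied by a Gini index
#'
#' Under a lognormal income distribution the Gini index is
#' `G = 2 * pnorm(sigma / sqrt(2)) - 1`, so the scale parameter implied by an
#' observed Gini is `sigma = sqrt(2) * qnorm((G + 1) / 2)`. The round trip is
#' exact to numerical precision.
#'
#' @param gini Gini index in `[0, 1)`.
#' @return Nonnegative lognormal scale parameter.
#' @export
sigma_from_gini <- function(gini) {
  if (any(is.na(gini)) || any(gini < 0) || any(gini >= 1)) {
    abort("gini must lie in [0, 1)")
  }
  sqrt(2) * qnorm((gini + 1) / 2)
}

#' Gini index of a lognormal distribution with scale sigma
#' @param sigma Nonnegative lognormal scale parameter.
#' @return Gini index in `[0, 1)`.
#' @export
gini_from_sigma <- function(sigma) {
  if (any(sigma < 0)) abort("sigma must be nonnegative")
  2 * pnorm(sigma / sqrt(2)) - 1
}

#' Build the predicted-income model for a city
#'
#' The model predicts per-capita income from the household's position in the
#' wealth distribution, assuming incomes are lognormal with the city's
#' Gini-implied inequality and a mean anchored on GDP per capita corrected
#' for consumption expenditure. Two correction modes are available:
#' `consumption_ratio` (default) scales GDP per capita by the ratio of the
#' household consumption share to the total consumption share of GDP;
#' `hh_share_of_gdp` uses the household share directly as a fraction of GDP.
#'
#' @param context One-row city context (see [generate_context()]): needs
#'   `gdp_per_capita`, `gini`, `hh_consumption_share`,
#'   `total_consumption_share`.
#' @param mode `"consumption_ratio"` or `"hh_share_of_gdp"`.
#' @return A list of class `income_model`: `mean_income`, `sigma`, `mu`
#'   (lognormal location, so `mean = exp(mu + sigma^2/2)`), `gini`, `mode`.
#' @export
build_income_model <- function(context, mode = c("consumption_ratio",
                                                 "hh_share_of_gdp")) {
  mode <- match.arg(mode)
  if (context$hh_consumption_share <= 0 || context$total_consumption_share <= 0) {
    abort("consumption shares must be strictly positive")
  }
  mean_income <- switch(mode,
    consumption_ratio = context$gdp_per_capita *
      context$hh_consumption_share / context$total_consumption_share,
    hh_share_of_gdp = context$gdp_per_capita *
      context$hh_consumption_share / 100)
  sigma <- sigma_from_gini(context$gini)
  structure(list(mean_income = mean_income,
                 sigma = sigma,
                 mu = log(mean_income) - sigma^2 / 2,
                 gini = context$gini,
                 mode = mode),
            class = "income_model")
}

#' Predicted annual income at a wealth-distribution rank
#'
#' The lognormal quantile at the household's wealth percentile:
#' `exp(mu + sigma * qnorm(rank))`. Strictly increasing in rank, and its
#' integral over ranks recovers the model mean. Ranks of exactly 0 or 1 are
#' clamped to `[eps, 1 - eps]`.
#'
#' @param model An [build_income_model()] result.
#' @param rank Numeric ranks in (0, 1).
#' @param eps Clamping margin for boundary ranks; callers working with a city
#'   of n households use `1 / (2n)` (the smallest mid-distribution rank),
#'   capped at 1e-4 so interior ranks are never disturbed.
#' @return Predicted annual income (currency/year) at each rank.
#' @export
predicted_income_at_rank <- function(model, rank, eps = 1e-6) {
  stopifnot(inherits(model, "income_model"))
  if (any(is.na(rank)) || any(rank < 0) || any(rank > 1)) {
    abort("rank must lie in [0, 1]")
  }
  rank <- clamp(rank, eps, 1 - eps)
  exp(model$mu + model$sigma * qnorm(rank))
}

#' Classify households as below the poverty line
#'
#' Converts each household's predicted income into a daily amount and flags
#' households strictly below the line (default US$ 1.9/day). In the default
#' `household` mode the model prediction at the household's wealth rank is
#' read as household income and divided by the number of members and by
#' 365.25; in `percapita` mode the prediction is read as per-capita income
#' and only the day conversion applies.
#'
#' @param rank Wealth-distribution rank per household in (0, 1).
#' @param n_members Household sizes (>= 1).
#' @param model An [build_income_model()] result.
#' @param line Poverty line in currency per person per day.
#' @param division `"household"` (divide by members; the headline convention)
#'   or `"percapita"`.
#' @return Logical vector, `TRUE` = below the line.
#' @export
classify_below_poverty_line <- function(rank, n_members, model, line = 1.9,
                                        division = c("household", "percapita")) {
  division <- match.arg(division)
  eps <- min(1 / (2 * length(rank)), 1e-4)
  income <- predicted_income_at_rank(model, rank, eps = eps)
  daily <- switch(division,
                  household = income / n_members / 365.25,
                  percapita = income / 365.25)
  daily < line
}

# ---- Socioeconomic deprivation status (SDS) --------------------------------

#' Default SDS weights: nested equal weights over two dimensions
#'
#' Education (2 indicators) and living standards (6 indicators) each carry
#' half the total weight, so education indicators weigh 1/4 each and living
#' standards indicators 1/12 each.
#' @return Named numeric vector over the 8 deprivations, summing to 1.
#' @export
sds_weights <- function() {
  c(child_out_of_school = 1 / 4, no_educated_member = 1 / 4,
    no_electricity = 1 / 12, no_improved_water = 1 / 12,
    no_improved_sanitation = 1 / 12, poor_housing = 1 / 12,
    asset_deprived = 1 / 12, dirty_cooking_fuel = 1 / 12)
}

#' Socioeconomic deprivation status per household
#'
#' Eight binary deprivations: two educational (a school-aged child out of
#' school; no member aged 10+ with at least six completed years of education)
#' and six living standards (no electricity; no improved drinking water; no
#' adequate sanitation; non-durable housing materials; ownership of at most
#' one small asset and no car; dirty cooking fuel). The weighted deprivation
#' score lies in `[0, 1]` and a household is deprived when the score reaches
#' the threshold (default 1/3). Households whose roster is absent (so the
#' education indicators cannot be evaluated) get an NA score and flag.
#'
#' @param outcomes Household outcome tibble from [compute_outcomes()]
#'   (supplies the education and WASH deprivations).
#' @param households Household tibble (supplies housing, assets, fuel).
#' @param weights Deprivation weights, see [sds_weights()].
#' @param threshold Deprivation cut-off on the score, default 1/3.
#' @param dict Variable dictionary.
#' @return Tibble: `household_id`, the 8 deprivation booleans, `sds_score`,
#'   `sds_deprived`.
#' @export
sds_profile <- function(outcomes, households, weights = sds_weights(),
                        threshold = 1 / 3, dict = variable_dictionary()) {
  if (abs(sum(weights) - 1) > 1e-9) abort("SDS weights must sum to 1")
  hh <- households
  small <- paste0("asset_", intersect(dict$small_assets,
                                      sub("^asset_", "", grep("^asset_", names(hh),
                                                              value = TRUE))))
  n_small <- rowSums(dplyr::mutate(hh[small], dplyr::across(
    dplyr::everything(), as.numeric)))
  has_car <- if ("asset_car" %in% names(hh)) hh$asset_car else FALSE
  d <- tibble::tibble(
    household_id = hh$household_id,
    child_out_of_school = outcomes$out_of_school[match(hh$household_id,
                                                       outcomes$household_id)],
    no_educated_member = outcomes$low_education[match(hh$household_id,
                                                      outcomes$household_id)],
    no_electricity = outcomes$no_electricity[match(hh$household_id,
                                                   outcomes$household_id)],
    no_improved_water = outcomes$no_improved_water[match(hh$household_id,
                                                         outcomes$household_id)],
    no_improved_sanitation = outcomes$no_improved_sanitation[match(hh$household_id,
                                                                   outcomes$household_id)],
    poor_housing = !(hh$floor_material %in% codes_of(dict$floor_materials, "durable") &
                       hh$wall_material %in% codes_of(dict$wall_materials, "durable") &
                       hh$roof_material %in% codes_of(dict$roof_materials, "durable")),
    asset_deprived = n_small <= 1 & !has_car,
    dirty_cooking_fuel = !(hh$cooking_fuel %in% codes_of(dict$cooking_fuels, "clean"))
  )
  dep_mat <- as.matrix(dplyr::mutate(d[names(weights)], dplyr::across(
    dplyr::everything(), as.numeric)))
  d$sds_score <- as.numeric(dep_mat %*% weights)
  d$sds_deprived <- d$sds_score >= threshold
  d
}

# ---- UN-Habitat slum classification ----------------------------------------

#' UN-Habitat slum profile per household
#'
#' A household is a slum household if it lacks any of: durable housing
#' (floor, wall and roof all of durable materials), sufficient living space
#' (at most 3 persons per room), easy access to safe water (improved source
#' with a round-trip fetch under the time threshold), or adequate sanitation
#' (improved facility not shared with other households). Security of tenure,
#' the fifth criterion of the full definition, is not measurable in these
#' surveys and is omitted. Households with any required input missing are
#' excluded (NA flag) rather than counted as slum.
#'
#' @param households Household tibble.
#' @param time_threshold_min Round-trip water-fetch threshold in minutes;
#'   times at or above it make an improved source unsafe. Default 30.
#' @param dict Variable dictionary.
#' @return Tibble: `household_id`, the four criterion booleans (`TRUE` =
#'   criterion met), `slum`.
#' @export
slum_profile <- function(households, time_threshold_min = 30,
                         dict = variable_dictionary()) {
  hh <- households
  durable_housing <- hh$floor_material %in% codes_of(dict$floor_materials, "durable") &
    hh$wall_material %in% codes_of(dict$wall_materials, "durable") &
    hh$roof_material %in% codes_of(dict$roof_materials, "durable")
  sufficient_space <- hh$persons_per_room <= 3
  improved_water <- hh$water_source %in% codes_of(dict$water_sources, "improved")
  time_ok <- is.na(hh$time_to_water) | hh$time_to_water < time_threshold_min
  safe_water <- ifelse(is.na(hh$water_source), NA, improved_water & time_ok)
  improved_san <- hh$sanitation_type %in% codes_of(dict$sanitation_types, "improved")
  adequate_sanitation <- ifelse(is.na(hh$sanitation_type), NA,
                                ifelse(!improved_san, FALSE,
                                       ifelse(is.na(hh$sanitation_shared), NA,
                                              !hh$sanitation_shared)))
  slum <- !(durable_housing & sufficient_space & safe_water & adequate_sanitation)
  # any criterion definitely failed => slum, even if another is missing
  any_failed <- (!durable_housing & !is.na(durable_housing)) |
    (!sufficient_space & !is.na(sufficient_space)) |
    (!safe_water & !is.na(safe_water)) |
    (!adequate_sanitation & !is.na(adequate_sanitation))
  slum[any_failed] <- TRUE
  tibble::tibble(household_id = hh$household_id,
                 durable_housing = durable_housing,
                 sufficient_space = sufficient_space,
                 safe_water = safe_water,
                 adequate_sanitation = adequate_sanitation,
                 slum = slum)
}
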