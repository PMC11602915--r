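#' Household welfare outcome indicators
#'
#' Computes the five household-level outcomes used throughout the analysis,
#' each a boolean where `TRUE` marks the adverse state:
#'
#' * `out_of_school` — at least one school-aged child (default ages 6-14) in
#'   the household does not attend school. Households with no school-aged
#'   children count as not deprived (the prevalence denominator keeps them).
#' * `low_education` — under the default `no_member` reading, no household
#'   member aged 10 or older has completed at least six years of education;
#'   under the `any_member` reading, at least one member older than 10 has
#'   fewer than six years. Missing (NA) when no member reaches the age bound.
#' * `no_electricity` — the household lacks electricity; NA when unrecorded.
#' * `no_improved_water` — the drinking-water source is unimproved, or
#'   improved but at a round-trip fetch of `water_time_threshold` minutes or
#'   longer. A missing fetch time on an improved source is treated as within
#'   the threshold.
#' * `no_improved_sanitation` — the sanitation facility is unimproved, absent,
#'   or improved but shared with other households. NA when the shared flag is
#'   missing on an improved facility.
#'
#' Each outcome is a pure function of the household row and its roster;
#' roster order never matters.
#'
#' @param households Household tibble.
#' @param persons Person roster tibble.
#' @param school_age `[min, max]` ages counted as school-aged.
#' @param water_time_threshold Round-trip minutes at or above which an
#'   improved source no longer counts as easy access. Default 30.
#' @param low_education_mode `"no_member"` (default) or `"any_member"`.
#' @param dict Variable dictionary.
#' @return Tibble with `household_id` and the five outcome booleans.
#' @export
compute_outcomes <- function(households, persons,
                             school_age = c(6, 14),
                             water_time_threshold = 30,
                             low_education_mode = c("no_member", "any_member"),
                             dict = variable_dictionary()) {
  low_education_mode <- match.arg(low_education_mode)
  hh_id <- households$household_id

  # education indicators from the roster
  p <- persons
  p_school <- p[!is.na(p$age_years) & p$age_years >= school_age[1] &
                  p$age_years <= school_age[2], ]
  out_ids <- unique(p_school$household_id[!is.na(p_school$in_school) &
                                            !p_school$in_school])
  out_of_school <- hh_id %in% out_ids

  p_adult <- p[!is.na(p$age_years) & p$age_years >= 10, ]
  if (low_education_mode == "no_member") {
    educated <- unique(p_adult$household_id[p_adult$edu_years >= 6])
    has_adult <- hh_id %in% unique(p_adult$household_id)
    low_education <- ifelse(has_adult, !(hh_id %in% educated), NA)
  } else {
    p_over10 <- p[!is.na(p$age_years) & p$age_years > 10, ]
    low_ids <- unique(p_over10$household_id[p_over10$edu_years < 6])
    has_adult <- hh_id %in% unique(p_over10$household_id)
    low_education <- ifelse(has_adult, hh_id %in% low_ids, NA)
  }

  no_electricity <- ifelse(is.na(households$electricity), NA,
                           !households$electricity)

  improved <- households$water_source %in% codes_of(dict$water_sources, "improved")
  far <- !is.na(households$time_to_water) &
    households$time_to_water >= water_time_threshold
  no_improved_water <- ifelse(is.na(households$water_source), NA,
                              !improved | (improved & far))

  san_class <- unname(dict$sanitation_types[households$sanitation_type])
  no_improved_sanitation <- ifelse(
    is.na(households$sanitation_type), NA,
    ifelse(san_class != "improved", TRUE,
           ifelse(is.na(households$sanitation_shared), NA,
                  households$sanitation_shared)))

  tibble::tibble(household_id = hh_id,
                 out_of_school = out_of_school,
                 low_education = low_education,
                 no_electricity = no_electricity,
                 no_improved_water = no_improved_water,
                 no_improved_sanitation = no_improved_sanitation)
}

#' Names of the five outcome indicators
#' @return Character vector in canonical order.
#' @export
outcome_names <- function() {
  c("out_of_school", "low_education", "no_electricity",
    "no_improved_water", "no_improved_sanitation")
}
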