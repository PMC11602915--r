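#' Construct a validated single-city survey dataset
#'
#' Bundles the household table and the person roster for one city and enforces
#' the structural invariants every downstream stage relies on: strictly
#' positive sampling weights, household sizes of at least one, every roster
#' member linked to an existing household, and roster sizes consistent with
#' the household `n_members` field when a roster is present.
#'
#' @param households Tibble with one row per household. Mandatory columns:
#'   `household_id`, `city_id`, `weight`, `n_members`. Classification stages
#'   additionally use `electricity`, `water_source`, `time_to_water`,
#'   `sanitation_type`, `sanitation_shared`, `cooking_fuel`,
#'   `floor_material`, `wall_material`, `roof_material`, `persons_per_room`
#'   and `asset_*` columns.
#' @param persons Tibble with one row per roster member: `person_id`,
#'   `household_id`, `age_years`, `edu_years`, `in_school`.
#' @param city_id Single city identifier; defaults to the one present in
#'   `households`.
#' @return An object of class `survey_dataset`: a list with elements
#'   `city_id`, `households`, `persons`.
#' @export
survey_dataset <- function(households, persons, city_id = NULL) {
  households <- tibble::as_tibble(households)
  persons <- tibble::as_tibble(persons)
  mandatory <- c("household_id", "city_id", "weight", "n_members")
  missing_cols <- setdiff(mandatory, names(households))
  if (length(missing_cols)) {
    abort(paste0("household table is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "urbanpoverty_mapping_error")
  }
  city_id <- city_id %||% unique(households$city_id)
  if (length(city_id) != 1L) {
    abort("a survey_dataset holds exactly one city; got multiple city_id values")
  }
  if (any(is.na(households$weight)) || any(households$weight <= 0)) {
    abort("sampling weights must be strictly positive and nonmissing")
  }
  if (any(households$n_members < 1L)) {
    abort("household sizes (n_members) must be >= 1")
  }
  if (anyDuplicated(households$household_id)) {
    abort("duplicate household_id in household table")
  }
  if (nrow(persons)) {
    orphan <- setdiff(unique(persons$household_id), households$household_id)
    if (length(orphan)) {
      abort(paste0("person rows reference unknown household_id(s): ",
                   paste(head(orphan, 5), collapse = ", ")),
            class = "urbanpoverty_integrity_error")
    }
    roster_n <- table(persons$household_id)
    hh_n <- households$n_members[match(names(roster_n), households$household_id)]
    if (any(hh_n != as.integer(roster_n))) {
      abort("n_members disagrees with roster size for at least one household",
            class = "urbanpoverty_integrity_error")
    }
    if (any(persons$age_years < 0 | persons$age_years > 110, na.rm = TRUE)) {
      abort("person age_years must lie in [0, 110]")
    }
    if (any(persons$edu_years > persons$age_years, na.rm = TRUE)) {
      abort("edu_years may not exceed age_years")
    }
  }
  structure(list(city_id = city_id, households = households, persons = persons),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf("<survey_dataset> city %s: %d households, %d roster members\n",
              x$city_id, nrow(x$households), nrow(x$persons)))
  invisible(x)
}

#' Survey-weighted prevalence of a household indicator
#'
#' Point estimate of the weighted share of households for which a boolean
#' indicator holds: sum(w * x) / sum(w) over the (optionally subset) rows with
#' a nonmissing indicator. Households with a missing indicator are excluded
#' from numerator and denominator alike, and the unweighted count actually
#' used is returned alongside the estimate for transparency. No
#' design-based variance is attached; these are point estimates.
#'
#' @param indicator Logical vector, one element per household; may contain NA.
#' @param weights Strictly positive numeric weights, same length.
#' @param subset Optional logical mask selecting the estimation domain.
#' @return A list with `estimate` (proportion in \[0, 1\]), `n` (unweighted
#'   number of households contributing) and `n_excluded` (rows dropped for a
#'   missing indicator within the domain).
#' @examples
#' weighted_prevalence(c(TRUE, FALSE), weights = c(1, 3))$estimate  # 0.25
#' @export
weighted_prevalence <- function(indicator, weights, subset = NULL) {
  if (length(indicator) != length(weights)) {
    abort("indicator and weights must have equal length")
  }
  if (any(weights <= 0, na.rm = TRUE)) abort("weights must be strictly positive")
  keep <- if (is.null(subset)) rep(TRUE, length(indicator)) else subset
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) {
    abort("empty estimation domain: subset selects no households",
          class = "urbanpoverty_empty_domain")
  }
  x <- indicator[keep]
  w <- weights[keep]
  ok <- !is.na(x)
  if (!any(ok)) {
    abort("empty estimation domain: indicator missing for every selected household",
          class = "urbanpoverty_empty_domain")
  }
  list(estimate = sum(w[ok] * as.numeric(x[ok])) / sum(w[ok]),
       n = sum(ok),
       n_excluded = sum(!ok))
}

#' Weighted mid-distribution percentile ranks
#'
#' Position of every household in the weighted distribution of a score,
#' expressed in (0, 1). The rank of a household is the cumulative weight of
#' households scoring strictly below it, plus half the weight of those tied
#' with it, divided by the total weight. This mid-distribution convention
#' makes ranks deterministic and order-independent under ties and invariant
#' to rescaling all weights by a constant.
#'
#' @param score Numeric score per household; NA scores yield NA ranks (and are
#'   excluded from the distribution).
#' @param weights Strictly positive weights, same length as `score`.
#' @return Numeric vector of ranks in (0, 1), NA where `score` is NA.
#' @examples
#' weighted_quantile_rank(c(1, 1, 2), rep(1, 3))  # 1/3, 1/3, 5/6
#' @export
weighted_quantile_rank <- function(score, weights) {
  if (length(score) != length(weights)) {
    abort("score and weights must have equal length")
  }
  if (all(is.na(score))) abort("cannot rank: score is missing for all households")
  ok <- !is.na(score)
  s <- score[ok]
  w <- weights[ok]
  total <- sum(w)
  o <- order(s)
  grp <- cumsum(!duplicated(s[o]))  # tie groups are adjacent once sorted
  wv <- as.numeric(rowsum(w[o], grp))
  cum_below <- cumsum(c(0, wv[-length(wv)]))
  rank_by_group <- (cum_below + wv / 2) / total
  ranks_sorted <- rank_by_group[grp]
  res <- numeric(length(s))
  res[o] <- ranks_sorted
  out <- rep(NA_real_, length(score))
  out[ok] <- res
  out
}

#' Read a column-mapping configuration
#'
#' A column mapping translates an arbitrary survey export into the canonical
#' variable names of this package. The YAML file has `household` and `person`
#' sections, each with a `columns` map (canonical name -> source column), an
#' optional `assets` map for the household table (canonical asset name ->
#' source column), and an optional `recodes` map (canonical variable -> map of
#' source code -> dictionary code).
#'
#' @param path Path to the mapping YAML.
#' @return A list with `household` and `person` mapping specs.
#' @export
read_column_mapping <- function(path) {
  m <- yaml::read_yaml(path)
  for (section in c("household", "person")) {
    m[[section]]$columns <- lapply(m[[section]]$columns, as.character)
    m[[section]]$recodes <- lapply(m[[section]]$recodes, function(r) {
      setNames(as.character(unlist(r)), names(unlist(r)))
    })
  }
  m$household$assets <- lapply(m$household$assets, as.character)
  m
}

apply_mapping_section <- function(df, section, what, dict) {
  cols <- section$columns
  missing_src <- setdiff(unlist(cols), names(df))
  if (length(missing_src)) {
    abort(sprintf("%s table is missing mapped source column(s): %s",
                  what, paste(missing_src, collapse = ", ")),
          class = "urbanpoverty_mapping_error")
  }
  out <- df[unlist(cols)]
  names(out) <- names(cols)
  for (var in names(section$recodes)) {
    rec <- section$recodes[[var]]
    src <- as.character(out[[var]])
    hit <- src %in% names(rec)
    bad <- !hit & !is.na(src) & !(src %in% unname(rec))
    if (any(bad)) {
      abort(sprintf("recode error for `%s`: unknown source code(s) %s (first offending row %d)",
                    var, paste(unique(src[bad])[1:min(3, length(unique(src[bad])))], collapse = ", "),
                    which(bad)[1]),
            class = "urbanpoverty_recode_error")
    }
    out[[var]] <- ifelse(hit, unname(rec[src]), src)
  }
  tibble::as_tibble(out)
}

#' Read a household survey from delimited files via a column mapping
#'
#' Reads the household and person CSV tables, renames and recodes columns to
#' the canonical schema, validates category codes against the variable
#' dictionary, and returns a validated [survey_dataset()]. Row counts are
#' preserved; optional variables left unmapped are simply absent.
#'
#' @param household_path,person_path CSV file paths.
#' @param mapping A mapping as returned by [read_column_mapping()].
#' @param dict Variable dictionary, defaults to [variable_dictionary()].
#' @return A [survey_dataset()].
#' @export
read_survey <- function(household_path, person_path, mapping,
                        dict = variable_dictionary()) {
  hh_raw <- readr::read_csv(household_path, show_col_types = FALSE,
                            progress = FALSE)
  pp_raw <- readr::read_csv(person_path, show_col_types = FALSE,
                            progress = FALSE)
  hh <- apply_mapping_section(hh_raw, mapping$household, "household", dict)
  for (asset in names(mapping$household$assets)) {
    src <- mapping$household$assets[[asset]]
    if (!src %in% names(hh_raw)) {
      abort(sprintf("household table is missing asset column `%s`", src),
            class = "urbanpoverty_mapping_error")
    }
    hh[[paste0("asset_", asset)]] <- as.logical(hh_raw[[src]])
  }
  pp <- apply_mapping_section(pp_raw, mapping$person, "person", dict)
  validate_category_codes(hh, dict)
  for (col in c("electricity", "sanitation_shared")) {
    if (col %in% names(hh)) hh[[col]] <- as.logical(hh[[col]])
  }
  if ("in_school" %in% names(pp)) pp$in_school <- as.logical(pp$in_school)
  survey_dataset(hh, pp)
}

validate_category_codes <- function(hh, dict) {
  checks <- list(water_source = dict$water_sources,
                 sanitation_type = dict$sanitation_types,
                 floor_material = dict$floor_materials,
                 wall_material = dict$wall_materials,
                 roof_material = dict$roof_materials,
                 cooking_fuel = dict$cooking_fuels)
  for (var in names(checks)) {
    if (!var %in% names(hh)) next
    vals <- unique(stats::na.omit(hh[[var]]))
    bad <- setdiff(vals, names(checks[[var]]))
    if (length(bad)) {
      abort(sprintf("unknown %s code(s) not in the variable dictionary: %s",
                    var, paste(head(bad, 5), collapse = ", ")),
            class = "urbanpoverty_recode_error")
    }
  }
  invisible(hh)
}

#' Write a single-city dataset to CSV files
#'
#' @param dataset A [survey_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (household, person).
#' @export
write_survey <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hh_path <- file.path(dir, paste0(dataset$city_id, "_households.csv"))
  pp_path <- file.path(dir, paste0(dataset$city_id, "_persons.csv"))
  readr::write_csv(dataset$households, hh_path, progress = FALSE)
  readr::write_csv(dataset$persons, pp_path, progress = FALSE)
  invisible(c(households = hh_path, persons = pp_path))
}
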