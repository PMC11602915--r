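#' Group prevalences and gaps for one city under one measure
#'
#' Weighted prevalence of each outcome within the poor group, within the rich
#' group, and overall, with unweighted group sizes and the gap
#' `rich - poor` in proportion units (multiply by 100 for percentage
#' points; negative when the poor fare worse). An empty group yields missing
#' prevalences with a diagnostic flag rather than zero.
#'
#' @param labels One city's [poverty_labels()] table.
#' @param measure Measure id, e.g. `"w40"`.
#' @param outcomes Outcome names.
#' @return Tibble, one row per outcome: `city_id`, `outcome`, `prev_poor`,
#'   `prev_rich`, `prev_overall`, `gap`, `n_poor`, `n_rich`, `empty_group`.
#' @export
group_prevalences <- function(labels, measure = "w40",
                              outcomes = outcome_names()) {
  col <- paste0("poor_", measure)
  poor <- labels[[col]]
  dplyr::bind_rows(lapply(outcomes, function(oc) {
    x <- labels[[oc]]
    w <- labels$weight
    est <- function(mask) {
      if (!any(mask & !is.na(x))) return(list(estimate = NA_real_, n = 0L))
      weighted_prevalence(x, w, subset = mask)
    }
    p <- est(!is.na(poor) & poor)
    r <- est(!is.na(poor) & !poor)
    o <- est(!is.na(poor))
    tibble::tibble(city_id = labels$city_id[1],
                   outcome = oc,
                   prev_poor = p$estimate,
                   prev_rich = r$estimate,
                   prev_overall = o$estimate,
                   gap = r$estimate - p$estimate,
                   n_poor = p$n,
                   n_rich = r$n,
                   empty_group = p$n == 0L || r$n == 0L)
  }))
}

#' Performance classification bands
#'
#' @param prev_low,prev_high Prevalence band edges in percent: prevalence
#'   below `prev_low` is low, `prev_low` to `prev_high` (inclusive both ends)
#'   intermediate, above `prev_high` high.
#' @param gap_low Inequality band half-width in percentage points: gaps with
#'   absolute value at or below it are low inequality, outside high.
#' @return List of class `performance_rule`.
#' @export
performance_rule <- function(prev_low = 5, prev_high = 15, gap_low = 5) {
  structure(list(prev_low = prev_low, prev_high = prev_high,
                 gap_low = gap_low),
            class = "performance_rule")
}

#' Classify a city's performance on one outcome
#'
#' Combines the prevalence band and the inequality band: low prevalence with
#' low inequality is a good performer; intermediate prevalence with low
#' inequality, or low prevalence with high inequality, is intermediate; high
#' or intermediate prevalence with high inequality is a worse performer.
#' High prevalence with low inequality — a combination the narrative rule
#' leaves unassigned — is classed worse, since a high burden cannot be good;
#' the decision record flags when it fires. Band edges: prevalences of
#' exactly `prev_low` or `prev_high` are intermediate, and an absolute gap of
#' exactly `gap_low` is low inequality.
#'
#' @param prevalence Prevalence in percent, in `[0, 100]`.
#' @param gap Rich-minus-poor gap in percentage points, in `[-100, 100]`.
#' @param rule A [performance_rule()].
#' @return Character vector over `{"good", "intermediate", "worse"}` (NA for
#'   missing inputs).
#' @export
classify_performance <- function(prevalence, gap, rule = performance_rule()) {
  if (any(prevalence < 0 | prevalence > 100, na.rm = TRUE)) {
    abort("prevalence must lie in [0, 100] percent")
  }
  if (any(abs(gap) > 100, na.rm = TRUE)) {
    abort("gap must lie in [-100, 100] percentage points")
  }
  prev_band <- ifelse(prevalence < rule$prev_low, "low",
                      ifelse(prevalence <= rule$prev_high, "intermediate",
                             "high"))
  low_ineq <- abs(gap) <= rule$gap_low
  out <- ifelse(prev_band == "low" & low_ineq, "good",
         ifelse(prev_band == "intermediate" & low_ineq, "intermediate",
         ifelse(prev_band == "low" & !low_ineq, "intermediate",
                "worse")))
  out[is.na(prevalence) | is.na(gap)] <- NA_character_
  out
}

#' City-by-outcome performance table
#'
#' Applies [classify_performance()] to every city and outcome and appends
#' per-city counts of good/intermediate/worse cells. Prevalence defaults to
#' the overall weighted prevalence of the outcome in the city
#' (`prevalence_basis = "overall"`); `"poor"` uses the poor-group prevalence
#' instead.
#'
#' @param summaries Row-bound [group_prevalences()] tables for all cities.
#' @param rule A [performance_rule()].
#' @param prevalence_basis `"overall"` or `"poor"`.
#' @return List: `table` (wide tibble city x outcome classes plus class
#'   counts), `long` (tidy city x outcome tibble with inputs and class).
#' @export
performance_table <- function(summaries, rule = performance_rule(),
                              prevalence_basis = c("overall", "poor")) {
  prevalence_basis <- match.arg(prevalence_basis)
  prev_col <- switch(prevalence_basis, overall = "prev_overall",
                     poor = "prev_poor")
  long <- summaries |>
    dplyr::mutate(prev_pct = 100 * .data[[prev_col]],
                  gap_pp = 100 * .data$gap,
                  class = classify_performance(.data$prev_pct, .data$gap_pp,
                                               rule)) |>
    dplyr::select("city_id", "outcome", "prev_pct", "gap_pp", "class")
  wide <- long |>
    dplyr::select("city_id", "outcome", "class") |>
    tidyr::pivot_wider(names_from = "outcome", values_from = "class")
  cls <- as.matrix(wide[, -1])
  wide$n_good <- rowSums(cls == "good", na.rm = TRUE)
  wide$n_intermediate <- rowSums(cls == "intermediate", na.rm = TRUE)
  wide$n_worse <- rowSums(cls == "worse", na.rm = TRUE)
  list(table = wide, long = long)
}

#' Pearson correlations of city results with development indices
#'
#' For every outcome, each of the three city-level statistics (poor-group
#' prevalence, rich-group prevalence, rich-minus-poor gap) is correlated
#' across cities with each development index (HDI and its health, education
#' and income components). Confidence intervals use the Fisher
#' z-transform: `tanh(atanh(r) +/- 1.96 / sqrt(n - 3))`. Cells where either
#' variable is constant across cities are flagged undefined.
#'
#' @param summaries Row-bound [group_prevalences()] tables.
#' @param contexts City context tibble with `hdi`, `health_index`,
#'   `education_index`, `income_index`.
#' @return Tibble: `outcome`, `statistic`, `index`, `r`, `ci_low`, `ci_high`,
#'   `n`, `undefined`.
#' @export
context_correlations <- function(summaries, contexts) {
  stats_map <- c(prev_poor = "prev_poor", prev_rich = "prev_rich",
                 gap = "gap")
  idx_map <- c(hdi = "hdi", health = "health_index",
               education = "education_index", income = "income_index")
  joined <- dplyr::left_join(summaries, contexts, by = "city_id")
  grid <- tidyr::expand_grid(outcome = unique(summaries$outcome),
                             statistic = names(stats_map),
                             index = names(idx_map))
  purrr::pmap_dfr(grid, function(outcome, statistic, index) {
    df <- joined[joined$outcome == outcome, ]
    x <- df[[stats_map[[statistic]]]]
    y <- df[[idx_map[[index]]]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 4 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(tibble::tibble(outcome = outcome, statistic = statistic,
                            index = index, r = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, n = n, undefined = TRUE))
    }
    r <- cor(x[ok], y[ok])
    z <- atanh(clamp(r, -1 + 1e-15, 1 - 1e-15))
    half <- 1.96 / sqrt(n - 3)
    # the interval always contains the point estimate, including at |r| = 1
    tibble::tibble(outcome = outcome, statistic = statistic, index = index,
                   r = r, ci_low = min(tanh(z - half), r),
                   ci_high = max(tanh(z + half), r),
                   n = n, undefined = FALSE)
  })
}
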