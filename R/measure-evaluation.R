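#' Catalogue of the seven poverty measures
#'
#' @return Tibble with `id` and `kind` (`relative` or `absolute`), in the
#'   canonical order: poverty line, SDS, slum, then the four wealth cut-offs.
#' @export
measure_catalog <- function() {
  tibble::tibble(
    id = c("pline", "sds", "slum", "w30", "w40", "w50", "w60"),
    kind = c("absolute", "absolute", "absolute",
             "relative", "relative", "relative", "relative"))
}

#' Apply all seven poverty classifiers to one city
#'
#' Computes the wealth score (or validates and reuses a survey-provided one),
#' derives the weighted wealth ranks, and attaches the four relative labels
#' (`poor_w30` ... `poor_w60`), the predicted-income poverty-line label
#' (`poor_pline`), the deprivation-score label (`poor_sds`) and the slum
#' label (`poor_slum`).
#'
#' @param dataset A [survey_dataset()].
#' @param context One-row context tibble for the same city.
#' @param cutoffs Relative cut-off percentages.
#' @param line Poverty line, currency per person per day.
#' @param division Poverty-line member-division mode, see
#'   [classify_below_poverty_line()].
#' @param wealth A [wealth_spec()].
#' @param use_provided_threshold Correlation gate for adopting a
#'   survey-provided `wealth_score` column, see [validate_against_provided()].
#' @param sds_threshold Deprivation-score cut-off.
#' @param low_education_mode Passed to [compute_outcomes()].
#' @param dict Variable dictionary.
#' @return Tibble, one row per household: ids, `weight`, `wealth_score`,
#'   `wealth_rank`, seven `poor_*` labels and the five outcome columns.
#' @export
poverty_labels <- function(dataset, context,
                           cutoffs = c(30, 40, 50, 60),
                           line = 1.9,
                           division = "household",
                           wealth = wealth_spec(),
                           use_provided_threshold = 0.95,
                           sds_threshold = 1 / 3,
                           low_education_mode = "no_member",
                           dict = variable_dictionary()) {
  hh <- dataset$households
  score <- compute_wealth_score(hh, wealth, dict)
  if ("wealth_score" %in% names(hh) && !all(is.na(hh$wealth_score))) {
    val <- validate_against_provided(score, hh$wealth_score,
                                     threshold = use_provided_threshold)
    if (val$use_provided) {
      score <- if (val$flipped) -hh$wealth_score else hh$wealth_score
    }
  }
  rank <- weighted_quantile_rank(score, hh$weight)
  out <- tibble::tibble(household_id = hh$household_id,
                        city_id = hh$city_id,
                        weight = hh$weight,
                        n_members = hh$n_members,
                        wealth_score = score,
                        wealth_rank = rank)
  for (c_pct in cutoffs) {
    out[[sprintf("poor_w%d", c_pct)]] <-
      classify_relative_poor(score, hh$weight, c_pct)
  }
  model <- build_income_model(context)
  out$poor_pline <- classify_below_poverty_line(rank, hh$n_members, model,
                                                line = line,
                                                division = division)
  outcomes <- compute_outcomes(hh, dataset$persons,
                               low_education_mode = low_education_mode,
                               dict = dict)
  sds <- sds_profile(outcomes, hh, threshold = sds_threshold, dict = dict)
  out$poor_sds <- sds$sds_deprived[match(out$household_id, sds$household_id)]
  slum <- slum_profile(hh, dict = dict)
  out$poor_slum <- slum$slum[match(out$household_id, slum$household_id)]
  dplyr::left_join(out, outcomes, by = "household_id")
}

#' Poorest-group sample sizes across cities
#'
#' For every measure, the unweighted count of households labelled poor in
#' each city and that count as a percentage of the city sample, summarised
#' across cities by median, quartiles, minimum and maximum (each city counts
#' once; no weighting across cities).
#'
#' @param labels Row-bound [poverty_labels()] tables for all cities.
#' @param measures Measure ids, default the full catalogue.
#' @return Tibble: `measure`, `stat` (`count` or `share_pct`), `median`,
#'   `p25`, `p75`, `min`, `max`.
#' @export
poorest_group_sizes <- function(labels, measures = measure_catalog()$id) {
  per_city <- dplyr::bind_rows(lapply(measures, function(m) {
    col <- paste0("poor_", m)
    labels |>
      dplyr::group_by(.data$city_id) |>
      dplyr::summarise(count = sum(.data[[col]], na.rm = TRUE),
                       share_pct = 100 * .data$count /
                         sum(!is.na(.data[[col]])),
                       .groups = "drop") |>
      dplyr::mutate(measure = m)
  }))
  per_city |>
    tidyr::pivot_longer(c("count", "share_pct"), names_to = "stat") |>
    dplyr::group_by(.data$measure, .data$stat) |>
    dplyr::summarise(median = median(.data$value),
                     p25 = unname(quantile(.data$value, 0.25)),
                     p75 = unname(quantile(.data$value, 0.75)),
                     min = min(.data$value),
                     max = max(.data$value),
                     .groups = "drop")
}

#' Observed agreement between two poverty classifications
#'
#' Share of households assigned the same poor/rich label by both measures,
#' over their nonmissing overlap. Unweighted by default; pass `weights` for
#' the weighted variant.
#'
#' @param labels_a,labels_b Logical vectors.
#' @param weights Optional positive weights for a weighted agreement.
#' @return Proportion in `[0, 1]`.
#' @export
observed_agreement <- function(labels_a, labels_b, weights = NULL) {
  ok <- !is.na(labels_a) & !is.na(labels_b)
  if (!any(ok)) abort("no households with both labels nonmissing",
                      class = "urbanpoverty_empty_domain")
  same <- labels_a[ok] == labels_b[ok]
  if (is.null(weights)) mean(same) else weighted.mean(same, weights[ok])
}

#' Per-city agreement between relative and absolute measures
#'
#' @param labels Row-bound [poverty_labels()] tables.
#' @param threshold Adequacy threshold on the median agreement, default 0.60.
#' @param weighted Use weighted agreement within city. Default unweighted.
#' @return List with `per_city` (tibble city x pair agreement), `medians`
#'   (tibble: relative measure, absolute measure, median agreement, pass) and
#'   `pass_all` (per relative measure: all medians at or above threshold).
#' @export
agreement_summary <- function(labels, threshold = 0.60, weighted = FALSE) {
  cat_tab <- measure_catalog()
  rel <- cat_tab$id[cat_tab$kind == "relative"]
  abs_m <- cat_tab$id[cat_tab$kind == "absolute"]
  grid <- tidyr::expand_grid(relative = rel, absolute = abs_m)
  per_city <- labels |>
    dplyr::group_by(.data$city_id) |>
    dplyr::group_modify(function(df, key) {
      grid$agreement <- purrr::map2_dbl(grid$relative, grid$absolute,
        function(r, a) observed_agreement(df[[paste0("poor_", r)]],
                                          df[[paste0("poor_", a)]],
                                          weights = if (weighted) df$weight))
      grid
    }) |>
    dplyr::ungroup()
  medians <- per_city |>
    dplyr::group_by(.data$relative, .data$absolute) |>
    dplyr::summarise(median_agreement = median(.data$agreement),
                     .groups = "drop") |>
    dplyr::mutate(pass = .data$median_agreement >= threshold)
  pass_all <- medians |>
    dplyr::group_by(.data$relative) |>
    dplyr::summarise(pass_all = all(.data$pass), .groups = "drop")
  list(per_city = per_city, medians = medians, pass_all = pass_all,
       threshold = threshold)
}

#' Median poor/rich outcome prevalences and their gap, by measure
#'
#' For each measure and outcome: the weighted outcome prevalence within the
#' poor and within the rich group of every city, then the across-city median
#' of each, and the gap `median_rich - median_poor` (negative when the poor
#' fare worse).
#'
#' @param labels Row-bound [poverty_labels()] tables (with outcome columns).
#' @param measures Measure ids.
#' @param outcomes Outcome names.
#' @return List with `per_city` (city x measure x outcome group prevalences)
#'   and `medians` (measure x outcome: `median_poor`, `median_rich`, `gap`).
#' @export
median_gap <- function(labels, measures = measure_catalog()$id,
                       outcomes = outcome_names()) {
  per_city <- dplyr::bind_rows(lapply(measures, function(m) {
    col <- paste0("poor_", m)
    dplyr::bind_rows(lapply(outcomes, function(oc) {
      labels |>
        dplyr::group_by(.data$city_id) |>
        dplyr::group_modify(function(df, key) {
          poor <- df[[col]]
          prev <- function(mask) {
            if (!any(mask & !is.na(df[[oc]]), na.rm = TRUE)) return(NA_real_)
            weighted_prevalence(df[[oc]], df$weight, subset = mask)$estimate
          }
          tibble::tibble(measure = m, outcome = oc,
                         prev_poor = prev(!is.na(poor) & poor),
                         prev_rich = prev(!is.na(poor) & !poor))
        }) |>
        dplyr::ungroup()
    }))
  }))
  medians <- per_city |>
    dplyr::group_by(.data$measure, .data$outcome) |>
    dplyr::summarise(median_poor = median(.data$prev_poor, na.rm = TRUE),
                     median_rich = median(.data$prev_rich, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(gap = .data$median_rich - .data$median_poor)
  list(per_city = per_city, medians = medians)
}

#' Select the preferred poverty measure
#'
#' Freezes the three selection criteria into a deterministic rule:
#' 1. feasibility — keep measures whose median poorest-group unweighted count
#'    across cities reaches `min_n` (default 100);
#' 2. comparability — among the surviving *relative* measures, keep those
#'    whose median observed agreement with *every* absolute measure reaches
#'    the agreement threshold;
#' 3. discriminatory power — of those, pick the measure with the largest mean
#'    absolute median gap across the five outcomes; ties go to the smaller
#'    cut-off.
#'
#' A complete decision record (every criterion's value for every measure) is
#' returned; when no measure survives, the selection is `NA` and the record
#' says which step emptied the field.
#'
#' @param size_summary From [poorest_group_sizes()].
#' @param agreement From [agreement_summary()].
#' @param gaps From [median_gap()].
#' @param min_n Minimum median poorest-group count.
#' @return List of class `measure_selection`: `selected` (measure id or NA),
#'   `decision_record` (tibble over relative measures), `min_n`,
#'   `agreement_threshold`.
#' @export
select_preferred_measure <- function(size_summary, agreement, gaps,
                                     min_n = 100) {
  rel <- measure_catalog()$id[measure_catalog()$kind == "relative"]
  counts <- size_summary |>
    dplyr::filter(.data$stat == "count") |>
    dplyr::select("measure", median_count = "median")
  mean_abs_gap <- gaps$medians |>
    dplyr::group_by(.data$measure) |>
    dplyr::summarise(mean_abs_gap = mean(abs(.data$gap), na.rm = TRUE),
                     .groups = "drop")
  record <- tibble::tibble(measure = rel) |>
    dplyr::left_join(counts, by = "measure") |>
    dplyr::left_join(agreement$pass_all,
                     by = c(measure = "relative")) |>
    dplyr::left_join(mean_abs_gap, by = "measure") |>
    dplyr::mutate(cutoff = as.numeric(sub("^w", "", .data$measure)),
                  size_ok = .data$median_count >= min_n,
                  agreement_ok = .data$size_ok & .data$pass_all)
  eligible <- record |> dplyr::filter(.data$agreement_ok)
  if (!nrow(eligible)) {
    step <- if (!any(record$size_ok)) "sample_size" else "agreement"
    return(structure(list(selected = NA_character_,
                          decision_record = record,
                          failed_step = step,
                          min_n = min_n,
                          agreement_threshold = agreement$threshold),
                     class = "measure_selection"))
  }
  eligible <- eligible |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_gap), .data$cutoff)
  structure(list(selected = eligible$measure[1],
                 decision_record = record,
                 failed_step = NA_character_,
                 min_n = min_n,
                 agreement_threshold = agreement$threshold),
            class = "measure_selection")
}

#' @export
print.measure_selection <- function(x, ...) {
  if (is.na(x$selected)) {
    cat(sprintf("<measure_selection> no measure selected (failed at %s step)\n",
                x$failed_step))
  } else {
    cat(sprintf("<measure_selection> selected: %s\n", x$selected))
  }
  print(x$decision_record)
  invisible(x)
}
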