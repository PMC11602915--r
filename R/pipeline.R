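#' Run the full poverty measurement and evaluation pipeline
#'
#' Applies the seven classifiers and the five outcome indicators to every
#' city, evaluates the measures by the three selection criteria, and — under
#' the selected measure (or `force_measure`) — computes per-city group
#' prevalences, the performance classification and the correlations with the
#' city development indices.
#'
#' @param scenario A `poverty_scenario` (from [generate_scenario()]) or any
#'   list with `cities` (list of [survey_dataset()]) and `contexts` tibble.
#' @param min_n Feasibility threshold on the median poorest-group count.
#' @param agreement_threshold Adequacy threshold on median agreement.
#' @param force_measure Optional measure id to use for the city
#'   characterisation regardless of the selection outcome.
#' @param rule [performance_rule()] for the quadrant classification.
#' @param ... Passed to [poverty_labels()] (cut-offs, modes, thresholds).
#' @return List of class `poverty_analysis`: `labels`, `size_summary`,
#'   `agreement`, `gaps`, `selection`, `measure_used`, `city_summaries`,
#'   `performance`, `correlations`.
#' @export
run_scenario_analysis <- function(scenario,
                                  min_n = 100,
                                  agreement_threshold = 0.60,
                                  force_measure = NULL,
                                  rule = performance_rule(),
                                  ...) {
  contexts <- scenario$contexts
  labels <- dplyr::bind_rows(lapply(scenario$cities, function(d) {
    ctx <- contexts[contexts$city_id == d$city_id, ]
    if (!nrow(ctx)) abort(sprintf("no context row for city %s", d$city_id))
    poverty_labels(d, ctx, ...)
  }))
  size_summary <- poorest_group_sizes(labels)
  agreement <- agreement_summary(labels, threshold = agreement_threshold)
  gaps <- median_gap(labels)
  selection <- select_preferred_measure(size_summary, agreement, gaps,
                                        min_n = min_n)
  measure_used <- force_measure %||% selection$selected
  city_summaries <- NULL
  performance <- NULL
  correlations <- NULL
  if (!is.na(measure_used)) {
    city_summaries <- labels |>
      dplyr::group_split(.data$city_id) |>
      lapply(group_prevalences, measure = measure_used) |>
      dplyr::bind_rows()
    performance <- performance_table(city_summaries, rule = rule)
    correlations <- context_correlations(city_summaries, contexts)
  }
  structure(list(labels = labels,
                 size_summary = size_summary,
                 agreement = agreement,
                 gaps = gaps,
                 selection = selection,
                 measure_used = measure_used,
                 city_summaries = city_summaries,
                 performance = performance,
                 correlations = correlations),
            class = "poverty_analysis")
}

#' @export
print.poverty_analysis <- function(x, ...) {
  cat(sprintf("<poverty_analysis> %d cities, measure used: %s\n",
              length(unique(x$labels$city_id)),
              x$measure_used %||% NA))
  invisible(x)
}

#' Export tidy result tables for plotting and reporting
#'
#' Writes deterministic CSVs: the poorest-group size summary, the per-pair
#' agreement table, the measure-by-outcome median gap table, the selection
#' decision record (JSON), equiplot data (city x group x outcome
#' prevalence), quadrant data (prevalence vs gap with the performance class),
#' the wide performance table, and the correlation matrix with confidence
#' intervals. Re-running on the same analysis object reproduces the files
#' byte for byte.
#'
#' @param analysis A [run_scenario_analysis()] result.
#' @param dir Output directory.
#' @return Invisibly, a named character vector of file paths.
#' @export
export_tidy_outputs <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    readr::write_csv(df, p, progress = FALSE)
    paths[[name]] <<- p
  }
  wr(analysis$size_summary, "poorest_group_sizes.csv")
  wr(analysis$agreement$per_city, "agreement_per_city.csv")
  wr(analysis$agreement$medians, "agreement_medians.csv")
  wr(analysis$gaps$medians, "median_gaps.csv")
  rec_path <- file.path(dir, "selection_record.json")
  jsonlite::write_json(list(selected = analysis$selection$selected,
                            failed_step = analysis$selection$failed_step,
                            min_n = analysis$selection$min_n,
                            agreement_threshold = analysis$selection$agreement_threshold,
                            decision_record = analysis$selection$decision_record),
                       rec_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths[["selection_record.json"]] <- rec_path
  if (!is.null(analysis$city_summaries)) {
    equiplot <- analysis$city_summaries |>
      dplyr::select("city_id", "outcome", "prev_poor", "prev_rich") |>
      tidyr::pivot_longer(c("prev_poor", "prev_rich"),
                          names_to = "group", values_to = "prevalence",
                          names_prefix = "prev_")
    wr(equiplot, "equiplot.csv")
    wr(analysis$performance$long, "quadrant.csv")
    wr(analysis$performance$table, "performance_table.csv")
    wr(analysis$correlations, "context_correlations.csv")
  }
  invisible(unlist(paths))
}

#' Equiplot of poor/rich prevalences by city
#'
#' Dot plot with one line per city and one dot per group, the standard
#' display for group gaps in coverage/prevalence. Requires ggplot2.
#'
#' @param city_summaries Row-bound [group_prevalences()] tables.
#' @param outcome Outcome to plot.
#' @return A ggplot object.
#' @export
plot_equiplot <- function(city_summaries, outcome = "no_electricity") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for plotting")
  }
  df <- city_summaries[city_summaries$outcome == outcome, ] |>
    tidyr::pivot_longer(c("prev_poor", "prev_rich"), names_to = "group",
                        values_to = "prevalence", names_prefix = "prev_")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prevalence,
                                   y = stats::reorder(.data$city_id,
                                                      .data$prevalence),
                                   colour = .data$group)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$city_id),
                       colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = paste("Prevalence of", outcome), y = NULL,
                  colour = "Group") +
    ggplot2::theme_minimal()
}
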