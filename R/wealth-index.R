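#' Specification of the wealth-index PCA
#'
#' @param variables Character vector of household columns entering the
#'   principal-components analysis (asset indicators plus housing/WASH
#'   booleans). Needs at least two variables.
#' @param standardise Standardise indicators to weighted mean 0 / sd 1 before
#'   the decomposition (PCA on the correlation matrix, the DHS convention).
#' @return A list of class `wealth_spec`.
#' @export
wealth_spec <- function(variables = NULL, standardise = TRUE) {
  structure(list(variables = variables, standardise = standardise),
            class = "wealth_spec")
}

# Default PCA input set: every asset_* column plus derived booleans for
# electricity, improved water/sanitation, durable materials and clean fuel.
wealth_matrix <- function(households, spec, dict = variable_dictionary()) {
  hh <- households
  derived <- tibble::tibble(
    electricity = as.numeric(hh$electricity),
    improved_water = as.numeric(hh$water_source %in%
                                  codes_of(dict$water_sources, "improved")),
    improved_sanitation = as.numeric(hh$sanitation_type %in%
                                       codes_of(dict$sanitation_types, "improved")),
    durable_floor = as.numeric(hh$floor_material %in%
                                 codes_of(dict$floor_materials, "durable")),
    durable_wall = as.numeric(hh$wall_material %in%
                                codes_of(dict$wall_materials, "durable")),
    durable_roof = as.numeric(hh$roof_material %in%
                                codes_of(dict$roof_materials, "durable")),
    clean_fuel = as.numeric(hh$cooking_fuel %in%
                              codes_of(dict$cooking_fuels, "clean"))
  )
  asset_cols <- grep("^asset_", names(hh), value = TRUE)
  x <- cbind(as.matrix(dplyr::mutate(hh[asset_cols], dplyr::across(
    dplyr::everything(), as.numeric))), as.matrix(derived))
  vars <- spec$variables %||% colnames(x)
  missing_vars <- setdiff(vars, colnames(x))
  if (length(missing_vars)) {
    abort(paste0("wealth_spec variables not found in dataset: ",
                 paste(missing_vars, collapse = ", ")))
  }
  x[, vars, drop = FALSE]
}

#' Compute the PCA wealth score
#'
#' First principal component of the (weighted) correlation matrix of the
#' indicator set: each indicator is centred and scaled by its weighted mean
#' and standard deviation, the weighted covariance of the standardised matrix
#' is eigendecomposed, and the score is the projection on the leading
#' eigenvector. The sign is oriented so that the score correlates positively
#' with the simple count of indicators owned, i.e. higher score = richer.
#' Missing indicator values are imputed to the variable's weighted mode
#' (a warning reports how many cells); zero-variance indicators are dropped
#' with a warning.
#'
#' @param households Household tibble (see [survey_dataset()]).
#' @param spec A [wealth_spec()]; `NULL` uses every asset and derived
#'   housing/WASH indicator.
#' @param dict Variable dictionary.
#' @return Numeric score per household (weighted mean 0).
#' @export
compute_wealth_score <- function(households, spec = wealth_spec(),
                                 dict = variable_dictionary()) {
  x <- wealth_matrix(households, spec, dict)
  w <- households$weight
  n_na <- sum(is.na(x))
  if (n_na > 0) {
    for (j in seq_len(ncol(x))) {
      miss <- is.na(x[, j])
      if (any(miss)) {
        mode_val <- as.numeric(weighted.mean(x[!miss, j], w[!miss]) >= 0.5)
        x[miss, j] <- mode_val
      }
    }
    warn(sprintf("imputed %d missing indicator cells to the variable mode", n_na))
  }
  wm <- colSums(x * w) / sum(w)
  xc <- sweep(x, 2, wm)
  wv <- colSums(xc^2 * w) / sum(w)
  keep <- wv > 1e-12
  if (any(!keep)) {
    warn(paste0("dropping zero-variance indicator(s): ",
                paste(colnames(x)[!keep], collapse = ", ")))
  }
  if (sum(keep) < 2) abort("fewer than 2 usable indicators for the wealth PCA")
  xs <- if (isTRUE(spec$standardise)) {
    sweep(xc[, keep, drop = FALSE], 2, sqrt(wv[keep]), "/")
  } else {
    xc[, keep, drop = FALSE]
  }
  cw <- crossprod(xs * sqrt(w / sum(w)))  # weighted correlation matrix
  v <- eigen(cw, symmetric = TRUE)$vectors[, 1]
  score <- as.numeric(xs %*% v)
  owned <- rowSums(x[, keep, drop = FALSE])
  if (sd(owned) > 0 && cor(score, owned) < 0) score <- -score
  score
}

#' Compare a recomputed wealth score against the survey-provided score
#'
#' Pearson correlation between the two scores on their nonmissing overlap.
#' The pipeline policy is to use the survey's original score when the
#' absolute correlation reaches the threshold (sign-flipping a negatively
#' oriented provided score first), and the recomputed score otherwise.
#'
#' @param score_computed,score_provided Numeric vectors, same length.
#' @param threshold Correlation gate, default 0.95.
#' @return List: `r` (Pearson correlation), `use_provided` (logical),
#'   `flipped` (whether the provided score had to be sign-flipped), `n`.
#' @export
validate_against_provided <- function(score_computed, score_provided,
                                      threshold = 0.95) {
  ok <- !is.na(score_computed) & !is.na(score_provided)
  if (sum(ok) < 3) abort("need at least 3 paired scores")
  if (sd(score_computed[ok]) == 0 || sd(score_provided[ok]) == 0) {
    abort("correlation undefined: a score has zero variance")
  }
  r <- cor(score_computed[ok], score_provided[ok])
  list(r = r,
       use_provided = abs(r) >= threshold,
       flipped = r < 0,
       n = sum(ok))
}

#' Classify households as relatively poor at a percentile cut-off
#'
#' A household is poor iff its weighted mid-distribution percentile rank of
#' the wealth score is at or below `percent_poor`/100. Because ranks are
#' shared within tie groups, the realised weighted poor share sits within one
#' household's weight of the nominal share, and cut-offs are nested: the 30%
#' poor set is contained in the 40% set, and so on.
#'
#' @param score Numeric wealth score per household.
#' @param weights Sampling weights.
#' @param percent_poor Cut-off in (0, 100); the convention uses 30, 40, 50, 60.
#' @return Logical vector, `TRUE` = poor.
#' @export
classify_relative_poor <- function(score, weights, percent_poor) {
  if (percent_poor <= 0 || percent_poor >= 100) {
    abort("percent_poor must lie strictly inside (0, 100)")
  }
  weighted_quantile_rank(score, weights) <= percent_poor / 100
}
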