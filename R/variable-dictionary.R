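#' Load the household variable dictionary
#'
#' The dictionary is the versioned config shipped with the package that fixes
#' the category code lists used throughout classification: asset variables,
#' water-source and sanitation codes with their JMP-style improved/unimproved
#' mapping, durable floor/wall/roof material lists, and cooking-fuel codes.
#' All classifiers validate their categorical inputs against these lists, so a
#' survey mapped onto unknown codes fails loudly rather than silently.
#'
#' @param path Optional path to an alternative dictionary YAML. Defaults to the
#'   dictionary shipped in `inst/extdata/variable_dictionary.yaml`.
#' @return A named list with elements `assets`, `small_assets`,
#'   `water_sources`, `sanitation_types`, `floor_materials`, `wall_materials`,
#'   `roof_materials`, `cooking_fuels` and `version`. Code-list elements are
#'   named character vectors mapping code to its class
#'   (`improved`/`unimproved`/`none`, `durable`/`not_durable`,
#'   `clean`/`dirty`).
#' @examples
#' dict <- variable_dictionary()
#' names(dict$water_sources)[dict$water_sources == "improved"]
#' @export
variable_dictionary <- function(path = NULL) {
  path <- path %||% system.file("extdata", "variable_dictionary.yaml",
                                package = "urbanpoverty", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  for (nm in c("water_sources", "sanitation_types", "floor_materials",
               "wall_materials", "roof_materials", "cooking_fuels")) {
    raw[[nm]] <- unlist(raw[[nm]])
  }
  raw$assets <- as.character(raw$assets)
  raw$small_assets <- as.character(raw$small_assets)
  raw
}

# Codes of a given class from a named mapping vector.
codes_of <- function(mapping, class) names(mapping)[mapping == class]
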