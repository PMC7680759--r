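#' Bundled screen summary tables
#'
#' Small CSV summaries of a complete chemical CI-suppression screen ship
#' with the package and drive examples and validation tests:
#'
#' * `"crosses-control-food"`: pooled hatch rates and egg totals of the
#'   Control, CI and Rescue crosses on control food, for a natural (wRi)
#'   and a transinfected (wMel) strain, in mass-mating and mating-confirmed
#'   single-pair formats.
#' * `"crosses-nabu-food"`: the same cross summaries under NaBu feeding.
#' * `"hits-wri"`: per-treatment screen outcomes (dose, wells, plates,
#'   Yes/Borderline/No call, reported p-value) against wRi-induced CI,
#'   24 treatments.
#' * `"hits-wmel"`: re-tests of the wRi hits against wMel-induced CI,
#'   8 treatments.
#' * `"hits-combination"`: dual-treatment combinations against wRi-induced
#'   CI, 7 rows.
#'
#' Hit tables report p-values as printed, including bounds such as
#' `"< 0.001"`; a parsed numeric column `p_value_num` (via
#' [parse_reported_p()]) is appended.
#'
#' @param name One of the table names above.
#' @return A data frame.
#' @examples
#' hits <- screen_fixture("hits-wri")
#' table(hits$significant)
#' @export
screen_fixture <- function(name = c("crosses-control-food", "crosses-nabu-food",
                                    "hits-wri", "hits-wmel",
                                    "hits-combination")) {
  name <- match.arg(name)
  file <- c("crosses-control-food" = "crosses_control_food.csv",
            "crosses-nabu-food" = "crosses_nabu_food.csv",
            "hits-wri" = "hits_wri.csv",
            "hits-wmel" = "hits_wmel.csv",
            "hits-combination" = "hits_combination.csv")[[name]]
  path <- system.file("extdata", file, package = "ciscreen", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if ("p_value" %in% names(df)) {
    df$p_value_num <- parse_reported_p(df$p_value)
  }
  df
}
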