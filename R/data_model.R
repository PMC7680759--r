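#' ciscreen: plate-based screening statistics for chemical suppression of CI
#'
#' Tools for analysing egg-hatch screens of chemical suppressors of
#' Wolbachia-induced cytoplasmic incompatibility (CI). The readout of such a
#' screen is the hatch rate: the fraction of laid eggs that hatch, computed
#' either pooled over eggs or per replicate well. The package covers the full
#' analysis path: well-level data handling ([screen_data()], [hatch_rate()]),
#' calibrated simulation of screening plates ([simulate_screen()]), plate QC
#' gating and dose tolerability scoring ([qc_gate()], [score_dose()]),
#' adaptive two-sample testing with hit classification
#' ([compare_conditions()], [classify_hit()]), Z-prime assay-quality scoring
#' ([zprime()]), and bootstrap sub-sampling sample-size determination
#' ([min_sufficient_wells()]).
#'
#' @keywords internal
"_PACKAGE"

## Canonical condition labels. Treated wells carry the treatment name in the
## `treatment` column; `condition` stays one of these four.
.ci_conditions <- c("control-cross", "ci-control", "rescue-control", "ci-treated")

#' Condition labels used throughout the package
#'
#' @return Character vector of the four canonical condition labels:
#'   `"control-cross"` (uninfected x uninfected), `"ci-control"` (uninfected
#'   female x infected male, the incompatible cross), `"rescue-control"`
#'   (infected x infected), and `"ci-treated"` (incompatible cross with the
#'   female chemically treated).
#' @export
ci_conditions <- function() .ci_conditions

#' Construct a well-level screen dataset
#'
#' A `screen_data` object is a data frame of per-well (or per-vial) egg-hatch
#' records plus free-form metadata. Each row is one replicate unit: a well of
#' a 24-well screening plate, or one female's vial in the vial assay format.
#'
#' @param wells Data frame with columns `plate_id`, `well_id`, `condition`,
#'   `eggs_laid`, `eggs_hatched`, and optionally `treatment` (added as `NA`
#'   when absent).
#' @param metadata Named list of free-form provenance (strain label, assay
#'   format, ...).
#' @return A `screen_data` object (a validated data frame).
#' @examples
#' wells <- data.frame(
#'   plate_id = "P1", well_id = c("A1", "A2"),
#'   condition = "ci-control", eggs_laid = c(120, 140),
#'   eggs_hatched = c(14, 12)
#' )
#' screen_data(wells, metadata = list(strain = "wRi"))
#' @export
screen_data <- function(wells, metadata = list()) {
  required <- c("plate_id", "well_id", "condition", "eggs_laid", "eggs_hatched")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols) > 0L) {
    stop("well table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  if (!"treatment" %in% names(wells)) wells$treatment <- NA_character_
  wells$plate_id <- as.character(wells$plate_id)
  wells$well_id <- as.character(wells$well_id)
  wells$condition <- as.character(wells$condition)
  wells$eggs_laid <- as.integer(wells$eggs_laid)
  wells$eggs_hatched <- as.integer(wells$eggs_hatched)
  validate_screen_data(wells)
  structure(
    wells[c("plate_id", "well_id", "condition", "treatment",
            "eggs_laid", "eggs_hatched")],
    metadata = metadata,
    class = c("screen_data", "data.frame")
  )
}

validate_screen_data <- function(wells) {
  if (anyNA(wells$eggs_laid) || anyNA(wells$eggs_hatched)) {
    stop("egg counts must not be missing")
  }
  if (any(wells$eggs_laid < 0L) || any(wells$eggs_hatched < 0L)) {
    stop("egg counts must be non-negative")
  }
  if (any(wells$eggs_hatched > wells$eggs_laid)) {
    stop("eggs_hatched must not exceed eggs_laid")
  }
  key <- paste(wells$plate_id, wells$well_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("(plate_id, well_id) pairs must be unique")
  }
  invisible(wells)
}

#' @export
print.screen_data <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("Screen dataset: %d wells, %d plate(s), conditions: %s\n",
              nrow(x), length(unique(x$plate_id)),
              paste(sort(unique(x$condition)), collapse = ", ")))
  if (length(md) > 0L) {
    cat("metadata:", paste(names(md), unlist(md), sep = "=", collapse = ", "), "\n")
  }
  print(as.data.frame(utils::head(x, 10L)))
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more wells\n")
  invisible(x)
}

#' Read or write a well-level table
#'
#' The on-disk format is plain CSV with a header and columns `plate_id`,
#' `well_id`, `condition`, `treatment`, `eggs_laid`, `eggs_hatched` (UTF-8).
#'
#' @param path Path to a CSV file.
#' @param metadata Metadata list attached to the returned object.
#' @return `read_well_table()` returns a [screen_data()] object;
#'   `write_well_table()` returns `path` invisibly.
#' @export
read_well_table <- function(path, metadata = list()) {
  wells <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  screen_data(wells, metadata = metadata)
}

#' @param x A `screen_data` object.
#' @rdname read_well_table
#' @export
write_well_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pooled hatch rate of a set of wells
#'
#' The pooled hatch rate is total eggs hatched over total eggs laid, the
#' egg-count-weighted mean of per-well rates. This is the summary used for
#' vial-format crosses, where egg totals per condition are pooled over
#' females.
#'
#' @param wells A [screen_data()] object or data frame with `eggs_laid` and
#'   `eggs_hatched` columns.
#' @return Pooled hatch proportion in `[0, 1]`.
#' @examples
#' hatch_rate(data.frame(eggs_laid = c(10, 10), eggs_hatched = c(3, 7)))
#' @export
hatch_rate <- function(wells) {
  total <- sum(wells$eggs_laid)
  if (length(total) == 0L || total <= 0L) {
    stop("hatch rate undefined: no eggs laid in these wells")
  }
  sum(wells$eggs_hatched) / total
}

#' Fold change in pooled hatch rate between two groups of wells
#'
#' Ratio of the treated group's pooled hatch rate to the control group's.
#' A fold change above 1 indicates CI suppression (higher hatch under
#' treatment).
#'
#' @param treated,control Well collections as in [hatch_rate()].
#' @return Ratio of pooled hatch rates.
#' @examples
#' treated <- data.frame(eggs_laid = 292, eggs_hatched = 47)
#' control <- data.frame(eggs_laid = 454, eggs_hatched = 45)
#' fold_change(treated, control) # ~1.6
#' @export
fold_change <- function(treated, control) {
  rc <- hatch_rate(control)
  if (rc == 0) stop("fold change undefined: control hatch rate is zero")
  hatch_rate(treated) / rc
}

#' Per-condition summary of well-level hatch rates
#'
#' Collects one condition's wells into the summary used by the Z-prime and
#' hit-range computations: pooled rate, the ordered per-well rates, and their
#' mean and standard deviation (sample sd, n - 1 denominator, the screening
#' convention). Wells with zero eggs laid carry no rate and are excluded from
#' the per-well statistics.
#'
#' @param dataset A [screen_data()] object.
#' @param condition Condition label to summarise.
#' @param treatment Optional treatment name to additionally filter
#'   `ci-treated` wells by.
#' @return A `condition_summary` object.
#' @examples
#' plate <- simulate_screen(default_calibration("nabu-effect"))
#' summarize_condition(plate, "ci-control")
#' @export
summarize_condition <- function(dataset, condition, treatment = NULL) {
  keep <- dataset$condition == condition
  if (!is.null(treatment)) keep <- keep & !is.na(dataset$treatment) &
      dataset$treatment == treatment
  sub <- dataset[keep, , drop = FALSE]
  if (nrow(sub) == 0L) {
    if (!is.null(treatment) && any(dataset$condition == condition)) {
      stop("no ", condition, " wells carry treatment \"", treatment,
           "\" (present: ",
           paste(unique(stats::na.omit(
             dataset$treatment[dataset$condition == condition])),
             collapse = ", "), ")")
    }
    stop("condition not present in dataset: ", condition)
  }
  sub <- sub[order(sub$plate_id, sub$well_id), , drop = FALSE]
  laid <- sub$eggs_laid
  if (sum(laid) <= 0L) stop("hatch rate undefined: no eggs laid for ", condition)
  rates <- sub$eggs_hatched[laid > 0L] / laid[laid > 0L]
  condition_summary(
    condition = condition,
    per_well_rates = rates,
    pooled_hatch_rate = sum(sub$eggs_hatched) / sum(laid)
  )
}

#' Low-level condition summary constructor
#'
#' Builds a `condition_summary` either from per-well rates (mean and sd are
#' then computed) or directly from summary statistics, as when evaluating the
#' Z-prime formula on reported control means and sds.
#'
#' @param condition Condition label.
#' @param per_well_rates Numeric vector of per-well hatch proportions, or
#'   `NULL` when supplying `mean_rate`/`sd_rate` directly.
#' @param mean_rate,sd_rate,n_wells Summary statistics; computed from
#'   `per_well_rates` when those are given.
#' @param pooled_hatch_rate Optional pooled (egg-weighted) rate.
#' @return A `condition_summary` object: list with fields `condition`,
#'   `n_wells`, `pooled_hatch_rate`, `per_well_rates`, `mean_rate`,
#'   `sd_rate`.
#' @export
condition_summary <- function(condition, per_well_rates = NULL,
                              mean_rate = NULL, sd_rate = NULL,
                              n_wells = NULL, pooled_hatch_rate = NA_real_) {
  if (!is.null(per_well_rates)) {
    stopifnot(length(per_well_rates) >= 1L,
              all(per_well_rates >= 0 & per_well_rates <= 1))
    n_wells <- length(per_well_rates)
    mean_rate <- mean(per_well_rates)
    sd_rate <- if (n_wells >= 2L) stats::sd(per_well_rates) else NA_real_
  } else {
    if (is.null(mean_rate) || is.null(n_wells)) {
      stop("supply per_well_rates, or mean_rate and n_wells")
    }
  }
  structure(
    list(condition = condition, n_wells = as.integer(n_wells),
         pooled_hatch_rate = pooled_hatch_rate,
         per_well_rates = per_well_rates,
         mean_rate = mean_rate, sd_rate = sd_rate),
    class = "condition_summary"
  )
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("Condition %s: n = %d wells, mean rate %.3f (sd %.4f), pooled %.3f\n",
              x$condition, x$n_wells, x$mean_rate,
              if (is.na(x$sd_rate)) NA else x$sd_rate, x$pooled_hatch_rate))
  invisible(x)
}

#' Per-well hatch rates for one condition
#'
#' Convenience extractor used by the testing and power modules: the ordered
#' per-well hatch proportions of one condition (optionally one treatment).
#'
#' @inheritParams summarize_condition
#' @return Numeric vector of per-well proportions.
#' @export
condition_rates <- function(dataset, condition, treatment = NULL) {
  summarize_condition(dataset, condition, treatment)$per_well_rates
}

#' Reconstruct hatched/unhatched counts from a printed rate and egg total
#'
#' Published cross tables report a hatch percentage and an egg total; the
#' underlying hatched count is recovered as `round(rate * total)`.
#'
#' @param rate_pct Hatch rate in percent (e.g. 10 for 10%).
#' @param total Total eggs laid.
#' @return Named integer vector with elements `hatched` and `unhatched`.
#' @examples
#' counts_from_rate(10, 712) # 71 hatched, 641 unhatched
#' @export
counts_from_rate <- function(rate_pct, total) {
  stopifnot(rate_pct >= 0, rate_pct <= 100, total >= 0)
  hatched <- as.integer(round(rate_pct / 100 * total))
  c(hatched = hatched, unhatched = as.integer(total) - hatched)
}
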