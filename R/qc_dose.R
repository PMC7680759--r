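#' Plate quality-control gate
#'
#' A screening plate enters hit scoring only if its pooled CI-control hatch
#' rate is at or below the gate threshold: strong CI in the untreated control
#' is the evidence that the incompatible cross worked on that plate. The
#' conventional gate is 12%, boundary inclusive.
#'
#' @param dataset A [screen_data()] object.
#' @param plate_id Plate to gate.
#' @param threshold Maximum admissible pooled CI-control hatch rate.
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @examples
#' plate <- simulate_screen(default_calibration("nabu-effect", seed = 3))
#' qc_gate(plate, "P1")
#' @export
qc_gate <- function(dataset, plate_id, threshold = 0.12) {
  sub <- dataset[dataset$plate_id == plate_id, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no such plate: ", plate_id)
  ctrl <- sub[sub$condition == "ci-control", , drop = FALSE]
  if (nrow(ctrl) == 0L) stop("plate ", plate_id, " has no ci-control wells")
  if (sum(ctrl$eggs_laid) <= 0L) stop("ci-control wells on plate ", plate_id,
                                      " have no eggs")
  ## tolerance keeps rates that are exactly at the boundary (e.g. 12/100)
  ## from failing through floating-point representation
  hatch_rate(ctrl) <= threshold + 1e-12
}

#' QC report over all plates of a dataset
#'
#' @param dataset A [screen_data()] object.
#' @param threshold As in [qc_gate()].
#' @return Data frame with one row per plate: `plate_id`, the pooled
#'   `ci_control_rate`, and logical `pass`.
#' @export
qc_report <- function(dataset, threshold = 0.12) {
  plates <- unique(dataset$plate_id)
  rate <- vapply(plates, function(p) {
    ctrl <- dataset[dataset$plate_id == p & dataset$condition == "ci-control", ]
    if (nrow(ctrl) == 0L || sum(ctrl$eggs_laid) <= 0L) return(NA_real_)
    hatch_rate(ctrl)
  }, numeric(1))
  data.frame(plate_id = plates, ci_control_rate = rate,
             pass = !is.na(rate) & rate <= threshold + 1e-12,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Score one dose of a tolerability series
#'
#' Dose-response tolerability testing exposes flies to a candidate dose over
#' two consecutive vial windows (early, days 1-6; late, days 7-12) and counts
#' eggs, larvae and pupae against matched controls. A stage shows a defect
#' when its count falls 40% or more below the control count (boundary
#' inclusive), with counts pooled within each window. Grades:
#' `"-"` if some stage is defective in both windows (a consistent defect),
#' `"some"` if defects appear only in the late window, `"+"` otherwise.
#'
#' @param record Data frame for one dose with columns `window` (`"early"` or
#'   `"late"`), `stage` (`"eggs"`, `"larvae"`, `"pupae"`), `count`, and
#'   `control_count`.
#' @param loss_threshold Fractional loss counting as a defect (default 0.4).
#' @return A `dose_score` object: list with `grade` (one of `"+"`, `"some"`,
#'   `"-"`) and the per-window defective stages.
#' @examples
#' rec <- data.frame(
#'   window = rep(c("early", "late"), each = 3),
#'   stage = rep(c("eggs", "larvae", "pupae"), 2),
#'   count = c(100, 80, 60, 40, 30, 25),
#'   control_count = c(100, 80, 60, 100, 80, 60)
#' )
#' score_dose(rec) # late-window-only defects: "some"
#' @export
score_dose <- function(record, loss_threshold = 0.4) {
  needed <- c("window", "stage", "count", "control_count")
  if (!all(needed %in% names(record))) {
    stop("dose record needs columns: ", paste(needed, collapse = ", "))
  }
  if (!all(c("early", "late") %in% record$window)) {
    stop("both early and late windows are required to score a dose")
  }
  defective <- function(win) {
    sub <- record[record$window == win, , drop = FALSE]
    counts <- tapply(sub$count, sub$stage, sum)
    ctrl <- tapply(sub$control_count, sub$stage, sum)
    if (any(ctrl <= 0)) stop("zero control count: loss undefined in ", win,
                             " window")
    loss <- 1 - counts / ctrl
    names(loss)[loss >= loss_threshold]
  }
  early <- defective("early")
  late <- defective("late")
  grade <- if (length(intersect(early, late)) > 0L) {
    "-"
  } else if (length(late) > 0L) {
    "some"
  } else {
    "+"
  }
  structure(list(grade = grade, defective_early = early,
                 defective_late = late),
            class = "dose_score")
}

#' @export
print.dose_score <- function(x, ...) {
  cat(sprintf("Dose grade: \"%s\"", x$grade))
  if (length(x$defective_early) || length(x$defective_late)) {
    cat(sprintf("  (>=40%% loss early: %s; late: %s)",
                paste(x$defective_early, collapse = ",") ,
                paste(x$defective_late, collapse = ",")))
  }
  cat("\n")
  invisible(x)
}

#' Select the feeding dose from a graded series
#'
#' The feeding dose for screening is the highest concentration with no
#' adverse effect, i.e. the maximum dose graded `"+"` in the tolerability
#' series.
#'
#' @param doses Numeric vector of concentrations, ascending.
#' @param grades Character vector of grades (`"+"`, `"some"`, `"-"`),
#'   parallel to `doses`.
#' @return The selected dose.
#' @examples
#' select_dose(c(1, 5, 10, 50), c("+", "+", "some", "-")) # 5
#' @export
select_dose <- function(doses, grades) {
  stopifnot(length(doses) == length(grades))
  if (is.unsorted(doses)) stop("doses must be sorted ascending")
  if (!all(grades %in% c("+", "some", "-"))) {
    stop("grades must be \"+\", \"some\" or \"-\"")
  }
  ok <- grades == "+"
  if (!any(ok)) stop("no tolerated dose: no concentration graded \"+\"")
  max(doses[ok])
}

#' Score a full dose-response series from a table
#'
#' @param series Data frame with columns `dose`, `window`, `stage`, `count`,
#'   `control_count` covering several doses.
#' @param loss_threshold As in [score_dose()].
#' @return Data frame with one row per dose (`dose`, `grade`) plus the
#'   selected dose as attribute `"selected_dose"` (`NA` if none tolerated).
#' @export
score_dose_series <- function(series, loss_threshold = 0.4) {
  doses <- sort(unique(series$dose))
  grades <- vapply(doses, function(d) {
    score_dose(series[series$dose == d, , drop = FALSE], loss_threshold)$grade
  }, character(1))
  out <- data.frame(dose = doses, grade = grades, stringsAsFactors = FALSE)
  sel <- if (any(grades == "+")) max(doses[grades == "+"]) else NA_real_
  attr(out, "selected_dose") <- sel
  out
}
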