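#' Simulation parameters for synthetic screening data
#'
#' The generator draws, for each well, an egg total from a Poisson law with
#' mean `lambda` (redrawn until at least one egg) and a hatched count from a
#' beta-binomial law with condition-specific mean and intraclass correlation
#' `rho`. The beta-binomial captures between-well heterogeneity (female age,
#' feeding, local dosing); `rho = 0` degenerates to a plain binomial. The
#' per-well hatch proportion then has variance approximately
#' `p (1 - p) (1 + (lambda - 1) rho) / lambda`.
#'
#' @param p Named numeric vector of per-condition hatch means in (0, 1);
#'   names are condition labels (see [ci_conditions()]).
#' @param rho Intraclass correlation (overdispersion) in `[0, 1)`.
#' @param lambda Expected eggs laid per well (> 0).
#' @param n_wells_per_condition Wells per condition per plate.
#' @param n_plates Number of replicate plates for [simulate_screen()].
#' @param seed Root seed; the same seed and parameters always reproduce the
#'   same dataset.
#' @return A `sim_params` object.
#' @seealso [default_calibration()] for ready-made parameter sets.
#' @export
sim_params <- function(p, rho = 0.002, lambda = 150,
                       n_wells_per_condition = 8L, n_plates = 1L,
                       seed = 1L) {
  if (is.null(names(p)) || any(!nzchar(names(p)))) {
    stop("p must be a named vector of per-condition hatch means")
  }
  if (any(p <= 0) || any(p >= 1)) stop("hatch means p must lie in (0, 1)")
  if (rho < 0 || rho >= 1) stop("overdispersion rho must lie in [0, 1)")
  if (lambda <= 0) stop("fecundity mean lambda must be positive")
  if (n_wells_per_condition < 1L) stop("need at least one well per condition")
  if (n_plates < 1L) stop("need at least one plate")
  structure(
    list(p = p, rho = rho, lambda = lambda,
         n_wells_per_condition = as.integer(n_wells_per_condition),
         n_plates = as.integer(n_plates), seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters:\n")
  cat("  hatch means:",
      paste(names(x$p), format(x$p, digits = 3), sep = "=", collapse = ", "), "\n")
  cat(sprintf("  rho = %g, lambda = %g eggs/well, %d wells/condition, %d plate(s), seed %d\n",
              x$rho, x$lambda, x$n_wells_per_condition, x$n_plates, x$seed))
  invisible(x)
}

#' Calibrated parameter sets for standard screening scenarios
#'
#' Ready-made [sim_params()] whose condition means sit at the midpoints of
#' the hatch-rate ranges characteristic of a chemical CI-suppression screen:
#' CI control 12%, treated CI 25% (a NaBu-sized effect), Rescue control 92%,
#' uninfected control cross 90%. All scenarios use `lambda = 150` eggs/well
#' (ten females laying over a one-day window) and `rho = 0.002`, five plates
#' of eight wells per condition.
#'
#' @param scenario One of `"ci-null"` (treated mean equals the CI-control
#'   mean; no effect), `"nabu-effect"` (treated mean 0.25), or
#'   `"rescue-vs-ci"` (focus on the two control conditions for assay-quality
#'   scoring).
#' @param seed Root seed passed through to [sim_params()].
#' @return A `sim_params` object.
#' @examples
#' default_calibration("nabu-effect")
#' @export
default_calibration <- function(scenario = c("ci-null", "nabu-effect", "rescue-vs-ci"),
                                seed = 1L) {
  scenario <- match.arg(scenario)
  p <- c("control-cross" = 0.90, "ci-control" = 0.12,
         "ci-treated" = 0.25, "rescue-control" = 0.92)
  if (scenario == "ci-null") p[["ci-treated"]] <- 0.12
  sim_params(p = p, rho = 0.002, lambda = 150,
             n_wells_per_condition = 8L, n_plates = 5L, seed = seed)
}

## Beta-binomial draw with mean p and intraclass correlation rho.
## Parameterisation: q ~ Beta(p(1-rho)/rho, (1-p)(1-rho)/rho) so that
## ICC = 1/(a+b+1) = rho exactly; rho = 0 is plain binomial.
rbetabinom <- function(n, size, p, rho) {
  if (rho <= 0) return(stats::rbinom(n, size, p))
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  stats::rbinom(n, size, stats::rbeta(n, a, b))
}

## Poisson egg totals, redrawn at zero: a well with no eggs has no rate.
rfecundity <- function(n, lambda) {
  eggs <- stats::rpois(n, lambda)
  while (any(eggs < 1L)) {
    zero <- eggs < 1L
    eggs[zero] <- stats::rpois(sum(zero), lambda)
  }
  eggs
}

#' Simulate a single well
#'
#' Draws one well's egg total and hatched count from the generator described
#' in [sim_params()], consuming the current RNG stream (set a seed with
#' `set.seed()` for reproducibility, or use [simulate_screen()] which seeds
#' itself).
#'
#' @param condition Condition label; must be named in `params$p`.
#' @param params A [sim_params()] object.
#' @param plate_id,well_id Identifiers stamped on the observation.
#' @return One-row [screen_data()] well record as a data frame.
#' @export
simulate_well <- function(condition, params, plate_id = "P1", well_id = "A1") {
  stopifnot(inherits(params, "sim_params"))
  if (!condition %in% names(params$p)) {
    stop("no hatch mean given for condition: ", condition)
  }
  eggs <- rfecundity(1L, params$lambda)
  hatched <- rbetabinom(1L, eggs, params$p[[condition]], params$rho)
  data.frame(plate_id = plate_id, well_id = well_id, condition = condition,
             treatment = NA_character_, eggs_laid = eggs,
             eggs_hatched = hatched, stringsAsFactors = FALSE)
}

## 24-well plate labels A1..D6, row-major.
plate_well_labels <- function(n) {
  labs <- as.vector(t(outer(LETTERS[1:4], 1:6, paste0)))
  if (n > length(labs)) labs <- paste0("W", seq_len(n)) else labs <- labs[seq_len(n)]
  labs
}

#' Simulate one screening plate
#'
#' Populates one 24-well plate in the canonical screen layout: eight
#' `ci-control`, eight `ci-treated` and eight `rescue-control` wells (or
#' fewer per condition when `params$n_wells_per_condition` is smaller).
#' Consumes the current RNG stream.
#'
#' @param params A [sim_params()] object.
#' @param plate_id Plate identifier.
#' @param conditions Conditions placed on the plate.
#' @param treatment Treatment label stamped on `ci-treated` wells.
#' @return A [screen_data()] object for one plate.
#' @export
simulate_screen_plate <- function(params, plate_id = "P1",
                                  conditions = c("ci-control", "ci-treated",
                                                 "rescue-control"),
                                  treatment = "treatment") {
  stopifnot(inherits(params, "sim_params"))
  k <- params$n_wells_per_condition
  n_total <- length(conditions) * k
  if (n_total > 24L) {
    stop("layout exceeds 24-well plate capacity: ", n_total, " wells requested")
  }
  cond <- rep(conditions, each = k)
  eggs <- rfecundity(n_total, params$lambda)
  hatched <- integer(n_total)
  for (cnd in conditions) {
    idx <- which(cond == cnd)
    if (!cnd %in% names(params$p)) {
      stop("no hatch mean given for condition: ", cnd)
    }
    hatched[idx] <- rbetabinom(length(idx), eggs[idx], params$p[[cnd]], params$rho)
  }
  wells <- data.frame(
    plate_id = plate_id, well_id = plate_well_labels(n_total),
    condition = cond,
    treatment = ifelse(cond == "ci-treated", treatment, NA_character_),
    eggs_laid = eggs, eggs_hatched = hatched, stringsAsFactors = FALSE
  )
  screen_data(wells, metadata = list(simulated = TRUE))
}

## Child seed for plate i from the root seed, by fixed arithmetic; kept
## within the 32-bit integer range.
child_seed <- function(root, i) {
  as.integer((as.double(root) + 1000003 * i) %% 2147483647)
}

#' Simulate a multi-plate screen
#'
#' Generates `params$n_plates` replicate plates. Each plate draws from its
#' own RNG stream, seeded from the root seed by fixed arithmetic, so the
#' full dataset is reproducible and individual plates can be regenerated
#' independently.
#'
#' @param params A [sim_params()] object.
#' @param treatment Treatment label for `ci-treated` wells.
#' @return A [screen_data()] object with plates `P1 ... Pn`.
#' @examples
#' screen <- simulate_screen(default_calibration("nabu-effect", seed = 42))
#' hatch_rate(screen[screen$condition == "ci-control", ])
#' @export
simulate_screen <- function(params, treatment = "treatment") {
  stopifnot(inherits(params, "sim_params"))
  plates <- vector("list", params$n_plates)
  for (i in seq_len(params$n_plates)) {
    set.seed(child_seed(params$seed, i))
    plates[[i]] <- simulate_screen_plate(params, plate_id = paste0("P", i),
                                         treatment = treatment)
  }
  wells <- do.call(rbind, lapply(plates, as.data.frame))
  screen_data(wells, metadata = list(simulated = TRUE, seed = params$seed))
}
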