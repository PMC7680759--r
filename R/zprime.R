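#' Z-prime assay-quality factor of a screening plate
#'
#' The Z-prime factor summarises how well the two control conditions of a
#' plate separate: \eqn{Z' = 1 - 3(\sigma_{CI} + \sigma_R)/|\mu_R - \mu_{CI}|},
#' with means and standard deviations taken over per-well hatch proportions
#' of the CI control and Rescue control. Z-prime is positive exactly when
#' the two controls' three-sd envelopes do not overlap; values approaching 1
#' indicate a wide usable window. Negative values are reported as such (a
#' diagnostic for failed plates).
#'
#' @param ci,rescue `condition_summary` objects (see [summarize_condition()]
#'   and [condition_summary()]) for the CI-control and Rescue-control
#'   conditions; each needs at least two wells.
#' @param plate_id Optional identifier carried on the result.
#' @return A `zprime_result`: list with `plate_id`, `z_prime`, the four
#'   control summary statistics `mu_ci`, `sd_ci`, `mu_rescue`, `sd_rescue`,
#'   and `hit_range`, the normalized open interval between the CI boundary
#'   \eqn{\mu_{CI} + 3\sigma_{CI}} and the Rescue boundary
#'   \eqn{\mu_R - 3\sigma_R} (0 = CI mean, 1 = Rescue mean).
#' @examples
#' ci <- condition_summary("ci-control", mean_rate = 0.12, sd_rate = 0.05,
#'                         n_wells = 8)
#' re <- condition_summary("rescue-control", mean_rate = 0.92, sd_rate = 0.04,
#'                         n_wells = 8)
#' zprime(ci, re)$z_prime # 0.6625
#' @export
zprime <- function(ci, rescue, plate_id = NA_character_) {
  for (s in list(ci, rescue)) {
    if (!inherits(s, "condition_summary")) {
      stop("zprime expects condition_summary inputs")
    }
    if (s$n_wells < 2L || is.na(s$sd_rate)) {
      stop("insufficient replication: each control needs >= 2 wells")
    }
  }
  sep <- rescue$mean_rate - ci$mean_rate
  if (sep == 0) stop("Z-prime undefined: control means are equal")
  z <- 1 - 3 * (ci$sd_rate + rescue$sd_rate) / abs(sep)
  structure(
    list(plate_id = plate_id, z_prime = z,
         mu_ci = ci$mean_rate, sd_ci = ci$sd_rate,
         mu_rescue = rescue$mean_rate, sd_rescue = rescue$sd_rate,
         hit_range = c(lower = 3 * ci$sd_rate / abs(sep),
                       upper = 1 - 3 * rescue$sd_rate / abs(sep))),
    class = "zprime_result"
  )
}

#' @export
print.zprime_result <- function(x, ...) {
  cat(sprintf("Z' = %.3f  (CI control %.3f +/- %.4f; Rescue %.3f +/- %.4f)\n",
              x$z_prime, x$mu_ci, x$sd_ci, x$mu_rescue, x$sd_rescue))
  cat(sprintf("normalized hit range: (%.3f, %.3f)\n",
              x$hit_range[["lower"]], x$hit_range[["upper"]]))
  invisible(x)
}

#' Per-plate Z-prime over a multi-plate dataset
#'
#' @param dataset A [screen_data()] object whose plates carry `ci-control`
#'   and `rescue-control` wells.
#' @return Data frame with one row per plate: `plate_id`, `z_prime`, and the
#'   four control summary statistics.
#' @examples
#' screen <- simulate_screen(default_calibration("rescue-vs-ci", seed = 11))
#' plate_zprime(screen)
#' @export
plate_zprime <- function(dataset) {
  plates <- unique(dataset$plate_id)
  rows <- lapply(plates, function(p) {
    sub <- dataset[dataset$plate_id == p, , drop = FALSE]
    z <- zprime(summarize_condition(sub, "ci-control"),
                summarize_condition(sub, "rescue-control"),
                plate_id = p)
    data.frame(plate_id = p, z_prime = z$z_prime,
               mu_ci = z$mu_ci, sd_ci = z$sd_ci,
               mu_rescue = z$mu_rescue, sd_rescue = z$sd_rescue,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Normalized position of a treatment between the two controls
#'
#' Maps a treatment's mean per-well hatch rate onto the scale anchored at
#' the CI-control mean (0) and the Rescue-control mean (1), and flags
#' whether it falls in the "hit range": strictly above the CI boundary
#' \eqn{\mu_{CI} + 3\sigma_{CI}} and strictly below the Rescue boundary
#' \eqn{\mu_R - 3\sigma_R}. The flag applies the three-sd rule to the
#' treatment mean (the per-plate average), not to individual wells.
#'
#' @param treatment,ci,rescue `condition_summary` objects.
#' @return List with `position` (affine-normalized mean), `in_hit_range`
#'   (logical), and the raw-scale `bounds` of the hit range.
#' @examples
#' tr <- condition_summary("ci-treated", mean_rate = 0.25, n_wells = 8,
#'                         sd_rate = 0.03)
#' ci <- condition_summary("ci-control", mean_rate = 0.12, sd_rate = 0.01,
#'                         n_wells = 8)
#' re <- condition_summary("rescue-control", mean_rate = 0.92, sd_rate = 0.02,
#'                         n_wells = 8)
#' normalized_score(tr, ci, re) # position 0.1625, in hit range
#' @export
normalized_score <- function(treatment, ci, rescue) {
  sep <- rescue$mean_rate - ci$mean_rate
  if (sep == 0) stop("normalized score undefined: control means are equal")
  position <- (treatment$mean_rate - ci$mean_rate) / sep
  lower <- ci$mean_rate + 3 * ci$sd_rate
  upper <- rescue$mean_rate - 3 * rescue$sd_rate
  list(position = position,
       in_hit_range = treatment$mean_rate > lower && treatment$mean_rate < upper,
       bounds = c(lower = lower, upper = upper))
}

#' Plot per-plate treatment positions against the normalized hit range
#'
#' Draws each plate's treatment mean on the normalized control scale with
#' the CI-control band (below the lower boundary), the Rescue band (above
#' the upper boundary) and the white hit range between them. Requires
#' ggplot2.
#'
#' @param dataset A multi-plate [screen_data()] object with both controls
#'   and a `ci-treated` condition.
#' @return A ggplot object.
#' @export
plot_hit_range <- function(dataset) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_hit_range requires the ggplot2 package")
  }
  plates <- unique(dataset$plate_id)
  rows <- lapply(plates, function(p) {
    sub <- dataset[dataset$plate_id == p, , drop = FALSE]
    ci <- summarize_condition(sub, "ci-control")
    re <- summarize_condition(sub, "rescue-control")
    tr <- summarize_condition(sub, "ci-treated")
    ns <- normalized_score(tr, ci, re)
    sep <- re$mean_rate - ci$mean_rate
    data.frame(plate_id = p, position = ns$position,
               lower = 3 * ci$sd_rate / abs(sep),
               upper = 1 - 3 * re$sd_rate / abs(sep))
  })
  df <- do.call(rbind, rows)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$plate_id)) +
    ggplot2::geom_rect(ggplot2::aes(xmin = -Inf, xmax = Inf, ymin = -Inf,
                                    ymax = .data$lower), fill = "firebrick",
                       alpha = 0.15) +
    ggplot2::geom_rect(ggplot2::aes(xmin = -Inf, xmax = Inf,
                                    ymin = .data$upper, ymax = Inf),
                       fill = "cadetblue", alpha = 0.15) +
    ggplot2::geom_point(ggplot2::aes(y = .data$position), size = 3,
                        colour = "goldenrod") +
    ggplot2::labs(x = "plate", y = "normalized hatch rate (CI = 0, Rescue = 1)") +
    ggplot2::theme_minimal()
}
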