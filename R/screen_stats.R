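#' Bonferroni-scaled significance policy
#'
#' Significance in multi-category cross experiments is judged against a
#' Bonferroni-scaled alpha: the base level divided by the number of data
#' categories compared in that experiment (e.g. 0.05/6 = 0.0083 for
#' three-cross comparisons, 0.05/4 = 0.0125 for the NaBu vial experiments).
#'
#' @param base_alpha Base significance level (default 0.05).
#' @param m Number of data categories compared (default 1, no scaling).
#' @return An `alpha_policy` object with fields `base_alpha`, `m` and
#'   `alpha_adj = base_alpha / m`.
#' @examples
#' alpha_policy(0.05, 6)$alpha_adj # 0.00833...
#' @export
alpha_policy <- function(base_alpha = 0.05, m = 1L) {
  stopifnot(base_alpha > 0, base_alpha < 1, m >= 1)
  structure(list(base_alpha = base_alpha, m = as.integer(m),
                 alpha_adj = base_alpha / m),
            class = "alpha_policy")
}

new_test_result <- function(test_name, statistic, p_value, alpha_used,
                            n_per_group, diagnostics = list()) {
  structure(
    list(test_name = test_name, statistic = unname(statistic),
         p_value = min(max(p_value, 0), 1), alpha_used = alpha_used,
         n_per_group = n_per_group,
         significant = p_value < alpha_used,
         diagnostics = diagnostics),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (alpha = %.4g) -> %s\n",
              x$test_name, x$statistic, x$p_value, x$alpha_used,
              if (x$significant) "significant" else "not significant"))
  if (length(x$diagnostics)) {
    d <- x$diagnostics
    if (!is.null(d$shapiro_p)) {
      cat(sprintf("  normality p: %.3g / %.3g; variance homogeneity p: %.3g\n",
                  d$shapiro_p[1], d$shapiro_p[2], d$levene_p))
    }
  }
  invisible(x)
}

## Two-group Levene test on absolute deviations from the group centers
## (mean centering, the SPSS default). Equivalent to the one-way ANOVA F on
## the |x - center| scores; closed form for two groups, used inside the
## sub-sampling loop where a model-formula interface would dominate runtime.
levene_p_value <- function(a, b, center = mean) {
  za <- abs(a - center(a))
  zb <- abs(b - center(b))
  na <- length(za); nb <- length(zb)
  ma <- mean(za); mb <- mean(zb); mg <- (sum(za) + sum(zb)) / (na + nb)
  ssb <- na * (ma - mg)^2 + nb * (mb - mg)^2
  ssw <- sum((za - ma)^2) + sum((zb - mb)^2)
  if (ssw <= 0) return(if (ssb <= 0) 1 else 0)
  f <- ssb / (ssw / (na + nb - 2))
  stats::pf(f, 1, na + nb - 2, lower.tail = FALSE)
}

## Shapiro-Wilk p, with degenerate samples (constant, or all-but-one tied)
## treated as non-normal rather than erroring mid-pipeline.
shapiro_p_value <- function(x) {
  if (length(unique(x)) < 3L) return(0)
  out <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
  out
}

#' Choose the two-sample test for a pair of per-well rate samples
#'
#' The adaptive decision path screens each group for normality with the
#' Shapiro-Wilk test and the pair for homogeneity of variance with Levene's
#' test (both at `screen_alpha`), then selects:
#' * both normal, homogeneous variance: Student t
#' * both normal, heterogeneous: Welch t
#' * non-normal, homogeneous: Mann-Whitney U
#' * non-normal, heterogeneous: bootstrap t (Welch statistic, resampled null)
#'
#' Zero-variance (constant) groups cannot be screened and are flagged as
#' degenerate: two identical constant groups show no separation (p = 1 in
#' [compare_conditions()]), two distinct constant groups show complete
#' separation (p = 0).
#'
#' @param a,b Numeric vectors of per-well hatch proportions (>= 3 each).
#' @param screen_alpha Level of the normality/homogeneity screens.
#' @return List with `test_name`, logicals `normal` and `homogeneous`,
#'   `degenerate`, and the screening p-values `shapiro_p` (length 2) and
#'   `levene_p`.
#' @export
choose_test <- function(a, b, screen_alpha = 0.05) {
  if (length(a) < 3L || length(b) < 3L) {
    stop("each group needs at least 3 observations")
  }
  degenerate <- stats::var(a) == 0 || stats::var(b) == 0
  sp <- c(shapiro_p_value(a), shapiro_p_value(b))
  lp <- levene_p_value(a, b)
  normal <- all(sp > screen_alpha)
  homogeneous <- lp > screen_alpha
  test_name <- if (normal) {
    if (homogeneous) "t" else "welch-t"
  } else {
    if (homogeneous) "mann-whitney-u" else "bootstrap-t"
  }
  list(test_name = test_name, normal = normal, homogeneous = homogeneous,
       degenerate = degenerate, shapiro_p = sp, levene_p = lp)
}

## Vectorised bootstrap null for the Welch statistic: both groups centered
## at their own means (null of equal means), resampled with replacement.
boot_welch_p <- function(a, b, B) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  se <- sqrt(va / na + vb / nb)
  if (se == 0) return(if (mean(a) == mean(b)) 1 else 0)
  t_obs <- (mean(a) - mean(b)) / se
  a0 <- a - mean(a); b0 <- b - mean(b)
  A <- matrix(sample(a0, na * B, replace = TRUE), nrow = na)
  Bm <- matrix(sample(b0, nb * B, replace = TRUE), nrow = nb)
  mA <- colMeans(A); mB <- colMeans(Bm)
  vA <- (colSums(A * A) - na * mA^2) / (na - 1)
  vB <- (colSums(Bm * Bm) - nb * mB^2) / (nb - 1)
  seb <- sqrt(vA / na + vB / nb)
  tb <- ifelse(seb > 0, (mA - mB) / seb, 0)
  (1 + sum(abs(tb) >= abs(t_obs))) / (B + 1)
}

## Shared fast path: run the adaptive comparison, return name/statistic/p.
adaptive_test <- function(a, b, boot_reps = 10000L, screen_alpha = 0.05) {
  choice <- choose_test(a, b, screen_alpha)
  if (choice$degenerate && stats::var(a) == 0 && stats::var(b) == 0) {
    p <- if (a[1] == b[1]) 1 else 0
    return(list(test_name = "welch-t",
                statistic = if (a[1] == b[1]) 0 else Inf * sign(a[1] - b[1]),
                p_value = p, choice = choice))
  }
  out <- switch(choice$test_name,
    "t" = {
      tt <- stats::t.test(a, b, var.equal = TRUE)
      list(statistic = tt$statistic, p_value = tt$p.value)
    },
    "welch-t" = {
      tt <- stats::t.test(a, b)
      list(statistic = tt$statistic, p_value = tt$p.value)
    },
    "mann-whitney-u" = {
      wt <- suppressWarnings(stats::wilcox.test(a, b))
      list(statistic = wt$statistic, p_value = wt$p.value)
    },
    "bootstrap-t" = {
      se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
      stat <- if (se > 0) (mean(a) - mean(b)) / se else 0
      list(statistic = stat, p_value = boot_welch_p(a, b, boot_reps))
    }
  )
  list(test_name = choice$test_name, statistic = out$statistic,
       p_value = out$p_value, choice = choice)
}

#' Compare two conditions by per-well hatch proportions
#'
#' Runs the adaptive two-sided two-sample comparison selected by
#' [choose_test()] and records the Bonferroni-scaled alpha it was judged
#' against. This is the comparison used for plate screens, where the
#' replicate unit is the well; pooled-egg chi-square comparisons
#' ([chi_square_gof()]) are reserved for vial-format crosses.
#'
#' @param a,b Numeric vectors of per-well hatch proportions.
#' @param policy An [alpha_policy()].
#' @param boot_reps Bootstrap resamples for the bootstrap-t branch.
#' @param seed Optional seed for the bootstrap branch.
#' @param screen_alpha Level of the normality/homogeneity screens.
#' @return A `test_result` object.
#' @examples
#' screen <- simulate_screen(default_calibration("nabu-effect", seed = 7))
#' compare_conditions(condition_rates(screen, "ci-treated"),
#'                    condition_rates(screen, "ci-control"))
#' @export
compare_conditions <- function(a, b, policy = alpha_policy(),
                               boot_reps = 10000L, seed = NULL,
                               screen_alpha = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  res <- adaptive_test(a, b, boot_reps = boot_reps, screen_alpha = screen_alpha)
  new_test_result(
    test_name = res$test_name, statistic = res$statistic,
    p_value = res$p_value, alpha_used = policy$alpha_adj,
    n_per_group = c(length(a), length(b)),
    diagnostics = res$choice[c("shapiro_p", "levene_p", "normal",
                               "homogeneous", "degenerate")]
  )
}

#' Chi-square goodness of fit of pooled hatch counts against a reference rate
#'
#' The vial-format comparison: the test condition's pooled
#' (hatched, unhatched) counts are compared against expected counts under a
#' fixed reference hatch rate (typically the control cross's observed rate),
#' with the usual one-degree-of-freedom statistic
#' \eqn{\sum (O - E)^2 / E}.
#'
#' @param observed Length-2 vector `c(hatched, unhatched)` (or a named
#'   vector as returned by [counts_from_rate()]).
#' @param reference_rate Expected hatch proportion in (0, 1).
#' @param policy An [alpha_policy()]; the Bonferroni-scaled alpha is
#'   recorded on the result.
#' @return A `test_result` with `test_name = "chi-square-gof"`.
#' @examples
#' chi_square_gof(c(8, 12), 0.5) # statistic 0.8
#' @export
chi_square_gof <- function(observed, reference_rate, policy = alpha_policy()) {
  stopifnot(length(observed) == 2L, all(observed >= 0))
  total <- sum(observed)
  if (total <= 0) stop("no observations: chi-square undefined")
  if (reference_rate <= 0 || reference_rate >= 1) {
    stop("reference rate must lie strictly inside (0, 1)")
  }
  expected <- total * c(reference_rate, 1 - reference_rate)
  if (any(expected == 0)) stop("degenerate expectation: expected count of zero")
  statistic <- sum((observed - expected)^2 / expected)
  p <- stats::pchisq(statistic, df = 1L, lower.tail = FALSE)
  new_test_result("chi-square-gof", statistic, p, policy$alpha_adj,
                  n_per_group = total,
                  diagnostics = list(expected = expected))
}

#' Classify a treatment comparison as a hit
#'
#' Maps a comparison p-value onto the three-way screen call: `"Yes"` (clear
#' hit) below the borderline band, `"Borderline"` inside it, `"No"` at or
#' above alpha. The default band `[0.04, 0.05)` is the narrowest rule
#' consistent with conventional borderline calls just under alpha = 0.05.
#'
#' @param result A `test_result`, or a bare p-value.
#' @param treatment Treatment label carried on the call.
#' @param borderline_low Lower edge of the borderline band.
#' @param alpha Significance level (upper edge of the band).
#' @return A `hit_call` object with fields `treatment`, `grade`, `p_value`.
#' @examples
#' classify_hit(0.047)$grade # "Borderline"
#' classify_hit(0.005)$grade # "Yes"
#' @export
classify_hit <- function(result, treatment = NA_character_,
                         borderline_low = 0.04, alpha = 0.05) {
  if (!(borderline_low > 0 && borderline_low < alpha)) {
    stop("thresholds must satisfy 0 < borderline_low < alpha")
  }
  p <- if (inherits(result, "test_result")) result$p_value else result
  stopifnot(is.numeric(p), p >= 0, p <= 1)
  grade <- if (p < borderline_low) "Yes" else if (p < alpha) "Borderline" else "No"
  structure(list(treatment = treatment, grade = grade, p_value = p),
            class = "hit_call")
}

#' @export
print.hit_call <- function(x, ...) {
  cat(sprintf("%s: %s (p = %.4g)\n",
              if (is.na(x$treatment)) "treatment" else x$treatment,
              x$grade, x$p_value))
  invisible(x)
}

#' Parse a reported p-value string
#'
#' Published screen tables report p-values either numerically (`"0.047"`) or
#' as a bound (`"< 0.001"`). Bounds are mapped to a representative value
#' just inside the bound (0.9 times it), so `"< 0.001"` parses to 0.0009.
#'
#' @param x Character vector of reported p-values.
#' @return Numeric vector.
#' @export
parse_reported_p <- function(x) {
  x <- trimws(x)
  bounded <- grepl("^<", x)
  val <- suppressWarnings(as.numeric(sub("^<\\s*", "", x)))
  ifelse(bounded, val * 0.9, val)
}

#' Score one treatment across screening plates
#'
#' Full per-treatment scoring as used for a plate screen: checks the QC gate
#' per plate, pools per-well rates of QC-passing plates, runs
#' [compare_conditions()] between the treated and CI-control wells, and
#' classifies the result.
#'
#' @param dataset A [screen_data()] object (one or more plates).
#' @param treatment Treatment label of the `ci-treated` wells scored.
#' @param policy An [alpha_policy()].
#' @param borderline_low,alpha Hit-classification thresholds.
#' @param qc Apply the 12% QC gate before scoring (default `TRUE`).
#' @param boot_reps,seed Passed to [compare_conditions()].
#' @return List with the `hit_call`, the underlying `test_result`, and the
#'   per-plate QC report.
#' @export
score_treatment <- function(dataset, treatment = NULL,
                            policy = alpha_policy(),
                            borderline_low = 0.04, alpha = 0.05,
                            qc = TRUE, boot_reps = 10000L, seed = NULL) {
  qcr <- qc_report(dataset)
  use <- if (qc) qcr$plate_id[qcr$pass] else qcr$plate_id
  if (length(use) == 0L) stop("no plate passes the QC gate")
  sub <- dataset[dataset$plate_id %in% use, , drop = FALSE]
  treated <- condition_rates(sub, "ci-treated", treatment)
  control <- condition_rates(sub, "ci-control")
  res <- compare_conditions(treated, control, policy = policy,
                            boot_reps = boot_reps, seed = seed)
  call <- classify_hit(res, treatment = if (is.null(treatment)) NA else treatment,
                       borderline_low = borderline_low, alpha = alpha)
  list(hit_call = call, test_result = res, qc = qcr,
       n_wells = c(treated = length(treated), control = length(control)),
       n_plates = length(use))
}
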