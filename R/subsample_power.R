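#' Crosswise pairing of screening plates
#'
#' Builds every unordered pair of plate replicates and pools each pair's
#' wells per condition (two 8-well plates give 16 wells per condition).
#' Pair datasets are the input unit of the sub-sampling power analysis:
#' they mimic the practical screening decision of how many plates (and
#' wells) to run per treatment.
#'
#' @param plates A multi-plate [screen_data()] object, or a list of
#'   single-plate `screen_data` objects.
#' @return Named list of `screen_data` objects, one per unordered pair,
#'   named `"P1-P2"` etc.
#' @examples
#' screen <- simulate_screen(default_calibration("nabu-effect", seed = 5))
#' length(plate_pairs(screen)) # choose(5, 2) = 10
#' @export
plate_pairs <- function(plates) {
  if (inherits(plates, "screen_data")) {
    ids <- unique(plates$plate_id)
    plist <- lapply(ids, function(p) plates[plates$plate_id == p, , drop = FALSE])
  } else {
    plist <- plates
    ids <- vapply(plist, function(p) unique(p$plate_id)[1], character(1))
  }
  if (length(plist) < 2L) stop("need at least two plates to pair")
  combos <- utils::combn(length(plist), 2L)
  pairs <- vector("list", ncol(combos))
  names(pairs) <- apply(combos, 2L, function(ij) paste(ids[ij], collapse = "-"))
  for (j in seq_len(ncol(combos))) {
    ij <- combos[, j]
    pooled <- rbind(as.data.frame(plist[[ij[1]]]), as.data.frame(plist[[ij[2]]]))
    pairs[[j]] <- screen_data(pooled, metadata = list(pair_id = names(pairs)[j]))
  }
  pairs
}

#' Rejection probability of the adaptive comparison at a sub-sample size
#'
#' Estimates, by Monte-Carlo sub-sampling, the probability that the adaptive
#' two-sample comparison ([compare_conditions()]) rejects at level `alpha`
#' when only `k` wells per condition are used. Each of the `B` resamples
#' draws `k` wells without replacement from each group (a sub-sample of
#' distinct wells) and re-runs the full adaptive procedure, including test
#' re-selection.
#'
#' @param a,b Numeric vectors of per-well hatch proportions (the two pooled
#'   condition groups).
#' @param k Wells drawn per group (`3 <= k <= min(length(a), length(b))`).
#' @param alpha Significance level of the per-resample test.
#' @param B Number of sub-samples.
#' @param seed Optional seed.
#' @param boot_reps Resamples for any bootstrap-t branch hit along the way.
#' @return Estimated rejection probability in `[0, 1]`.
#' @export
rejection_probability <- function(a, b, k, alpha = 0.05, B = 2000L,
                                  seed = NULL, boot_reps = 10000L) {
  if (k < 3L) stop("k must be at least 3 (the adaptive tests need 3 per group)")
  if (k > length(a) || k > length(b)) {
    stop("k exceeds a group size: cannot sub-sample ", k, " of ",
         min(length(a), length(b)), " wells")
  }
  if (B < 1L) stop("B must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  reject <- 0L
  for (i in seq_len(B)) {
    sa <- a[sample.int(length(a), k)]
    sb <- b[sample.int(length(b), k)]
    res <- adaptive_test(sa, sb, boot_reps = boot_reps)
    if (res$p_value < alpha) reject <- reject + 1L
  }
  reject / B
}

#' Minimum sufficient wells per condition by sub-sampling
#'
#' Sweeps the number of wells per condition `k` upward and, for every
#' crosswise plate pair, estimates the probability that the adaptive
#' comparison between the two conditions rejects at `alpha` when `k` wells
#' are sub-sampled per condition. The minimum sufficient well count is the
#' smallest `k` whose rejection probability meets `criterion` in every pair
#' dataset simultaneously (`NA` if none does within the sweep).
#'
#' @param plates Input accepted by [plate_pairs()]: at least two plates.
#' @param conditions Length-2 character vector: the two conditions compared
#'   (default treated vs CI control).
#' @param alpha Significance level of the per-resample test.
#' @param criterion Required rejection probability (default 0.995).
#' @param B Sub-samples per (pair, k).
#' @param seed Root seed; each (pair, k) cell derives its own child stream,
#'   so results do not depend on sweep order.
#' @param k_range Candidate well counts, ascending (default 3 to the pooled
#'   group size).
#' @param stop_when_met Stop sweeping once the criterion holds in all pairs
#'   (the curve is then truncated at that `k`).
#' @param boot_reps Passed through to the per-resample test.
#' @return A `power_curve` object: data frame `curve` (`pair_id`, `k`,
#'   `rejection_probability`) plus fields `alpha`, `criterion`, `B`, and
#'   `min_sufficient_k` (integer or `NA`).
#' @examples
#' \donttest{
#' screen <- simulate_screen(default_calibration("nabu-effect", seed = 2))
#' pc <- min_sufficient_wells(screen, B = 200, seed = 9, stop_when_met = TRUE)
#' pc$min_sufficient_k
#' }
#' @export
min_sufficient_wells <- function(plates,
                                 conditions = c("ci-treated", "ci-control"),
                                 alpha = 0.05, criterion = 0.995, B = 2000L,
                                 seed = 1L, k_range = NULL,
                                 stop_when_met = FALSE, boot_reps = 10000L) {
  stopifnot(length(conditions) == 2L)
  pairs <- plate_pairs(plates)
  groups <- lapply(pairs, function(pd) {
    list(a = condition_rates(pd, conditions[1]),
         b = condition_rates(pd, conditions[2]))
  })
  max_k <- min(vapply(groups, function(g) min(length(g$a), length(g$b)),
                      numeric(1)))
  if (is.null(k_range)) k_range <- 3L:max_k
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range > max_k)) stop("k_range exceeds the pooled group size ", max_k)

  rows <- list()
  min_k <- NA_integer_
  for (k in k_range) {
    probs <- numeric(length(groups))
    for (j in seq_along(groups)) {
      cell_seed <- child_seed(seed, 1000L * k + j)
      probs[j] <- rejection_probability(groups[[j]]$a, groups[[j]]$b, k,
                                        alpha = alpha, B = B,
                                        seed = cell_seed,
                                        boot_reps = boot_reps)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      pair_id = names(groups), k = k, rejection_probability = probs,
      stringsAsFactors = FALSE, row.names = NULL
    )
    if (is.na(min_k) && all(probs >= criterion)) {
      min_k <- k
      if (stop_when_met) break
    }
  }
  structure(
    list(curve = do.call(rbind, rows), alpha = alpha, criterion = criterion,
         B = as.integer(B), k_range = k_range,
         min_sufficient_k = min_k),
    class = "power_curve"
  )
}

#' @export
print.power_curve <- function(x, ...) {
  cat(sprintf("Sub-sampling power curve: alpha = %g, criterion = %g, B = %d\n",
              x$alpha, x$criterion, x$B))
  agg <- stats::aggregate(rejection_probability ~ k, data = x$curve, FUN = min)
  names(agg)[2] <- "min_rejection_probability_over_pairs"
  print(agg, row.names = FALSE)
  if (is.na(x$min_sufficient_k)) {
    cat("criterion not met at any swept k\n")
  } else {
    cat("minimum sufficient wells per condition:", x$min_sufficient_k, "\n")
  }
  invisible(x)
}
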