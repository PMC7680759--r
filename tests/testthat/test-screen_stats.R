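test_that("alpha policies scale the base level by the category count", {
  expect_equal(alpha_policy(0.05, 6)$alpha_adj, 0.05 / 6)  # 0.0083
  expect_equal(alpha_policy(0.05, 4)$alpha_adj, 0.0125)
  expect_equal(alpha_policy(0.05, 1)$alpha_adj, 0.05)
  expect_error(alpha_policy(0.05, 0))
  expect_error(alpha_policy(1.5, 2))
})

test_that("the decision path picks the conventional test for each data shape", {
  set.seed(71)
  picks <- replicate(200, choose_test(rnorm(20), rnorm(20))$test_name)
  expect_gt(mean(picks == "t"), 0.7)

  set.seed(72)
  picks <- replicate(200, choose_test(exp(rnorm(20)), exp(rnorm(20)))$test_name)
  expect_gt(mean(picks == "mann-whitney-u"), 0.6)

  # normal with strongly unequal spread: Welch branch dominates
  set.seed(73)
  picks <- replicate(200, choose_test(rnorm(20, sd = 1),
                                      rnorm(20, sd = 6))$test_name)
  expect_gt(mean(picks == "welch-t"), 0.6)

  expect_error(choose_test(c(1, 2), c(1, 2, 3)), "at least 3")
  expect_true(choose_test(rep(0.1, 5), rep(0.1, 5))$degenerate)
})

test_that("screening diagnostics agree with the reference implementations", {
  skip_if_not_installed("car")
  set.seed(74)
  for (i in 1:10) {
    a <- exp(rnorm(12)); b <- rnorm(15)
    ours <- choose_test(a, b)
    lt <- car::leveneTest(c(a, b), factor(rep(1:2, c(12, 15))), center = mean)
    expect_equal(ours$levene_p, lt[["Pr(>F)"]][1], tolerance = 1e-10)
    expect_equal(ours$shapiro_p[1], stats::shapiro.test(a)$p.value)
  }
})

test_that("identical groups show no separation, extreme ones full separation", {
  skewed <- c(0.01, 0.02, 0.03, 0.04, 0.05, 0.1, 0.5, 3)
  r <- compare_conditions(skewed, skewed)
  expect_equal(r$test_name, "mann-whitney-u")
  expect_equal(r$p_value, 1)

  # constant groups with distinct values: degenerate, complete separation
  r2 <- compare_conditions(rep(0.1, 3), rep(0.9, 3))
  expect_true(r2$diagnostics$degenerate)
  expect_equal(r2$p_value, 0)
  expect_equal(compare_conditions(rep(0.4, 3), rep(0.4, 3))$p_value, 1)

  # a 10-sd shift between tight normal groups
  set.seed(75)
  r3 <- compare_conditions(rnorm(10, 0, 0.01), rnorm(10, 0.1, 0.01))
  expect_lt(r3$p_value, 1e-6)
})

test_that("the calibrated NaBu effect is detected at 16 wells per condition", {
  params <- default_calibration("nabu-effect")
  set.seed(76)
  detected <- replicate(50, {
    # 16 wells per condition = two pooled 8-well plates
    d <- rbind(
      simulate_screen_plate(params, plate_id = "P1",
                            conditions = c("ci-control", "ci-treated")),
      simulate_screen_plate(params, plate_id = "P2",
                            conditions = c("ci-control", "ci-treated"))
    )
    r <- compare_conditions(condition_rates(d, "ci-treated"),
                            condition_rates(d, "ci-control"), boot_reps = 2000)
    r$p_value < 0.05
  })
  expect_gte(mean(detected), 0.99)
})

test_that("two-sided p-values are symmetric under group exchange", {
  set.seed(77)
  for (i in 1:10) {
    a <- rnorm(12, 0.2, 0.05); b <- rnorm(12, 0.25, 0.05)
    r1 <- compare_conditions(a, b, seed = 5)
    r2 <- compare_conditions(b, a, seed = 5)
    tol <- if (r1$test_name == "bootstrap-t") 0.02 else 1e-12
    expect_equal(r1$p_value, r2$p_value, tolerance = tol)
    expect_equal(r1$test_name, r2$test_name)
  }
})

test_that("the bootstrap t branch is calibrated against the Welch branch", {
  # heteroscedastic normal data: bootstrap null reference should give a
  # p-value close to the analytic Welch p at moderate n
  set.seed(78)
  a <- rnorm(25, 0.2, 0.02); b <- rnorm(25, 0.21, 0.08)
  welch <- stats::t.test(a, b)$p.value
  set.seed(79)
  boot <- ciscreen:::boot_welch_p(a, b, 20000)
  expect_equal(boot, welch, tolerance = 0.05)
})

test_that("chi-square goodness of fit matches hand evaluation", {
  r <- chi_square_gof(c(8, 12), 0.5)
  expect_equal(r$statistic, 0.8)  # (8-10)^2/10 + (12-10)^2/10
  expect_equal(r$p_value, stats::pchisq(0.8, 1, lower.tail = FALSE))
  expect_equal(chi_square_gof(c(10, 10), 0.5)$statistic, 0)

  # brute-force oracle on random 2-cell tables
  set.seed(80)
  for (i in 1:50) {
    o <- sample(0:500, 2L)
    if (sum(o) == 0) o <- o + 1L
    ref <- stats::runif(1, 0.05, 0.95)
    e <- sum(o) * c(ref, 1 - ref)
    brute <- (o[1] - e[1])^2 / e[1] + (o[2] - e[2])^2 / e[2]
    expect_equal(chi_square_gof(o, ref)$statistic, brute, tolerance = 1e-10)
  }

  expect_error(chi_square_gof(c(0, 0), 0.5), "no observations")
  expect_error(chi_square_gof(c(5, 5), 1), "inside \\(0, 1\\)")
})

test_that("the mating-confirmed CI cross rejects the control hatch rate", {
  # pooled counts reconstructed from printed rates: CI 10% of 672 eggs,
  # control cross 90% of 679 eggs; judged at the four-category adjusted alpha
  ci <- counts_from_rate(10, 672)
  ctrl <- counts_from_rate(90, 679)
  ref <- ctrl[["hatched"]] / sum(ctrl)
  r <- chi_square_gof(ci, ref, policy = alpha_policy(0.05, 4))
  expect_equal(r$alpha_used, 0.0125)
  expect_true(r$significant)
  expect_lt(r$p_value, 0.001)
})

test_that("hit classification applies the borderline band", {
  expect_equal(classify_hit(0.047)$grade, "Borderline")
  expect_equal(classify_hit(0.769)$grade, "No")
  expect_equal(classify_hit(0.005)$grade, "Yes")
  expect_equal(classify_hit(0.04)$grade, "Borderline")   # band is [0.04, 0.05)
  expect_equal(classify_hit(0.05)$grade, "No")
  r <- compare_conditions(c(0.2, 0.22, 0.25, 0.3), c(0.1, 0.11, 0.12, 0.13))
  expect_s3_class(classify_hit(r, treatment = "NaBu"), "hit_call")
  expect_error(classify_hit(0.02, borderline_low = 0.06), "thresholds")
})

test_that("score_treatment runs the gate, comparison and call end to end", {
  screen <- simulate_screen(default_calibration("nabu-effect", seed = 13),
                            treatment = "NaBu")
  out <- score_treatment(screen, treatment = "NaBu", seed = 1)
  expect_s3_class(out$hit_call, "hit_call")
  expect_equal(out$hit_call$treatment, "NaBu")
  expect_equal(out$hit_call$grade, "Yes")
  expect_equal(nrow(out$qc), 5L)
})
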