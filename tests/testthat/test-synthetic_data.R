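test_that("simulation parameters are validated", {
  expect_error(sim_params(p = c(0.5)), "named")
  expect_error(sim_params(p = c("ci-control" = 1.2)), "\\(0, 1\\)")
  expect_error(sim_params(p = c("ci-control" = 0.1), rho = 1), "rho")
  expect_error(sim_params(p = c("ci-control" = 0.1), lambda = 0), "lambda")
})

test_that("calibrated scenarios carry the expected condition means", {
  nabu <- default_calibration("nabu-effect")
  expect_equal(nabu$p[["ci-treated"]], 0.25)
  expect_equal(nabu$p[["ci-control"]], 0.12)
  expect_equal(nabu$p[["rescue-control"]], 0.92)
  expect_equal(nabu$p[["control-cross"]], 0.90)
  expect_equal(nabu$lambda, 150)
  expect_equal(nabu$rho, 0.002)
  null <- default_calibration("ci-null")
  expect_equal(null$p[["ci-treated"]], null$p[["ci-control"]])
  expect_equal(default_calibration("rescue-vs-ci")$p[["rescue-control"]], 0.92)
  expect_error(default_calibration("unknown"))
})

test_that("plate layout follows the 24-well screen format", {
  params <- default_calibration("nabu-effect")
  set.seed(11)
  plate <- simulate_screen_plate(params)
  expect_equal(nrow(plate), 24L)
  expect_equal(unname(table(plate$condition)[c("ci-control", "ci-treated",
                                               "rescue-control")]),
               rep(8L, 3), ignore_attr = TRUE)
  expect_true(all(plate$eggs_laid >= 1L))

  small <- sim_params(p = params$p, n_wells_per_condition = 1L)
  set.seed(11)
  expect_equal(nrow(simulate_screen_plate(small)), 3L)

  over <- sim_params(p = params$p, n_wells_per_condition = 9L)
  expect_error(simulate_screen_plate(over), "capacity")
})

test_that("the generator is bit-reproducible from the root seed", {
  params <- default_calibration("nabu-effect", seed = 77)
  a <- simulate_screen(params)
  b <- simulate_screen(params)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_screen(default_calibration("nabu-effect", seed = 78))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("a near-zero hatch mean yields no hatching", {
  params <- sim_params(p = c("ci-control" = 1e-9), lambda = 150)
  set.seed(21)
  wells <- replicate(50, simulate_well("ci-control", params)$eggs_hatched)
  expect_true(all(wells == 0L))
})

test_that("binomial sampling recovers the condition mean at large n", {
  params <- sim_params(p = c("ci-control" = 0.12), rho = 0, lambda = 150,
                       n_wells_per_condition = 1L)
  set.seed(31)
  n <- 10000L
  eggs <- integer(n); hatched <- integer(n)
  for (i in seq_len(n)) {
    w <- simulate_well("ci-control", params)
    eggs[i] <- w$eggs_laid; hatched[i] <- w$eggs_hatched
  }
  pooled <- sum(hatched) / sum(eggs)
  mc_se <- sqrt(0.12 * 0.88 / sum(eggs))
  expect_lt(abs(pooled - 0.12), 3 * mc_se)
})

test_that("per-well rate variance follows the beta-binomial law", {
  p <- 0.12; rho <- 0.01; lambda <- 150
  params <- sim_params(p = c("ci-control" = p), rho = rho, lambda = lambda)
  set.seed(41)
  n <- 10000L
  eggs <- rep(0L, n); hatched <- rep(0L, n)
  for (i in seq_len(n)) {
    w <- simulate_well("ci-control", params)
    eggs[i] <- w$eggs_laid; hatched[i] <- w$eggs_hatched
  }
  v_emp <- stats::var(hatched / eggs)
  v_theory <- p * (1 - p) * (1 + (lambda - 1) * rho) / lambda
  expect_lt(abs(v_emp - v_theory) / v_theory, 0.2)
})

test_that("moment fitting recovers p and rho from a large dataset", {
  p <- 0.12; rho <- 0.002; lambda <- 150
  params <- sim_params(p = c("ci-control" = p), rho = rho, lambda = lambda)
  set.seed(51)
  n <- 10000L
  eggs <- stats::rpois(n, lambda); eggs[eggs < 1L] <- 1L
  q <- stats::rbeta(n, p * (1 - rho) / rho, (1 - p) * (1 - rho) / rho)
  hatched <- stats::rbinom(n, eggs, q)
  # p: pooled rate of a package-simulated dataset
  sim_eggs <- integer(n); sim_hatched <- integer(n)
  for (i in seq_len(n)) {
    w <- simulate_well("ci-control", params)
    sim_eggs[i] <- w$eggs_laid; sim_hatched[i] <- w$eggs_hatched
  }
  p_hat <- sum(sim_hatched) / sum(sim_eggs)
  expect_lt(abs(p_hat - p), 0.01)
  # rho: method of moments on the per-well rate variance
  rates <- sim_hatched / sim_eggs
  inv_n <- mean(1 / sim_eggs)
  rho_hat <- (stats::var(rates) / (p_hat * (1 - p_hat)) - inv_n) / (1 - inv_n)
  expect_gt(rho_hat, rho / 2)
  expect_lt(rho_hat, rho * 2)
})
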