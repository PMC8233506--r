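test_that("closed-form trajectory solves the growth ODE and hits its limits", {
  p <- growth_params(y0 = 0.01, r = 0.8, k = 1.2, nu = 1.3, q0 = 0.05, v = 0.9)
  tt <- seq(0, 30, by = 0.25)
  traj <- br_trajectory(p, tt)
  # independent numerical integration oracle
  ode <- deSolve::lsoda(
    c(n = p$y0), tt,
    function(t, n, parms) {
      list(p$r * (p$q0 / (p$q0 + exp(-p$v * t))) * n * (1 - (n / p$k)^p$nu))
    }, NULL, rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(traj - ode[, "n"])), 1e-7)

  expect_equal(traj[1], p$y0)                      # t = 0
  expect_true(all(diff(traj) >= -1e-12))           # non-decreasing
  t_sat <- 10 * (br_lag(p$q0, p$v) + log(p$k / p$y0) / p$r)
  expect_lt(abs(br_trajectory(p, t_sat) - p$k), 1e-6 * p$k)

  # fully activated cells with nu = 1 follow the plain logistic closed form
  pl <- growth_params(y0 = 0.01, r = 0.8, k = 1.2, nu = 1, q0 = 1e9, v = 1)
  logistic <- pl$k * pl$y0 * exp(pl$r * tt) / (pl$k + pl$y0 * (exp(pl$r * tt) - 1))
  expect_lt(max(abs(br_trajectory(pl, tt) - logistic)), 1e-6)

  expect_error(br_trajectory(p, c(2, 1)), "non-decreasing")
  expect_error(growth_params(y0 = 0.5, r = 1, k = 0.2, q0 = 1, v = 1), "y0")
})

test_that("fitting recovers the generating parameters from a noiseless curve", {
  p <- ancestor_growth()
  curve <- gen_growth_curve(p, horizon = 24, interval = 5,
                            noise = noise_model(od_sd = 0), seed = 1)
  fit <- fit_growth(curve)
  expect_true(fit$ok)
  for (nm in names(p)) {
    expect_lt(abs(fit$params[[nm]] / p[[nm]] - 1), 0.01)
  }
  expect_lt(abs(fit$lag / br_lag(p$q0, p$v) - 1), 0.01)
  # refit reproduces the curve without overfit blow-up
  expect_lt(fit$rss / fit$n_points, 1e-10)
  # deterministic given the fixed multi-start grid
  expect_identical(fit$params, fit_growth(curve)$params)
})

test_that("degenerate curves yield a flagged fit failure, not an error", {
  flat <- data.frame(time = seq(0, 10, by = 0.25), od = 0.5)
  f1 <- fit_growth(flat)
  expect_false(f1$ok)
  expect_match(f1$diagnostic, "flat")

  rising <- data.frame(time = seq(0, 10, by = 0.25))
  rising$od <- 0.01 * exp(0.3 * rising$time) # never saturates
  f2 <- fit_growth(rising)
  expect_false(f2$ok)
  expect_match(f2$diagnostic, "saturate")

  expect_error(fit_growth(data.frame(time = 1:5, od = 1:5)), "20")
})

test_that("fitted lag difference recovers a true lag contrast under noise", {
  # two strains differing mainly in lag (5.00 vs 3.87 h), read every 5 min
  # with 0.005 OD additive noise
  p_long <- ancestor_growth(lag = 5.00)
  p_short <- ancestor_growth(lag = 3.87)
  n_rep <- 12
  lags <- vapply(seq_len(n_rep), function(i) {
    c(fit_growth(gen_growth_curve(p_long, 24, 5, noise_model(0.005), seed = i))$lag,
      fit_growth(gen_growth_curve(p_short, 24, 5, noise_model(0.005), seed = 1000 + i))$lag)
  }, numeric(2))
  gap <- mean(lags[1, ]) - mean(lags[2, ])
  expect_lt(abs(gap - 1.13), 0.2)
})

test_that("virtual competitions respect symmetry and growth-parameter advantages", {
  p <- ancestor_growth()
  vc <- virtual_competition(p, p)
  expect_identical(vc$w_virtual, 1) # exact symmetry
  expect_equal(vc$trajectories$n_a, vc$trajectories$n_b)

  # faster growth wins
  p_fast <- ancestor_growth(); p_fast$r <- p$r * 1.15
  expect_gt(virtual_competition(p_fast, p)$w_virtual, 1)
  # shorter lag wins
  p_lag <- ancestor_growth(lag = 3.5)
  expect_gt(virtual_competition(p_lag, p)$w_virtual, 1)

  # shared pool: total density never exceeds the larger capacity
  tot <- vc$trajectories$n_a + vc$trajectories$n_b
  expect_lt(max(tot), max(p$k, p$k) + 1e-6)

  # zero-growth horizon is flagged
  expect_warning(vc0 <- virtual_competition(p, p, horizon = 1e-6), "no net growth")
  expect_true(is.na(vc0$w_virtual))
  expect_equal(vc0$flag, "zero-growth")
})

test_that("concordance summarizes direct/virtual agreement and its degenerate cases", {
  x <- c(1.0, 1.05, 1.1, 0.97)
  expect_equal(concordance(x, x), list(correlation = 1, mean_abs_diff = 0, n = 4))

  set.seed(3)
  truth <- runif(20, 0.9, 1.2)
  d <- truth + rnorm(20, 0, 0.01)
  v <- truth + rnorm(20, 0, 0.01)
  expect_gt(concordance(d, v)$correlation, 0.9)

  expect_warning(cc <- concordance(c(1, 1.1, 1.2), c(1, 1, 1)), "constant")
  expect_true(is.na(cc$correlation))
  expect_error(concordance(1:3, 1:4), "pair")
  expect_error(concordance(1:2, 1:2), "3")
})
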