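test_that("growth-curve generator matches its deterministic skeleton", {
  p <- ancestor_growth()
  quiet <- noise_model(od_sd = 0)
  # zero noise: first reading is the initial density exactly
  curve <- gen_growth_curve(p, horizon = 24, interval = 5, noise = quiet)
  expect_equal(curve$od[1], p$y0)
  # 5-min readings over 24 h -> 289 rows including t = 0
  expect_equal(nrow(curve), 289L)
  expect_equal(curve$time[1], 0)
  expect_equal(max(curve$time), 24)
  # a lag-free parameter set follows the plain logistic solution
  pl <- growth_params(y0 = 0.01, r = 0.8, k = 1.2, nu = 1, q0 = 1e9, v = 1)
  cl <- gen_growth_curve(pl, 24, 5, quiet)
  logistic <- pl$k * pl$y0 * exp(pl$r * cl$time) /
    (pl$k + pl$y0 * (exp(pl$r * cl$time) - 1))
  expect_lt(max(abs(cl$od - logistic)), 1e-6)
  # determinism and noise reproducibility
  expect_identical(gen_growth_curve(p, 24, 5, noise_model(0.01), seed = 7),
                   gen_growth_curve(p, 24, 5, noise_model(0.01), seed = 7))
  expect_error(gen_growth_curve(p, horizon = 0), "horizon")
  expect_error(gen_growth_curve(p, interval = -5), "interval")
})

test_that("OD noise has the nominal spread and stays physical", {
  # saturated stretch, far from the truncation boundary
  p <- growth_params(y0 = 0.5, r = 1, k = 1.0, nu = 1, q0 = 10, v = 1)
  sd_target <- 0.01
  curve <- gen_growth_curve(p, horizon = 833.4, interval = 5,
                            noise = noise_model(sd_target), seed = 5)
  expect_gte(nrow(curve), 1e4)
  clean <- br_trajectory(p, curve$time)
  expect_lt(abs(stats::sd(curve$od - clean) / sd_target - 1), 0.1)
  expect_true(all(curve$od >= 0))
})

test_that("fluctuation counts follow the Luria-Delbruck construction", {
  expect_identical(gen_fluctuation_counts(0, 1e6, 5), rep.int(0L, 5))
  expect_error(gen_fluctuation_counts(-0.1, 1e6, 5), "rate")
  expect_error(gen_fluctuation_counts(1, 1e6, 5), "rate")
  # determinism
  expect_identical(gen_fluctuation_counts(1e-6, 1e6, 10, seed = 4),
                   gen_fluctuation_counts(1e-6, 1e6, 10, seed = 4))
  # P(no mutants) = e^(-m) at m = 1
  n_final <- 2^20; rate <- 1 / n_final
  counts <- gen_fluctuation_counts(rate, n_final, 1e4, seed = 8)
  p0 <- mean(counts == 0)
  se <- sqrt(exp(-1) * (1 - exp(-1)) / 1e4)
  expect_lt(abs(p0 - exp(-1)), 3 * se)
  # heavy right tail: mean count exceeds m for m >= 1
  expect_gt(mean(counts), 1)
})

test_that("competition counts invert the fitness estimator", {
  # no sampling noise at w = 1: frequencies unchanged
  a <- gen_competition_counts(1, 1000, 1000, d = 1,
                              noise = noise_model(count_sampling = "none"))
  expect_equal(a$n_a_initial / 1000, a$n_a_final / 1000)
  expect_equal(relative_fitness(a)$w_rel, 1)

  # large counts: estimator recovers the target fitness within 1%
  b <- gen_competition_counts(1.083, 1e6, 1e6, d = 1, seed = 2)
  expect_lt(abs(relative_fitness(b)$w_rel / 1.083 - 1), 0.01)
  # two-day competitions too
  b2 <- gen_competition_counts(1.083, 1e6, 1e6, d = 2, seed = 3)
  expect_lt(abs(relative_fitness(b2)$w_rel / 1.083 - 1), 0.01)

  expect_error(gen_competition_counts(1.1, 1000, 1000, d = 0), "d")
  expect_error(gen_competition_counts(-1, 1000, 1000, d = 1), "w_ratio")
  # poisson sampling draws valid assays as well
  expect_s3_class(gen_competition_counts(1.05, 500, 500, 1,
                                         noise = noise_model(count_sampling = "poisson"),
                                         seed = 1),
                  "competition_assay")
})

test_that("mutation-profile generator spans the full sharing range", {
  # full sharing: every clone carries the whole pool
  pr1 <- gen_mutation_profiles(4, 4, 40, 1, 1, seed = 1)
  ms1 <- group_mean_similarity(pr1)
  expect_equal(unname(ms1$within), c(1, 1))
  expect_equal(ms1$between, 1)

  # no sharing, private loci only
  pr0 <- gen_mutation_profiles(4, 4, 40, 0, 0, n_private = 3, seed = 1)
  ms0 <- group_mean_similarity(pr0)
  expect_equal(unname(ms0$within), c(0, 0))
  expect_equal(ms0$between, 0)

  expect_error(gen_mutation_profiles(0, 4, 40, 0.5, 0.5), "n_group_a")
  expect_identical(gen_mutation_profiles(3, 3, 20, 0.4, 0.2, seed = 9),
                   gen_mutation_profiles(3, 3, 20, 0.4, 0.2, seed = 9))
})

test_that("within-group similarity exceeds between-group when sharing is asymmetric", {
  diffs <- vapply(1:200, function(i) {
    pr <- gen_mutation_profiles(5, 5, 40, 0.5, 0.1, seed = i)
    ms <- group_mean_similarity(pr)
    mean(ms$within) - ms$between
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs) / (stats::sd(diffs) / sqrt(length(diffs))), 3)
})

test_that("generated tables are written with a JSON parameter sidecar", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "curve.csv")
  curve <- gen_growth_curve(ancestor_growth(), 4, 30, noise_model(0), seed = 1)
  write_synthetic(curve, path, params = list(seed = 1, od_sd = 0))
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$seed, 1L)
  back <- utils::read.csv(path)
  expect_equal(back$od, curve$od, tolerance = 1e-12)
})
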