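test_that("parameter validation enforces the model's domain", {
  expect_s3_class(sg_params(c = 1, k = 0, f_p = 0.5), "sg_params")
  expect_error(sg_params(c = 0, k = 1, f_p = 0.5), "'c'")
  expect_error(sg_params(c = 1, k = -1, f_p = 0.5), "'k'")
  expect_error(sg_params(c = 1, k = 1, f_p = 1.2), "f_p")
  expect_error(sg_params(c = 1, k = 1, f_p = 0.5, p0 = 0), "p0")
  expect_error(sg_params(c = 1, k = 1, f_p = 0.5, d0 = -1), "d0")
  expect_error(sg_params(c = 1, k = 1, f_p = 0.5, t_onset = 9, t_end = 2),
               "t_end")
  expect_error(sg_params(c = 1, k = 1, f_p = 0.5, decay_scale = 0),
               "decay_scale")
})

test_that("growth rate matches its closed form and monotonicities", {
  p1 <- sg_params(c = 1, k = 2, f_p = 0.8)
  expect_equal(growth_rate(11, 0, 0, p1), 1.0)
  expect_equal(growth_rate(10, 10, 0, p1), 4.0)
  p2 <- sg_params(c = 2, k = 0, f_p = 0.8)
  expect_equal(growth_rate(10, 0, 2, p2), 2 * exp(-4 / 2), tolerance = 1e-12)
  # strictly decreasing in t; non-decreasing in d
  ts <- seq(0, 5, by = 0.5)
  expect_true(all(diff(growth_rate(10, 5, ts, p1)) < 0))
  ds <- seq(0, 50, by = 5)
  expect_true(all(diff(growth_rate(10, ds, 1, p1)) >= 0))
  # independent decay scale decouples duration from amplitude
  p3 <- sg_params(c = 2, k = 0, f_p = 0.8, decay_scale = 8)
  expect_equal(growth_rate(10, 0, 2, p3), 2 * exp(-4 / 8), tolerance = 1e-12)
  expect_error(growth_rate(0, 1, 0, p1), "positive")
  expect_error(growth_rate(10, -1, 0, p1), "d")
})

test_that("rate equations respect self-renewal bookkeeping", {
  st <- c(P = 10, D = 4)
  half <- sg_rhs(1, st, sg_params(c = 1.3, k = 1, f_p = 0.5))[[1]]
  expect_equal(half[1], 0)
  pure_renew <- sg_rhs(0, c(P = 10, D = 0),
                       sg_params(c = 1, k = 0, f_p = 1))[[1]]
  expect_equal(pure_renew, c(10, 0))
  pure_diff <- sg_rhs(0, c(P = 10, D = 0),
                      sg_params(c = 1, k = 0, f_p = 0))[[1]]
  expect_equal(pure_diff, c(-10, 10))
  expect_equal(sum(pure_diff), 0)
  # dp + dd = f_p * u * p for a generic state
  pr <- sg_params(c = 1.5, k = 2, f_p = 0.7)
  r <- sg_rhs(0.5, st, pr)[[1]]
  expect_equal(sum(r), pr$f_p * growth_rate(10, 4, 0.5, pr) * 10,
               tolerance = 1e-12)
})

test_that("trajectories satisfy the compartment invariants", {
  set.seed(3)
  for (i in 1:6) {
    pr <- sg_params(c = runif(1, 0.5, 2.5), k = runif(1, 0, 2.5),
                    f_p = runif(1, 0.5, 1))
    tr <- simulate_sg(pr)
    expect_equal(tr$P[1], pr$p0)
    expect_equal(tr$D[1], pr$d0)
    expect_true(all(tr$P >= 0) && all(tr$D >= 0))
    expect_true(all(diff(tr$D) >= -1e-8))
    expect_true(all(diff(tr$total) >= -1e-8))
  }
})

test_that("f_p = 0 conserves the total and f_p = 0.5 freezes the basal layer", {
  for (k in c(0, 1, 2)) {
    tr <- quiet(simulate_sg(sg_params(c = 1.5, k = k, f_p = 0)))
    expect_lt(max(abs(tr$total - 11)) / 11, 1e-6)
  }
  tr5 <- simulate_sg(sg_params(c = 1.5, k = 2, f_p = 0.5))
  expect_lt(max(abs(tr5$P - 11)) / 11, 1e-6)
})

test_that("the decoupled k = 0 case reaches its Gaussian-integral limit", {
  # dD/dt = 0.5 * p0 * c * exp(-t^2/c) with constant P, so
  # d(inf) = 0.5 * p0 * c * sqrt(pi * c) / 2
  for (cc in c(0.5, 1, 2)) {
    pr <- sg_params(c = cc, k = 0, f_p = 0.5, t_onset = 0, t_end = 40)
    d_inf <- endpoint(simulate_sg(pr))[["d_end"]]
    expect_equal(d_inf, 0.5 * 11 * cc * sqrt(pi * cc) / 2,
                 tolerance = 1e-4)
  }
})

test_that("adaptive endpoints match the fixed-step Euler oracle", {
  for (v in oracle_panel[c(1, 5, 10)]) {
    pr <- panel_params(v)
    e_ad <- endpoint(simulate_sg(pr))
    e_eu <- euler_endpoint(pr)
    expect_lt(max(abs(e_ad[1:2] - e_eu) / e_eu), 1e-3)
  }
})

test_that("endpoints are insensitive to the output grid resolution", {
  pr <- sg_params(c = 1.5, k = 2, f_p = 0.8)
  e1 <- endpoint(simulate_sg(pr, dt = 0.5))
  e2 <- endpoint(simulate_sg(pr, dt = 0.005))
  expect_equal(e1, e2, tolerance = 1e-7)
  # growth cessation: extending the horizon far past decay changes nothing
  pr_long <- sg_params(c = 1.5, k = 2, f_p = 0.8, t_end = 20)
  expect_equal(endpoint(simulate_sg(pr_long))[["total"]],
               e1[["total"]], tolerance = 1e-5)
})

test_that("endpoint extraction and division bookkeeping are consistent", {
  pr <- sg_params(c = 1.5, k = 2, f_p = 0.8)
  tr <- simulate_sg(pr)
  e <- endpoint(tr)
  expect_equal(e[["total"]], e[["p_end"]] + e[["d_end"]])
  expect_equal(unname(e[1:2]), c(tr$P[nrow(tr)], tr$D[nrow(tr)]))

  bk <- division_bookkeeping(tr)
  expect_lt(max(abs(bk$residual)) / max(bk$net_gain), 1e-6)
  # f_p = 1: every division self-renews, net gain is all basal
  tr1 <- simulate_sg(sg_params(c = 1, k = 1, f_p = 1))
  bk1 <- division_bookkeeping(tr1)
  expect_equal(bk1$net_gain, tr1$P - 11, tolerance = 1e-9)
  # f_p = 0: no net gain anywhere
  tr0 <- quiet(simulate_sg(sg_params(c = 1, k = 0, f_p = 0)))
  bk0 <- division_bookkeeping(tr0)
  expect_lt(max(abs(bk0$net_gain)), 1e-6)
  expect_lt(max(abs(bk0$cum_divisions)), 1e-12)
})

test_that("trajectory CSV round-trips and configs are read from flat files", {
  pr <- sg_params(c = 1.2, k = 1, f_p = 0.8)
  tr <- simulate_sg(pr, dt = 0.5)
  csv <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, csv)
  back <- read.csv(csv)
  expect_named(back, c("postnatal_day", "t_model", "P", "D", "total"))
  expect_equal(back$P, tr$P, tolerance = 1e-12)

  cfg <- tempfile(fileext = ".yml")
  writeLines(c("c: 1.2", "k: 1", "f_p: 0.8", "t_end: 7"), cfg)
  got <- read_sg_params(cfg)
  expect_equal(got$c, 1.2)
  expect_equal(got$t_end, 7)
  expect_equal(got$p0, 11)
  writeLines(c("k: 1", "f_p: 0.8"), cfg)
  expect_error(read_sg_params(cfg), "missing required")
})
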