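test_that("observation containers validate and round-trip through TSV", {
  obs <- count_observations(day = c(2, 9, 9), quantity = c("total", "P", "D"),
                            value = c(11, 40, 210))
  expect_s3_class(obs, "count_observations")
  expect_error(count_observations(numeric(0), character(0), numeric(0)),
               "at least one")
  expect_error(count_observations(2, "X", 5), "quantity")
  expect_error(count_observations(2, "P", -1), ">= 0")
  expect_error(count_observations(c(2, 2), c("P", "P"), c(1, 2)), "duplicate")

  tsv <- tempfile(fileext = ".tsv")
  write_count_observations(obs, tsv)
  expect_equal(read_count_observations(tsv), obs)
})

test_that("the loss is zero at truth and matches a hand-summed example", {
  truth <- sg_params(c = 1.5, k = 2, f_p = 0.8)
  obs <- synth_count_observations(truth, obs_days = 2:9, count_noise_cv = 0,
                                  seed = 1)
  expect_lt(sg_objective(truth, obs), 1e-10)

  # doubled single total: ((2x - x) / x)^2 = 1
  tr <- simulate_sg(truth)
  sim_total <- endpoint(tr)[["total"]]
  obs2 <- count_observations(9, "total", sim_total / 2)
  expect_equal(sg_objective(truth, obs2), 1.0, tolerance = 1e-6)

  # hand-summed three-day loss with weights
  days <- c(4, 6, 9)
  mu <- sapply(days, function(dd) tr$total[which.min(abs(tr$postnatal_day - dd))])
  vals <- c(10, 50, 100)
  w <- c(1, 2, 0.5)
  obs3 <- count_observations(days, rep("total", 3), vals, w)
  expect_equal(sg_objective(truth, obs3),
               sum(w * ((mu - vals) / vals)^2), tolerance = 1e-6)
})

test_that("the multistart fit recovers generating parameters from noiseless data", {
  truth <- sg_params(c = 1.5, k = 2, f_p = 0.8)
  obs <- synth_count_observations(truth, obs_days = 2:9, count_noise_cv = 0,
                                  seed = 7)
  fit <- quiet(sg_fit(obs, n_starts = 32, seed = 1))
  expect_true(fit$converged)
  expect_lt(max(abs(coef(fit) - c(1.5, 2, 0.8)) / c(1.5, 2, 0.8)), 1e-2)
  expect_lte(fit$objective, min(fit$per_start_losses, na.rm = TRUE))
})

test_that("noisy totals pin the trajectory even where parameters are sloppy", {
  # Totals-only data leave a sloppy, multi-modal valley in (c, k, f_p):
  # distant parameter combinations reproduce the same total-count curve
  # almost equally well, so individual parameters are not recoverable
  # from noisy totals. What the data do pin down is the fitted
  # trajectory itself.
  truth <- sg_params(c = 1.5, k = 2, f_p = 0.8)
  noisy <- synth_count_observations(truth, obs_days = 2:9,
                                    count_noise_cv = 0.05,
                                    n_replicates = 20, seed = 1)
  fit <- quiet(sg_fit(noisy, n_starts = 32, seed = 1))
  # the optimum found is at least as good as the generating parameters
  expect_lte(fit$objective, sg_objective(truth, noisy) * (1 + 1e-6))
  pred <- predict(fit, days = 2:9)$total
  tr <- simulate_sg(truth)
  tru <- sapply(2:9, function(dd) tr$total[which.min(abs(tr$postnatal_day - dd))])
  expect_lt(max(abs(pred - tru) / tru), 0.05)
})

test_that("fits are deterministic given seed, data and bounds", {
  truth <- sg_params(c = 1.2, k = 1, f_p = 0.75)
  obs <- synth_count_observations(truth, obs_days = c(3, 5, 7, 9),
                                  count_noise_cv = 0, seed = 2)
  f1 <- quiet(sg_fit(obs, n_starts = 6, seed = 42))
  f2 <- quiet(sg_fit(obs, n_starts = 6, seed = 42))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$per_start_losses, f2$per_start_losses)
})

test_that("degenerate and under-determined inputs are reported as such", {
  # constant observations at the initial pool: the optimum is the
  # zero-growth limit (c at its floor and/or pure differentiation off)
  obs_flat <- count_observations(c(3, 5, 7), rep("total", 3), rep(11, 3))
  fit_flat <- quiet(sg_fit(obs_flat, n_starts = 8, seed = 1))
  expect_lt(fit_flat$objective, 1e-6)
  expect_equal(endpoint(simulate_sg(fit_flat$params))[["total"]], 11,
               tolerance = 1e-2)

  # a single endpoint pair cannot pin three parameters
  obs_end <- count_observations(c(9, 9), c("P", "D"), c(40, 210))
  fit_end <- quiet(sg_fit(obs_end, n_starts = 12, seed = 1))
  expect_true(fit_end$underdetermined)

  expect_error(sg_fit(obs_end, bounds = list(c = c(2, 1), k = c(0, 6),
                                             f_p = c(0, 1))),
               "infeasible")
})

test_that("fit methods expose coefficients, predictions and residuals", {
  truth <- sg_params(c = 1.5, k = 2, f_p = 0.8)
  obs <- synth_count_observations(truth, obs_days = c(3, 5, 7, 9),
                                  count_noise_cv = 0, seed = 5)
  fit <- quiet(sg_fit(obs, n_starts = 16, seed = 3))
  expect_named(coef(fit), c("c", "k", "f_p"))
  pred <- predict(fit, days = c(2, 9))
  expect_equal(pred$total[1], 11, tolerance = 1e-6)
  expect_equal(pred$P + pred$D, pred$total, tolerance = 1e-9)
  r <- residuals(fit)
  expect_length(r, nrow(obs))
  expect_lt(max(abs(r)), 1e-2)
  expect_equal(fitted(fit) / obs$value - 1, unname(r), tolerance = 1e-9)
  s <- summary(fit)
  expect_s3_class(s, "summary.sg_fit")
  sims <- simulate(fit, nsim = 3, seed = 9, cv = 0.1)
  expect_equal(dim(sims), c(nrow(obs), 3L))
  expect_true(all(sims > 0))
})
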