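test_that("closed-form trajectory matches its analytic values and contracts", {
  # pre-onset and t = 0 are exactly zero
  expect_equal(predict_mrna(kinetic_params(0, 2, 1), 0), 0)
  expect_equal(predict_mrna(kinetic_params(5, 3, 0.5), 4), 0)
  # (alpha/delta)(1 - exp(-delta t)) at t = ln 2 with alpha=2, delta=1 is 1
  expect_equal(predict_mrna(kinetic_params(0, 2, 1), log(2)), 1.0)
  # zero degradation falls back to linear accumulation
  expect_equal(predict_mrna(kinetic_params(1, 2, 0), 3), 4)

  # monotone non-decreasing and converging to the steady state
  p <- kinetic_params(2, 1.5, 0.4)
  tgrid <- seq(0, 2 + 20 / 0.4, length.out = 400)
  traj <- predict_mrna(p, tgrid)
  expect_true(all(diff(traj) >= 0))
  expect_true(all(traj <= steady_state_level(p) + 1e-12))
  expect_equal(traj[length(traj)], steady_state_level(p),
               tolerance = 1e-6)
  expect_error(predict_mrna(p, -1), "non-negative")
  expect_error(kinetic_params(-1, 1, 1), "non-negative")
})

test_that("Runge-Kutta integration agrees with the closed form", {
  cases <- list(
    list(p = kinetic_params(0, 2, 1), grid = seq(0, 10, by = 0.1)),
    list(p = kinetic_params(3, 1, 0.2), grid = seq(0, 14, by = 2)),
    list(p = kinetic_params(3.417, 0.27, 1.41), grid = seq(0, 14, by = 0.25)),
    list(p = kinetic_params(0.05, 5, 3), grid = seq(0, 6, by = 0.1))
  )
  for (cs in cases) {
    num <- predict_mrna_numeric(cs$p, cs$grid)
    expect_lt(max(abs(num - predict_mrna(cs$p, cs$grid))), 1e-8)
  }
  # no production stays identically zero; pre-onset grid points are zero
  expect_equal(predict_mrna_numeric(kinetic_params(0, 0, 1), 0:10),
               rep(0, 11))
  expect_equal(predict_mrna_numeric(kinetic_params(3, 1, 0.2),
                                    seq(0, 14, 2))[1:2], c(0, 0))
  expect_error(predict_mrna_numeric(kinetic_params(0, 1, 1), c(0, 2, 1)),
               "increasing")
})

test_that("steady state and half-steady-state time follow the closed form", {
  expect_equal(steady_state_level(kinetic_params(0, 2, 1)), 2.0)
  expect_equal(steady_state_level(kinetic_params(0, 0, 0.3)), 0.0)
  expect_equal(steady_state_level(kinetic_params(0, 0.45, 0.5)), 0.9)
  expect_error(steady_state_level(kinetic_params(0, 1, 0)), "degradation")

  expect_equal(half_steady_state_time(kinetic_params(0, 1, 1)), log(2))
  expect_equal(half_steady_state_time(kinetic_params(3, 1, log(2))), 4.0)
  expect_error(half_steady_state_time(kinetic_params(0, 0, 1)), "production")

  # root-finding on the trajectory agrees with the analytic inversion,
  # including at the minutes-scale parameters typical of real fits
  for (p in list(kinetic_params(204.8, 0.9 * 0.0235, 0.0235),
                 kinetic_params(0, 1, 0.5),
                 kinetic_params(3.2, 0.2, 1.4))) {
    t_half <- half_steady_state_time(p)
    expect_lt(abs(half_steady_state_time(p, method = "numeric") - t_half),
              1e-6)
    # the trajectory at the returned time is half of the steady state
    expect_equal(predict_mrna(p, t_half), steady_state_level(p) / 2,
                 tolerance = 1e-6)
  }
})

test_that("rmsd matches hand-computed values and checks lengths", {
  expect_equal(rmsd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmsd(c(1, 2, 3), c(1, 2, 3) + 0.7), 0.7)
  expect_equal(rmsd(c(0, 1, 2), c(0, 0, 0)), sqrt(5 / 3))
  expect_error(rmsd(1:3, 1:4), "length")
})

test_that("fitting recovers noiseless parameters within 1%", {
  truth <- kinetic_params(3.4, 0.3, 0.33)
  fit <- fit_kinetics(noiseless_tc(truth), n_starts = 50, seed = 7)
  expect_lt(rel_err(fit$params$onset_time, 3.4), 0.01)
  expect_lt(rel_err(fit$params$production_rate, 0.3), 0.01)
  expect_lt(rel_err(fit$params$degradation_rate, 0.33), 0.01)
  expect_true(all(unlist(fit$params) >= 0))

  # constrained-onset variant recovers the remaining two parameters
  truth0 <- kinetic_params(0, 1, 0.5)
  fit0 <- fit_kinetics(noiseless_tc(truth0), fix_onset_zero = TRUE,
                       n_starts = 20, seed = 3)
  expect_identical(fit0$params$onset_time, 0)
  expect_true(fit0$onset_fixed_zero)
  expect_lt(rel_err(fit0$params$production_rate, 1), 0.01)
  expect_lt(rel_err(fit0$params$degradation_rate, 0.5), 0.01)
})

test_that("degenerate all-zero input yields a zero-production fit", {
  tc <- as_timecourse(
    data.frame(time = rep(seq(0, 14, 2), 2), replicate = rep(1:2, each = 8),
               value = 0),
    time_unit = "hours"
  )
  expect_warning(fit <- fit_kinetics(tc, n_starts = 5, seed = 1),
                 "zero")
  expect_lte(fit$params$production_rate, 1e-6)
})

test_that("best objective is monotone non-increasing in the number of starts", {
  truth <- kinetic_params(2.7, 0.8, 0.6)
  tc <- noiseless_tc(truth)
  set.seed(99)
  tc$value <- tc$value * (1 + rnorm(nrow(tc), 0, 0.08))
  tc$value <- pmax(tc$value, 0)
  objs <- vapply(c(2, 5, 10, 20), function(ns) {
    fit_kinetics(tc, n_starts = ns, seed = 11)$rmsd
  }, numeric(1))
  expect_true(all(diff(objs) <= 1e-12))
})

test_that("parameter recovery under 1% noise: median relative errors below 10%", {
  set.seed(202)
  errs <- t(vapply(1:20, function(i) {
    truth <- kinetic_params(
      onset_time = runif(1, 1, 6),
      production_rate = runif(1, 0.2, 2),
      degradation_rate = runif(1, 0.2, 1.5)
    )
    times <- seq(0, 14, by = 2)
    vals <- predict_mrna(truth, times)
    tc <- as_timecourse(
      data.frame(
        time = rep(times, 3), replicate = rep(1:3, each = length(times)),
        value = pmax(rep(vals, 3) * (1 + rnorm(3 * length(times), 0, 0.01)), 0)
      ),
      time_unit = "hours"
    )
    fit <- fit_kinetics(tc, n_starts = 25, seed = 500 + i)
    c(rel_err(fit$params$onset_time, truth$onset_time),
      rel_err(fit$params$production_rate, truth$production_rate),
      rel_err(fit$params$degradation_rate, truth$degradation_rate))
  }, numeric(3)))
  med <- apply(errs, 2, median)
  expect_true(all(med < 0.10))
})

test_that("tidy, glance and augment expose the fit", {
  fit <- fit_kinetics(noiseless_tc(kinetic_params(3, 0.3, 0.4)),
                      n_starts = 10, seed = 2)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_equal(nrow(td), 3)
  gl <- glance(fit)
  expect_equal(gl$steady_state, fit$params$production_rate /
                 fit$params$degradation_rate)
  aug <- augment(fit)
  expect_true(all(abs(aug$.resid) <= fit$rmsd * sqrt(nrow(aug)) + 1e-9))
})

test_that("per-replicate fitting mode returns one fit per replicate", {
  truth <- kinetic_params(3, 0.5, 0.5)
  fits <- fit_kinetics(noiseless_tc(truth, n_rep = 2), replicate_mode = "each",
                       n_starts = 8, seed = 4)
  expect_length(fits, 2)
  for (f in fits) expect_lt(rel_err(f$params$degradation_rate, 0.5), 0.05)
})
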