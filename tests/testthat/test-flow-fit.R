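make_observed <- function(truth, n_cells = 4000, seed = 21, n_rep = 3) {
  spec <- scenario_spec("s", kinetic_params(3, 0.3, 0.33), truth,
                        n_cells = n_cells, n_replicates = n_rep, seed = seed)
  make_flow_dataset(spec)
}

test_that("objective is near zero for self-fit and discriminates parameters", {
  truth <- flow_params(4, 1.05, 4, 0.55, 0.1, 0.0025)
  cfg <- flow_fit_config(n_restarts = 2, top_k = 2, n_sim_cells = 10000,
                         seed = 11)
  obs <- make_observed(truth, n_cells = 10000, seed = 11)
  self_obj <- flow_objective(truth, obs, cfg)
  expect_lt(self_obj, 0.01)
  # doubling the rate shape moves the simulated distributions away
  wrong <- flow_params(4, 1.05, 8, 0.55, 0.1, 0.0025)
  expect_gt(flow_objective(wrong, obs, cfg), self_obj)
  # replicate ordering does not matter: the target averages replicates
  shuffled <- obs[order(-obs$replicate, obs$time, obs$cell), ]
  expect_equal(flow_objective(truth, shuffled, cfg), self_obj)
  # a missing snapshot time is an error
  expect_error(flow_objective(truth, obs[obs$time != 4, ], cfg),
               "lack snapshot time")
})

test_that("fit is deterministic, respects bounds, and logs every restart", {
  truth <- flow_params(3, 1, 3, 0.6, 0, 0.01)
  obs <- make_observed(truth, n_cells = 1500, seed = 33, n_rep = 2)
  cfg <- tiny_flow_config(seed = 5, n_restarts = 3, top_k = 2)
  fit1 <- fit_flow_model(obs, cfg)
  fit2 <- fit_flow_model(obs, cfg)
  expect_identical(tidy(fit1)$estimate, tidy(fit2)$estimate)
  expect_identical(fit1$objective, fit2$objective)
  expect_equal(nrow(fit1$restart_log), 3)
  expect_lte(fit1$objective, min(fit1$restart_log$objective))
  expect_true(fit1$params$shape_time > 0 && fit1$params$scale_time > 0)
  expect_equal(fit1$mean_activation_time,
               fit1$params$shape_time * fit1$params$scale_time)
  # degenerate observed data are rejected
  degen <- obs
  degen$intensity <- 1
  expect_error(fit_flow_model(degen, cfg), "Degenerate")
})

test_that("best objective never worsens as restarts are added", {
  truth <- flow_params(3, 1, 3, 0.6, 0, 0.01)
  obs <- make_observed(truth, n_cells = 1500, seed = 12, n_rep = 2)
  objs <- vapply(c(1, 2, 4), function(nr) {
    fit_flow_model(obs, tiny_flow_config(seed = 8, n_restarts = nr,
                                         top_k = 1))$objective
  }, numeric(1))
  expect_true(all(diff(objs) <= 1e-12))
})

test_that("uncertainty ranges come from the top-k restarts and bracket the best", {
  log3 <- tibble::tibble(
    restart = 1:3, objective = c(0.5, 0.1, 0.3),
    shape_time = c(9, 1, 2), scale_time = c(9, 1, 2),
    shape_rate = c(9, 3, 1), scale_rate = c(9, 1, 2),
    noise_mean = c(9, 0, -1), noise_var = c(9, 1, 2)
  )
  rng <- summarize_uncertainty(log3, top_k = 2)
  # the chosen two are the restarts with objectives 0.1 and 0.3
  expect_equal(rng$low[rng$parameter == "shape_time"], 1)
  expect_equal(rng$high[rng$parameter == "shape_time"], 2)
  expect_equal(rng$low[rng$parameter == "shape_rate"], 1)
  expect_equal(rng$high[rng$parameter == "shape_rate"], 3)
  # top_k = 1 collapses to the best point
  rng1 <- summarize_uncertainty(log3, top_k = 1)
  expect_true(all(rng1$low == rng1$high))
  # identical restarts give zero-width ranges
  same <- log3
  same[3:8] <- lapply(same[3:8], function(x) rep(x[2], 3))
  rng0 <- summarize_uncertainty(same, top_k = 3)
  expect_true(all(rng0$high - rng0$low == 0))
  expect_error(summarize_uncertainty(log3, top_k = 5), "exceeds")
})

test_that("population summaries are the Gamma means", {
  expect_equal(mean_activation_time(flow_params(4, 1.05, 1, 1)), 4.2)
  expect_equal(mean_expression_rate(flow_params(1, 1, 1, 0.77)), 0.77)
  p <- flow_params(2, 3, 2, 3)
  expect_equal(mean_activation_time(flow_params(2, 6, 2, 3)),
               2 * mean_activation_time(p))
})

test_that("parameter recovery across synthetic datasets stays within 10%", {
  # five independently seeded datasets at the fast validation profile
  # (10,000 cells, 20 restarts); the median relative error of both
  # population summaries must be below 10%
  truth <- flow_params(4, 1.05, 4, 0.55, 0.1, 0.0025)
  errs <- vapply(1:5, function(i) {
    obs <- make_observed(truth, n_cells = 10000, seed = 400 + i)
    fit <- fit_flow_model(obs, flow_fit_config(profile = "reduced",
                                               seed = 700 + i))
    c(rel_err(fit$mean_activation_time, 4.2),
      rel_err(fit$mean_expression_rate, 2.2))
  }, numeric(2))
  expect_lt(median(errs[1, ]), 0.10)
  expect_lt(median(errs[2, ]), 0.10)
})
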