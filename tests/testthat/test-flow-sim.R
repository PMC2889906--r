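test_that("simulated populations obey the per-cell accumulation rule", {
  p <- flow_params(4, 1, 2, 1)
  snaps <- sample_population(p, n_cells = 500, times = c(0, 2, 4, 6), seed = 3)
  expect_setequal(unique(snaps$time), c(0, 2, 4, 6))
  expect_equal(nrow(snaps), 500 * 4)
  # with zero noise, no cell is active at t = 0 and nothing is negative
  expect_true(all(snaps$intensity[snaps$time == 0] == 0))
  expect_true(all(snaps$intensity >= 0))
  # each cell's trajectory is non-decreasing when noise is fixed per cell
  wide <- tidyr::pivot_wider(snaps, id_cols = "cell", names_from = "time",
                             values_from = "intensity")
  incr <- apply(as.matrix(wide[, -1]), 1, function(r) all(diff(r) >= 0))
  expect_true(all(incr))
  # determinism
  snaps2 <- sample_population(p, n_cells = 500, times = c(0, 2, 4, 6), seed = 3)
  expect_identical(snaps, snaps2)
  expect_error(flow_params(-1, 1, 1, 1), "positive")
})

test_that("population mean matches the Gamma-CDF expectation within 3 SE", {
  p <- flow_params(4, 1, 2, 1)
  n <- 100000
  snaps <- sample_population(p, n_cells = n, times = c(2, 6), seed = 17)
  for (tp in c(2, 6)) {
    x <- snaps$intensity[snaps$time == tp]
    se <- sd(x) / sqrt(n)
    expect_lt(abs(mean(x) - expected_mean_intensity(p, tp)), 3 * se)
  }
  # Gamma sample means converge to shape * scale
  tr <- galkinetics:::cell_triples(p, galkinetics:::draw_cell_variates(n, 5))
  expect_lt(abs(mean(tr$t_act) - 4) / 4, 3 * sd(tr$t_act) / sqrt(n) / 4)
  expect_lt(abs(mean(tr$rate) - 2) / 2, 3 * sd(tr$rate) / sqrt(n) / 2)
})

test_that("expected mean intensity has the right limits", {
  p <- flow_params(4, 1, 2, 1, noise_mean = 0.5)
  expect_equal(expected_mean_intensity(p, 0), 0.5)
  # late-time asymptote: noise_mean + mean_rate * (t - mean_activation)
  t_big <- 60
  expect_equal(expected_mean_intensity(p, t_big),
               0.5 + 2 * (t_big - 4), tolerance = 1e-8)
  expect_error(expected_mean_intensity(p, -1), "non-negative")
})

test_that("gate threshold is the documented order statistic and lands in band", {
  # all-distinct ranked reference of 1000 cells: rank 986 exactly
  ref <- sample(seq_len(1000))
  expect_equal(set_gate_threshold(ref), 986)
  expect_true(positive_fraction(ref, 986) >= 0.01 &&
                positive_fraction(ref, 986) <= 0.02)

  # large standard-normal reference: threshold near the 98.5% quantile
  set.seed(42)
  ref <- rnorm(1e5)
  thr <- set_gate_threshold(ref)
  expect_lt(abs(thr - qnorm(0.985)), 0.05)
  frac <- positive_fraction(ref, thr)
  expect_gte(frac, 0.01)
  expect_lte(frac, 0.02)

  expect_error(set_gate_threshold(rep(1, 2000)), "Constant")
  expect_error(set_gate_threshold(rnorm(10)), "1000")
})

test_that("positive fraction counts cells strictly above threshold", {
  expect_equal(positive_fraction(c(1, 2, 3), 5), 0)
  expect_equal(positive_fraction(c(6, 7, 8), 5), 1)
  expect_error(positive_fraction(numeric(0), 1), "Empty")
  # known 30:70 mixture separated far from the threshold
  set.seed(7)
  x <- c(rnorm(3000, 10, 1), rnorm(7000, 0, 1))
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(positive_fraction(x, 5) - 0.30), 3 * se)
})

test_that("geometric mean of gated cells behaves multiplicatively", {
  expect_equal(geometric_mean_positive(c(0.5, 42), 1), 42)
  expect_equal(geometric_mean_positive(c(10, 1000), 1), 100)
  set.seed(8)
  x <- rlnorm(500, 1, 0.5)
  g1 <- geometric_mean_positive(x, 0.5)
  expect_equal(geometric_mean_positive(3 * x, 3 * 0.5), 3 * g1)
  # non-positive intensities are excluded, not propagated
  expect_equal(geometric_mean_positive(c(-2, 5), -3), 5)
  expect_error(geometric_mean_positive(c(0.1, 0.2), 1), "No cells")
})

test_that("histogram counts partition in-range cells", {
  x <- c(0.1, 0.2, 0.3)
  h <- histogram_counts(x, breaks = c(0, 1))
  expect_equal(h$count, 3)
  set.seed(10)
  u <- runif(1e5)
  h <- histogram_counts(u, breaks = seq(0, 1, 0.1), normalize = TRUE)
  expect_equal(sum(h$frequency), 1)
  expect_equal(sum(h$count), 1e5)
  se <- sqrt(0.1 * 0.9 / 1e5)
  expect_true(all(abs(h$frequency - 0.1) < 3 * se))
  expect_error(histogram_counts(u, breaks = 1), "2 strictly increasing")
})

test_that("gate_summary aggregates per sample and time", {
  p <- flow_params(2, 1, 2, 1, noise_mean = 0, noise_var = 0.01)
  snaps <- sample_population(p, n_cells = 2000, times = c(0, 4), seed = 9)
  gs <- gate_summary(snaps, threshold = 0.5)
  expect_equal(nrow(gs), 2)
  expect_true(gs$positive_fraction[gs$time == 4] >
                gs$positive_fraction[gs$time == 0])
})
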