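#' Configuration for fitting the single-cell model
#'
#' Controls the multi-start stochastic fit of the six-parameter single-cell
#' model: the number of random restarts, how many top fits feed the
#' uncertainty ranges, the simulated population size, the snapshot times, the
#' genetic-algorithm budget, and the objective flavour.
#'
#' The `"full"` profile uses the full measurement-design conditions (100,000 simulated
#' cells, 200 restarts, top 50); the `"reduced"` profile (10,000 cells, 20
#' restarts, top 5, smaller GA budget) is the documented fast profile used in
#' the package's own validation runs.
#'
#' @param n_restarts Number of independent optimisation restarts.
#' @param top_k Number of lowest-objective restarts used for the
#'   per-parameter uncertainty ranges; must be <= `n_restarts`.
#' @param n_sim_cells Simulated cells per objective evaluation (>= 1000).
#' @param snapshot_times Measured time points, hours.
#' @param ga_population,ga_generations Genetic-algorithm budget per restart.
#' @param simplex_maxit Iteration cap of the Nelder-Mead polish.
#' @param seed Master seed; every restart and evaluation derives its own
#'   stream from it.
#' @param objective_mode `"histogram"` (RMSD between fixed-bin normalised
#'   histograms of asinh intensity) or `"quantile"` (RMSD between deciles of
#'   asinh intensity).
#' @param n_bins Number of histogram bins for the histogram objective.
#' @param profile Optional shortcut: `"full"` or `"reduced"` presets,
#'   applied before the explicit arguments.
#' @return A `flow_fit_config` list.
#' @export
flow_fit_config <- function(n_restarts = 200, top_k = 50,
                            n_sim_cells = 100000,
                            snapshot_times = c(0, 2, 4, 6),
                            ga_population = 60, ga_generations = 40,
                            simplex_maxit = 400, seed = 1,
                            objective_mode = c("histogram", "quantile"),
                            n_bins = 64, profile = NULL) {
  objective_mode <- match.arg(objective_mode)
  cfg <- list(
    n_restarts = n_restarts, top_k = top_k, n_sim_cells = n_sim_cells,
    snapshot_times = snapshot_times, ga_population = ga_population,
    ga_generations = ga_generations, simplex_maxit = simplex_maxit,
    seed = seed, objective_mode = objective_mode, n_bins = n_bins
  )
  if (!is.null(profile)) {
    preset <- switch(
      match.arg(profile, c("full", "reduced")),
      full = list(),
      reduced = list(n_restarts = 20, top_k = 5, n_sim_cells = 10000,
                     ga_population = 16, ga_generations = 8,
                     simplex_maxit = 200)
    )
    supplied <- names(match.call())[-1]
    preset <- preset[setdiff(names(preset), supplied)]
    cfg <- modifyList(cfg, preset)
  }
  if (cfg$top_k > cfg$n_restarts) abort("`top_k` must be <= `n_restarts`.")
  if (cfg$n_sim_cells < 1000) abort("`n_sim_cells` must be >= 1000.")
  structure(cfg, class = "flow_fit_config")
}

flow_param_names <- c("shape_time", "scale_time", "shape_rate", "scale_rate",
                      "noise_mean", "noise_var")

# Search bounds in natural units; shapes and scales are optimised on the log
# scale so the GA explores orders of magnitude evenly.
flow_bounds <- function() {
  list(
    lower = c(shape_time = 0.1, scale_time = 1e-3, shape_rate = 0.1,
              scale_rate = 1e-3, noise_mean = -5, noise_var = 0),
    upper = c(shape_time = 100, scale_time = 100, shape_rate = 100,
              scale_rate = 100, noise_mean = 5, noise_var = 25)
  )
}

to_search_space <- function(p) {
  c(log(p[1:4]), p[5], p[6])
}

from_search_space <- function(theta) {
  setNames(c(exp(theta[1:4]), theta[5], theta[6]), flow_param_names)
}

search_bounds <- function() {
  b <- flow_bounds()
  list(lower = to_search_space(b$lower), upper = to_search_space(b$upper))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

params_from_vector <- function(p) {
  flow_params(p[["shape_time"]], p[["scale_time"]], p[["shape_rate"]],
              p[["scale_rate"]], p[["noise_mean"]], p[["noise_var"]])
}

# ---- observed-data preparation ---------------------------------------------

check_snapshot_frame <- function(observed) {
  required <- c("time", "intensity")
  missing_cols <- setdiff(required, names(observed))
  if (length(missing_cols) > 0) {
    abort(paste0("Observed snapshots need column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  observed
}

# Turn the observed snapshots into the fitting target: per time point, the
# replicate-averaged summary (normalised histogram frequencies on common
# asinh-scale edges, or deciles of asinh intensity).
prepare_flow_target <- function(observed, config) {
  observed <- check_snapshot_frame(observed)
  times <- config$snapshot_times
  have <- unique(observed$time)
  missing_t <- setdiff(times, have)
  if (length(missing_t) > 0) {
    abort(paste0("Observed data lack snapshot time(s): ",
                 paste(missing_t, collapse = ", "), "."))
  }
  observed <- observed[observed$time %in% times, , drop = FALSE]
  if (max(observed$intensity) == min(observed$intensity)) {
    abort("Degenerate observed data: all intensities identical.")
  }
  if (!"replicate" %in% names(observed)) observed$replicate <- 1L
  tx <- asinh(observed$intensity)
  pad <- 1e-6 + 0.01 * diff(range(tx))
  edges <- seq(min(tx) - pad, max(tx) + pad, length.out = config$n_bins + 1)
  width <- edges[2] - edges[1]
  probs <- seq(0.1, 0.9, by = 0.1)
  target <- vapply(times, function(tp) {
    sub <- observed[observed$time == tp, , drop = FALSE]
    reps <- split(asinh(sub$intensity), sub$replicate)
    cols <- vapply(reps, function(v) {
      if (config$objective_mode == "histogram") {
        counts <- bin_counts_uniform(v, edges[1], width, config$n_bins)
        counts / max(sum(counts), 1)
      } else {
        quantile(v, probs = probs, names = FALSE, type = 7)
      }
    }, numeric(if (config$objective_mode == "histogram")
      config$n_bins else length(probs)))
    rowMeans(cols)
  }, numeric(if (config$objective_mode == "histogram")
    config$n_bins else length(probs)))
  list(times = times, edges = edges, width = width, n_bins = config$n_bins,
       probs = probs, target = target, mode = config$objective_mode)
}

# Objective on prepared target with fixed per-restart cell variates: smooth
# deterministic function of the parameters (common random numbers).
flow_objective_prepared <- function(pvec, target, variates) {
  params <- params_from_vector(pvec)
  triples <- cell_triples(params, variates, fast = TRUE)
  total <- 0
  for (j in seq_along(target$times)) {
    sim <- asinh(intensity_at(triples, target$times[j]))
    summary_j <- if (target$mode == "histogram") {
      counts <- bin_counts_uniform(sim, target$edges[1], target$width,
                                   target$n_bins)
      counts / max(sum(counts), 1)
    } else {
      quantile(sim, probs = target$probs, names = FALSE, type = 7)
    }
    total <- total + rmsd(summary_j, target$target[, j])
  }
  total
}

#' Distribution-distance objective of the single-cell model
#'
#' Measures how far a simulated population lies from observed snapshot
#' distributions: for each measured time point the observed intensities
#' (averaged over replicates) and a freshly simulated population are
#' summarised on a common asinh intensity scale — as normalised fixed-bin
#' histograms by default, or as deciles — and the RMSD between the two
#' summaries is summed over the time points.
#'
#' @param params A [flow_params()] object.
#' @param observed Tidy snapshot tibble with columns `time`, `intensity` and
#'   optionally `replicate` (and `sample`), covering every configured
#'   snapshot time.
#' @param config A [flow_fit_config()]; supplies the snapshot times, the
#'   simulated population size, the seed and the objective mode.
#' @return A non-negative objective value.
#' @export
flow_objective <- function(params, observed, config = flow_fit_config()) {
  stopifnot(inherits(params, "flow_params"))
  target <- prepare_flow_target(observed, config)
  variates <- draw_cell_variates(config$n_sim_cells,
                                 derive_seed(config$seed, 0))
  pvec <- setNames(unlist(params[flow_param_names]), flow_param_names)
  flow_objective_prepared(pvec, target, variates)
}

# ---- genetic algorithm + simplex, one restart -------------------------------

# Method-of-moments starting point derived from the observed snapshots: the
# earliest snapshot estimates the background Normal, the late-time slope of
# the population mean estimates the mean accumulation rate, and the linear
# extrapolation of the late-time mean back to background level estimates the
# mean activation time. Gamma shapes start at 4 (moderate cell-to-cell
# variability). Each restart jitters this guess, so it seeds - not fixes -
# the search.
moment_guess <- function(observed, config) {
  b <- flow_bounds()
  times <- sort(config$snapshot_times)
  m <- vapply(times, function(tp) {
    mean(observed$intensity[observed$time == tp])
  }, numeric(1))
  base <- observed$intensity[observed$time == times[1]]
  mu0 <- clamp(mean(base), b$lower["noise_mean"], b$upper["noise_mean"])
  v0 <- clamp(stats::var(base), b$lower["noise_var"], b$upper["noise_var"])
  nt <- length(times)
  slope <- (m[nt] - m[nt - 1]) / (times[nt] - times[nt - 1])
  slope <- max(slope, 1e-2)
  act <- times[nt] - (m[nt] - mu0) / slope
  act <- clamp(act, 0.1, times[nt])
  p <- c(shape_time = 4, scale_time = unname(act / 4),
         shape_rate = 4, scale_rate = unname(slope / 4),
         noise_mean = unname(mu0), noise_var = unname(max(v0, 1e-6)))
  to_search_space(clamp(p, b$lower, b$upper))
}

# Compact real-coded GA: tournament selection, blend crossover, Gaussian
# mutation, elitism of 2. Runs in the transformed (log-scale) search space.
run_ga <- function(fn, lower, upper, pop_size, generations, init = NULL) {
  d <- length(lower)
  span <- upper - lower
  pop <- t(replicate(pop_size, runif(d, lower, upper)))
  if (!is.null(init)) {
    init <- matrix(clamp(init, rep(lower, each = nrow(init)),
                         rep(upper, each = nrow(init))), nrow = nrow(init))
    pop[seq_len(min(nrow(init), pop_size)), ] <-
      init[seq_len(min(nrow(init), pop_size)), , drop = FALSE]
  }
  fitness <- apply(pop, 1, fn)
  for (g in seq_len(generations)) {
    elite_idx <- order(fitness)[1:2]
    newpop <- matrix(NA_real_, pop_size, d)
    newpop[1:2, ] <- pop[elite_idx, , drop = FALSE]
    for (i in 3:pop_size) {
      pick <- function() {
        cand <- sample.int(pop_size, 3)
        cand[which.min(fitness[cand])]
      }
      pa <- pop[pick(), ]
      pb <- pop[pick(), ]
      w <- runif(d, -0.25, 1.25)
      child <- w * pa + (1 - w) * pb
      mutate <- runif(d) < 0.2
      child[mutate] <- child[mutate] + rnorm(sum(mutate), 0, 0.1 * span[mutate])
      newpop[i, ] <- clamp(child, lower, upper)
    }
    pop <- newpop
    fitness <- apply(pop, 1, fn)
  }
  best <- which.min(fitness)
  list(par = pop[best, ], value = fitness[best])
}

run_one_restart <- function(target, config, restart_index, guess = NULL) {
  sb <- search_bounds()
  variates <- draw_cell_variates(config$n_sim_cells,
                                 derive_seed(config$seed, 100 + restart_index))
  obj <- function(theta) {
    theta_c <- clamp(theta, sb$lower, sb$upper)
    penalty <- sum((theta - theta_c)^2)
    flow_objective_prepared(from_search_space(theta_c), target, variates) +
      penalty
  }
  local_seed(derive_seed(config$seed, 200 + restart_index), {
    init <- if (is.null(guess)) NULL else {
      rbind(guess, guess + rnorm(length(guess), 0, 0.25))
    }
    ga <- run_ga(obj, sb$lower, sb$upper,
                 pop_size = config$ga_population,
                 generations = config$ga_generations, init = init)
    nm <- optim(ga$par, obj, method = "Nelder-Mead",
                control = list(maxit = config$simplex_maxit, reltol = 1e-8))
    nm <- optim(nm$par, obj, method = "Nelder-Mead",
                control = list(maxit = config$simplex_maxit, reltol = 1e-8))
    start_par <- from_search_space(ga$par)
    final_theta <- clamp(nm$par, sb$lower, sb$upper)
    list(start = start_par, par = from_search_space(final_theta),
         value = nm$value)
  })
}

#' Fit the single-cell model to observed snapshots
#'
#' Multi-start stochastic optimisation of the six model parameters: each
#' restart runs a genetic algorithm followed by a Nelder-Mead simplex polish,
#' using its own frozen set of per-cell random variates (common random
#' numbers) so the objective is deterministic within the restart. The final
#' parameters of every restart are then re-scored on one shared evaluation
#' draw, and the restart with the smallest re-scored objective wins; ranges
#' of each parameter across the `top_k` best restarts quantify fit
#' uncertainty. The whole procedure is deterministic given `config$seed`, and
#' enlarging `n_restarts` can only improve (never worsen) the best objective.
#'
#' @param observed Tidy snapshot tibble (`time`, `intensity`, optionally
#'   `replicate`, `sample`) covering every configured snapshot time; must not
#'   be degenerate (all intensities identical).
#' @param config A [flow_fit_config()].
#' @return A `flow_fit` object with elements `params`, `objective`,
#'   `mean_activation_time`, `mean_expression_rate`, `param_ranges`,
#'   `restart_log` (one row per restart: start and final parameters and the
#'   re-scored objective) and `config`.
#' @export
fit_flow_model <- function(observed, config = flow_fit_config()) {
  stopifnot(inherits(config, "flow_fit_config"))
  target <- prepare_flow_target(observed, config)
  guess <- moment_guess(check_snapshot_frame(observed), config)

  restarts <- lapply(seq_len(config$n_restarts), function(r) {
    run_one_restart(target, config, r, guess = guess)
  })

  # re-score every restart's final parameters on one shared draw so that
  # objectives are comparable across restarts
  eval_variates <- draw_cell_variates(config$n_sim_cells,
                                      derive_seed(config$seed, 999))
  scored <- vapply(restarts, function(r) {
    flow_objective_prepared(r$par, target, eval_variates)
  }, numeric(1))

  restart_log <- dplyr::bind_cols(
    tibble::tibble(restart = seq_len(config$n_restarts), objective = scored),
    tibble::as_tibble(do.call(rbind, lapply(restarts, `[[`, "par"))),
    tibble::as_tibble(do.call(rbind, lapply(restarts, `[[`, "start")))
      |> setNames(paste0("start_", flow_param_names))
  )

  best_idx <- which.min(scored)
  best_par <- restarts[[best_idx]]$par
  params <- params_from_vector(best_par)

  structure(
    list(
      params = params,
      objective = scored[best_idx],
      mean_activation_time = mean_activation_time(params),
      mean_expression_rate = mean_expression_rate(params),
      param_ranges = summarize_uncertainty(restart_log, config$top_k),
      restart_log = restart_log,
      config = config,
      target = target
    ),
    class = "flow_fit"
  )
}

#' Per-parameter uncertainty ranges from the best restarts
#'
#' Takes the `top_k` lowest-objective restarts of a fit's restart log and
#' reports the min-max range each parameter spanned among them — the
#' uncertainty summary used alongside the best-fit point.
#'
#' @param restart_log A tibble with an `objective` column and one column per
#'   model parameter (as in `fit_flow_model()$restart_log`).
#' @param top_k Number of best restarts to summarise; must not exceed the
#'   number of rows.
#' @return A tibble with columns `parameter`, `low`, `high`.
#' @export
summarize_uncertainty <- function(restart_log, top_k) {
  if (nrow(restart_log) == 0) abort("Empty restart log.")
  if (top_k > nrow(restart_log)) {
    abort("`top_k` exceeds the number of restarts.")
  }
  top <- restart_log[order(restart_log$objective)[seq_len(top_k)], ,
                     drop = FALSE]
  tibble::tibble(
    parameter = flow_param_names,
    low = vapply(flow_param_names, function(p) min(top[[p]]), numeric(1),
                 USE.NAMES = FALSE),
    high = vapply(flow_param_names, function(p) max(top[[p]]), numeric(1),
                  USE.NAMES = FALSE)
  )
}

#' @export
print.flow_fit <- function(x, ...) {
  cat("Single-cell accumulation-model fit\n")
  cat(sprintf("  mean activation time  %.3g h\n", x$mean_activation_time))
  cat(sprintf("  mean expression rate  %.3g counts/h\n",
              x$mean_expression_rate))
  cat(sprintf("  objective %.5g over %d restarts (top %d for ranges)\n",
              x$objective, x$config$n_restarts, x$config$top_k))
  invisible(x)
}

#' @method tidy flow_fit
#' @export
tidy.flow_fit <- function(x, ...) {
  est <- unlist(x$params[flow_param_names])
  dplyr::left_join(
    tibble::tibble(term = flow_param_names, estimate = unname(est)),
    dplyr::rename(x$param_ranges, term = "parameter"),
    by = "term"
  )
}

#' @method glance flow_fit
#' @export
glance.flow_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective,
    mean_activation_time = x$mean_activation_time,
    mean_expression_rate = x$mean_expression_rate,
    n_restarts = x$config$n_restarts,
    top_k = x$config$top_k,
    n_sim_cells = x$config$n_sim_cells,
    seed = x$config$seed
  )
}
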