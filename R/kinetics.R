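#' Parameters of the induction-kinetics model
#'
#' The bulk mRNA model has three non-negative parameters: the onset time at
#' which transcription begins, the constant production rate thereafter, and a
#' first-order degradation rate. Before the onset time the mRNA level is zero;
#' afterwards it follows dM/dt = production_rate - degradation_rate * M, so
#' the level relaxes exponentially towards the steady state
#' production_rate / degradation_rate.
#'
#' @param onset_time Time at which production begins (same unit as the data
#'   grid it will be fitted to); must be >= 0.
#' @param production_rate Constant production rate (expression units per
#'   time); must be >= 0.
#' @param degradation_rate First-order degradation rate (per time); must be
#'   >= 0, and strictly positive for steady-state and half-time queries.
#' @return A `kinetic_params` object.
#' @examples
#' p <- kinetic_params(onset_time = 3, production_rate = 1.2,
#'                     degradation_rate = 1.4)
#' steady_state_level(p)
#' @export
kinetic_params <- function(onset_time, production_rate, degradation_rate) {
  vals <- c(onset_time = onset_time, production_rate = production_rate,
            degradation_rate = degradation_rate)
  if (!is.numeric(vals) || length(vals) != 3 || anyNA(vals)) {
    abort("Kinetic parameters must be three finite numbers.")
  }
  if (any(vals < 0)) {
    abort("Kinetic parameters must be non-negative.")
  }
  structure(
    list(onset_time = unname(onset_time),
         production_rate = unname(production_rate),
         degradation_rate = unname(degradation_rate)),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "<kinetic_params: onset = %.4g, production = %.4g, degradation = %.4g>\n",
    x$onset_time, x$production_rate, x$degradation_rate
  ))
  invisible(x)
}

#' Closed-form mRNA level of the induction model
#'
#' Evaluates the exact solution of the induction ODE: zero before the onset
#' time, then (production/degradation) * (1 - exp(-degradation * (t - onset))).
#' When the degradation rate is exactly zero the limit is pure linear
#' accumulation, production_rate * (t - onset).
#'
#' @param params A [kinetic_params()] object.
#' @param t Numeric vector of times (>= 0).
#' @return Numeric vector of mRNA levels, non-decreasing in `t` and bounded
#'   above by the steady state.
#' @export
predict_mrna <- function(params, t) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(t < 0)) abort("Times must be non-negative.")
  dt <- pmax(t - params$onset_time, 0)
  if (params$degradation_rate == 0) {
    params$production_rate * dt
  } else {
    (params$production_rate / params$degradation_rate) *
      (1 - exp(-params$degradation_rate * dt))
  }
}

#' Numerical (Runge-Kutta) solution of the induction ODE
#'
#' Integrates the induction ODE with an adaptive Runge-Kutta scheme
#' (Dormand-Prince via [deSolve::ode()]) and returns the trajectory on the
#' requested grid. Used as a cross-check of [predict_mrna()]; the two agree to
#' within the integrator tolerance (default well below 1e-8). The
#' discontinuity at the onset time is handled by integrating only from the
#' onset, with zeros before it.
#'
#' @param params A [kinetic_params()] object.
#' @param times Strictly increasing time grid starting at 0.
#' @param rtol,atol Integrator tolerances.
#' @return Numeric vector of mRNA levels aligned to `times`.
#' @export
predict_mrna_numeric <- function(params, times, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "kinetic_params"))
  if (length(times) < 2 || any(diff(times) <= 0)) {
    abort("`times` must be a strictly increasing grid.")
  }
  if (times[1] < 0) abort("`times` must start at a non-negative time.")
  out <- numeric(length(times))
  active <- times >= params$onset_time
  if (!any(active)) return(out)
  grid <- c(params$onset_time, times[active])
  # de-duplicate in case the onset falls exactly on a grid point
  keep <- !duplicated(grid)
  grid <- grid[keep]
  deriv <- function(t, y, parms) {
    list(parms$alpha - parms$delta * y)
  }
  sol <- deSolve::ode(
    y = c(M = 0), times = grid, func = deriv,
    parms = list(alpha = params$production_rate,
                 delta = params$degradation_rate),
    method = "ode45", rtol = rtol, atol = atol
  )
  fitted <- sol[, "M"]
  # drop the leading onset node unless it coincided with the first grid point
  out[active] <- if (length(fitted) == sum(active)) fitted else fitted[-1]
  out
}

#' Steady-state expression level
#'
#' The equilibrium mRNA level production_rate / degradation_rate where
#' synthesis balances decay.
#'
#' @param params A [kinetic_params()] object with degradation_rate > 0.
#' @return The steady-state level.
#' @export
steady_state_level <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$degradation_rate <= 0) {
    abort("Steady state is undefined when the degradation rate is zero.")
  }
  params$production_rate / params$degradation_rate
}

#' Time to reach half the steady-state level
#'
#' Analytically, the trajectory reaches half its steady state at
#' onset_time + log(2) / degradation_rate. With `method = "numeric"` the same
#' quantity is obtained by root-finding on [predict_mrna()], which serves as
#' an independent numerical cross-check (agreement within 1e-6).
#'
#' @param params A [kinetic_params()] with positive production and
#'   degradation rates.
#' @param method `"analytic"` (default) or `"numeric"`.
#' @param tol Root-finder tolerance for the numeric method.
#' @return The half-steady-state time, in the parameters' time unit.
#' @export
half_steady_state_time <- function(params, method = c("analytic", "numeric"),
                                   tol = 1e-9) {
  stopifnot(inherits(params, "kinetic_params"))
  method <- match.arg(method)
  if (params$degradation_rate <= 0) {
    abort("Half-steady-state time requires a positive degradation rate.")
  }
  if (params$production_rate <= 0) {
    abort("Half-steady-state time requires a positive production rate.")
  }
  analytic <- params$onset_time + log(2) / params$degradation_rate
  if (method == "analytic") return(analytic)
  half <- steady_state_level(params) / 2
  upper <- params$onset_time + 40 / params$degradation_rate
  uniroot(
    function(t) predict_mrna(params, t) - half,
    lower = params$onset_time, upper = upper, tol = tol
  )$root
}

#' Root-mean-square deviation between two series
#'
#' @param model,data Numeric vectors of equal length.
#' @return sqrt(mean((model - data)^2)).
#' @export
rmsd <- function(model, data) {
  if (length(model) != length(data)) {
    abort("`model` and `data` must have the same length.")
  }
  sqrt(mean((model - data)^2))
}

# Objective for the kinetic fit: RMSD between the closed-form trajectory and
# the target series on the grid. `fixed_onset` pins the onset at zero for the
# reinduction (memory) variant of the model.
kinetic_objective <- function(theta, times, target, fixed_onset = FALSE) {
  if (fixed_onset) theta <- c(0, theta)
  p <- kinetic_params(theta[1], theta[2], theta[3])
  rmsd(predict_mrna(p, times), target)
}

#' Fit the induction-kinetics model to a time course
#'
#' Minimises the RMSD between the closed-form induction trajectory and the
#' replicate-averaged measurements, with all three parameters constrained to
#' be non-negative. Optimisation is multi-start: a heuristic start (onset at
#' the first time the signal exceeds 5% of its maximum) plus `n_starts - 1`
#' random starts drawn uniformly within the bounds, each refined by bounded
#' quasi-Newton (L-BFGS-B). Starts are drawn sequentially from a stream
#' seeded by `seed`, so enlarging `n_starts` extends the start set without
#' changing earlier starts, and the best objective can only improve.
#'
#' Ties between restarts (objectives within 1e-10) are broken by the smallest
#' onset time, then lexicographically on (production, degradation).
#'
#' @param tc A [as_timecourse()] object with at least 4 time points.
#' @param fix_onset_zero If `TRUE`, the onset time is pinned at zero and only
#'   production and degradation are fitted (the reinduction variant, where
#'   fitted onsets are indistinguishable from zero).
#' @param n_starts Number of optimisation starts (default 50).
#' @param seed Integer seed controlling the random starts.
#' @param replicate_mode `"mean"` (default) fits the replicate average;
#'   `"each"` fits every replicate separately and returns a list of fits.
#' @param bounds Optional list with elements `onset`, `production`,
#'   `degradation`, each `c(lo, hi)`. Defaults: onset in [0, max(time)],
#'   production in [0, 10 * max(value) * 5], degradation in [1e-4, 5].
#' @return A `kinetic_fit` object (or a list of them for
#'   `replicate_mode = "each"`), with elements `params`, `rmsd`,
#'   `onset_fixed_zero`, `n_starts`, `seed`, `converged`, plus the data used.
#' @examples
#' truth <- kinetic_params(3, 0.3, 0.33)
#' tc <- as_timecourse(
#'   data.frame(time = seq(0, 14, 2), replicate = 1,
#'              value = predict_mrna(truth, seq(0, 14, 2))),
#'   time_unit = "hours"
#' )
#' fit <- fit_kinetics(tc, n_starts = 10, seed = 1)
#' tidy(fit)
#' @export
fit_kinetics <- function(tc, fix_onset_zero = FALSE, n_starts = 50, seed = 1,
                         replicate_mode = c("mean", "each"), bounds = NULL) {
  stopifnot(inherits(tc, "timecourse"))
  replicate_mode <- match.arg(replicate_mode)
  if (replicate_mode == "each") {
    reps <- unique(tc$replicate)
    fits <- lapply(seq_along(reps), function(i) {
      sub <- tibble::as_tibble(tc)[tc$replicate == reps[i], ]
      fit_kinetics(
        as_timecourse(sub, time_unit = tc_time_unit(tc), label = attr(tc, "label")),
        fix_onset_zero = fix_onset_zero, n_starts = n_starts,
        seed = derive_seed(seed, i), replicate_mode = "mean", bounds = bounds
      )
    })
    names(fits) <- as.character(reps)
    return(fits)
  }

  avg <- tc_summarise(tc)
  times <- avg$time
  target <- avg$mean
  if (length(times) < 4) abort("Need at least 4 time points to fit.")

  if (all(target == 0)) {
    warn("All-zero time course: returning a zero-production fit.")
    params <- kinetic_params(0, 0, 1e-4)
    return(new_kinetic_fit(params, 0, fix_onset_zero, n_starts, seed, TRUE, tc))
  }

  default_bounds <- list(
    onset = c(0, max(times)),
    production = c(0, 10 * max(target) * 5),
    degradation = c(1e-4, 5)
  )
  bounds <- modifyList(default_bounds, bounds %||% list())
  lo <- c(bounds$onset[1], bounds$production[1], bounds$degradation[1])
  hi <- c(bounds$onset[2], bounds$production[2], bounds$degradation[2])
  if (fix_onset_zero) {
    lo <- lo[-1]
    hi <- hi[-1]
  }

  # heuristic start: onset where the signal first clears 5% of its maximum
  first_on <- times[which(target > 0.05 * max(target))[1]]
  if (is.na(first_on)) first_on <- 0
  delta0 <- 0.5
  start0 <- c(first_on, max(target) * delta0, delta0)
  if (fix_onset_zero) start0 <- start0[-1]
  start0 <- pmin(pmax(start0, lo), hi)

  starts <- local_seed(seed, {
    lapply(seq_len(max(n_starts - 1, 0)), function(i) {
      runif(length(lo), lo, hi)
    })
  })
  starts <- c(list(start0), starts)

  results <- lapply(starts, function(s) {
    res <- tryCatch(
      optim(
        par = s, fn = kinetic_objective, times = times, target = target,
        fixed_onset = fix_onset_zero, method = "L-BFGS-B",
        lower = lo, upper = hi,
        control = list(factr = 1e-3, maxit = 500)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) return(NULL)
    list(par = res$par, value = res$value, convergence = res$convergence)
  })
  results <- results[!vapply(results, is.null, logical(1))]
  if (length(results) == 0) abort("All optimisation starts failed.")

  values <- vapply(results, `[[`, numeric(1), "value")
  best_val <- min(values)
  cand <- results[values <= best_val + 1e-10]
  pars <- do.call(rbind, lapply(cand, function(r) {
    if (fix_onset_zero) c(0, r$par) else r$par
  }))
  ord <- order(pars[, 1], pars[, 2], pars[, 3])
  chosen <- pars[ord[1], ]
  conv <- cand[[ord[1]]]$convergence == 0

  params <- kinetic_params(chosen[1], chosen[2], chosen[3])
  new_kinetic_fit(params, best_val, fix_onset_zero, n_starts, seed, conv, tc)
}

new_kinetic_fit <- function(params, rmsd, onset_fixed_zero, n_starts, seed,
                            converged, tc) {
  structure(
    list(
      params = params,
      rmsd = rmsd,
      onset_fixed_zero = onset_fixed_zero,
      n_starts = n_starts,
      seed = seed,
      converged = converged,
      data = tc
    ),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Induction-kinetics fit\n")
  cat(sprintf("  onset_time       %.6g\n", x$params$onset_time))
  cat(sprintf("  production_rate  %.6g\n", x$params$production_rate))
  cat(sprintf("  degradation_rate %.6g\n", x$params$degradation_rate))
  cat(sprintf("  RMSD %.6g over %d starts (seed %d)%s\n",
              x$rmsd, x$n_starts, x$seed,
              if (x$onset_fixed_zero) ", onset fixed at 0" else ""))
  invisible(x)
}

#' @method tidy kinetic_fit
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("onset_time", "production_rate", "degradation_rate"),
    estimate = c(x$params$onset_time, x$params$production_rate,
                 x$params$degradation_rate)
  )
}

#' @method glance kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    rmsd = x$rmsd,
    steady_state = if (x$params$degradation_rate > 0)
      steady_state_level(x$params) else NA_real_,
    half_time = if (x$params$degradation_rate > 0 &&
                    x$params$production_rate > 0)
      half_steady_state_time(x$params) else NA_real_,
    n_starts = x$n_starts,
    seed = x$seed,
    converged = x$converged,
    onset_fixed_zero = x$onset_fixed_zero
  )
}

#' @method augment kinetic_fit
#' @export
augment.kinetic_fit <- function(x, ...) {
  avg <- tc_summarise(x$data)
  avg$.fitted <- predict_mrna(x$params, avg$time)
  avg$.resid <- avg$mean - avg$.fitted
  avg
}
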