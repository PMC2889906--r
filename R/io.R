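#' Read and write time courses as CSV
#'
#' The on-disk format is a headered UTF-8 CSV with columns `time`,
#' `replicate`, `value`. Reading validates the schema (missing columns,
#' non-numeric values and duplicate (time, replicate) pairs raise descriptive
#' errors); writing is the exact inverse, so a round trip reproduces the
#' table.
#'
#' @param path File path.
#' @param time_unit Unit the file's `time` column is in.
#' @param label Optional sample label attached on read.
#' @return `read_timecourse()` returns a [as_timecourse()] object;
#'   `write_timecourse()` returns `path` invisibly.
#' @export
read_timecourse <- function(path, time_unit = c("hours", "minutes"),
                            label = NULL) {
  time_unit <- match.arg(time_unit)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(c("time", "replicate", "value"), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("File ", path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (!is.numeric(raw$time) || !is.numeric(raw$value)) {
    abort(paste0("File ", path, " has non-numeric time or value entries."))
  }
  as_timecourse(raw, time_unit = time_unit, label = label)
}

#' @rdname read_timecourse
#' @param tc A `timecourse` object.
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "timecourse"))
  readr::write_csv(tibble::as_tibble(tc)[, c("time", "replicate", "value")],
                   path, progress = FALSE)
  invisible(path)
}

#' Read and write flow snapshots as CSV
#'
#' Columns: `sample`, `replicate` (optional), `time`, `intensity`.
#'
#' @param path File path.
#' @param snapshots A tidy snapshot tibble.
#' @return `read_snapshots()` returns a tibble; `write_snapshots()` returns
#'   `path` invisibly.
#' @export
read_snapshots <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(c("sample", "time", "intensity"), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("File ", path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  raw
}

#' @rdname read_snapshots
#' @export
write_snapshots <- function(snapshots, path) {
  check_snapshot_frame(snapshots)
  readr::write_csv(snapshots, path, progress = FALSE)
  invisible(path)
}

# Format numeric fields to 12 significant digits with fixed key order so
# rerunning a seeded pipeline yields byte-identical JSON.
write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(12),
                       pretty = TRUE)
  invisible(path)
}

#' Serialise a kinetic fit to JSON
#'
#' Writes the flat record `{onset_time, production_rate, degradation_rate,
#' rmsd, onset_fixed_zero, n_starts, seed}` with fixed key order and 12
#' significant digits.
#'
#' @param fit A `kinetic_fit`.
#' @param path Output path.
#' @return `write_kinetic_fit()` returns `path` invisibly;
#'   `read_kinetic_fit()` returns a `kinetic_fit` (without the original
#'   data attached).
#' @export
write_kinetic_fit <- function(fit, path) {
  stopifnot(inherits(fit, "kinetic_fit"))
  write_json_stable(list(
    onset_time = fit$params$onset_time,
    production_rate = fit$params$production_rate,
    degradation_rate = fit$params$degradation_rate,
    rmsd = fit$rmsd,
    onset_fixed_zero = fit$onset_fixed_zero,
    n_starts = fit$n_starts,
    seed = fit$seed
  ), path)
}

#' @rdname write_kinetic_fit
#' @export
read_kinetic_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_kinetic_fit(
    kinetic_params(x$onset_time, x$production_rate, x$degradation_rate),
    x$rmsd, x$onset_fixed_zero, x$n_starts, x$seed, TRUE, NULL
  )
}

#' Serialise a flow fit to JSON
#'
#' Writes best-fit parameters, the comparable objective, the population
#' summaries, per-parameter uncertainty ranges and the full restart log.
#'
#' @param fit A `flow_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flow_fit <- function(fit, path) {
  stopifnot(inherits(fit, "flow_fit"))
  write_json_stable(list(
    params = fit$params[flow_param_names],
    objective = fit$objective,
    mean_activation_time = fit$mean_activation_time,
    mean_expression_rate = fit$mean_expression_rate,
    param_ranges = fit$param_ranges,
    restart_log = fit$restart_log,
    seed = fit$config$seed,
    n_restarts = fit$config$n_restarts,
    top_k = fit$config$top_k,
    n_sim_cells = fit$config$n_sim_cells
  ), path)
}

stage_abort <- function(stage, parent) {
  abort(paste0("[", stage, "] ", conditionMessage(parent)))
}

#' Run the full synthetic-to-report pipeline
#'
#' Orchestrates the package end to end on synthetic scenarios: generate mRNA
#' time courses and flow snapshots for each scenario, fit the kinetic model,
#' derive phenotype metrics, build the relative and percent-change comparison
#' tables against a reference strain, and (optionally) fit the single-cell
#' model. All artefacts are written under `out_dir` (CSV tables, JSON fits,
#' and a JSON run log recording seeds), and rerunning with the same config
#' produces byte-identical outputs.
#'
#' @param config A list (or path to a YAML file parseable to one) with
#'   elements: `out_dir`; `seed`; `reference` (reference strain label,
#'   default `"wildtype"`); optional `scenarios` (named list of
#'   [scenario_spec()], default [strain_presets()]); `fit_starts` (kinetic
#'   multi-start count, default 50); `fit_flow` (logical, default `FALSE`);
#'   `flow_config` (a [flow_fit_config()], used when `fit_flow` is `TRUE`).
#' @return Invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("[config] Reading YAML configs requires the 'yaml' package.")
    }
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) abort("[config] `out_dir` is required.")
  if (is.null(config$seed)) abort("[config] an explicit `seed` is required.")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reference <- config$reference %||% "wildtype"
  scenarios <- config$scenarios %||% strain_presets(seed = config$seed)
  fit_starts <- config$fit_starts %||% 50
  paths <- list()

  message("[generate] ", length(scenarios), " scenario(s)")
  datasets <- tryCatch(
    purrr::map(scenarios, make_mrna_dataset),
    error = function(e) stage_abort("generate", e)
  )
  for (nm in names(datasets)) {
    p <- file.path(out_dir, paste0("mrna_", nm, ".csv"))
    write_timecourse(datasets[[nm]], p)
    paths[[paste0("mrna_", nm)]] <- p
  }

  message("[fit-mrna] multi-start kinetic fits (", fit_starts, " starts)")
  fits <- tryCatch(
    purrr::imap(datasets, function(tc, nm) {
      fit_kinetics(tc, n_starts = fit_starts,
                   seed = derive_seed(config$seed, match(nm, names(datasets))))
    }),
    error = function(e) stage_abort("fit-mrna", e)
  )
  for (nm in names(fits)) {
    p <- file.path(out_dir, paste0("fit_", nm, ".json"))
    write_kinetic_fit(fits[[nm]], p)
    paths[[paste0("fit_", nm)]] <- p
  }

  message("[derive-metrics] phenotypes relative to '", reference, "'")
  tables <- tryCatch({
    pheno <- purrr::imap_dfr(fits, function(f, nm) {
      derive_phenotypes(f, strain = nm, condition = "primary")
    })
    if (!reference %in% pheno$strain) {
      abort(paste0("reference strain '", reference, "' not among scenarios"))
    }
    list(phenotypes = pheno,
         relative = relative_to_reference(pheno, reference))
  }, error = function(e) stage_abort("derive-metrics", e))
  p <- file.path(out_dir, "phenotypes.csv")
  readr::write_csv(tables$phenotypes, p, progress = FALSE)
  paths$phenotypes <- p
  p <- file.path(out_dir, "relative_to_reference.csv")
  readr::write_csv(tables$relative, p, progress = FALSE)
  paths$relative <- p

  if (isTRUE(config$fit_flow)) {
    message("[fit-flow] single-cell model fits")
    flow_cfg <- config$flow_config %||%
      flow_fit_config(profile = "reduced", seed = config$seed)
    flow_fits <- tryCatch(
      purrr::imap(scenarios, function(sc, nm) {
        sc$n_cells <- flow_cfg$n_sim_cells
        fit_flow_model(make_flow_dataset(sc), flow_cfg)
      }),
      error = function(e) stage_abort("fit-flow", e)
    )
    for (nm in names(flow_fits)) {
      p <- file.path(out_dir, paste0("flowfit_", nm, ".json"))
      write_flow_fit(flow_fits[[nm]], p)
      paths[[paste0("flowfit_", nm)]] <- p
    }
  }

  log_path <- file.path(out_dir, "run_log.json")
  write_json_stable(list(
    seed = config$seed,
    reference = reference,
    scenarios = names(scenarios),
    fit_starts = fit_starts,
    fit_flow = isTRUE(config$fit_flow),
    package_version = as.character(utils::packageVersion("galkinetics"))
  ), log_path)
  paths$log <- log_path
  message("[done] artefacts in ", out_dir)
  invisible(paths)
}
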