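#' Derive induction phenotype metrics from a kinetic fit
#'
#' Converts fitted kinetic parameters into the four standard induction
#' phenotypes: activation (onset) time, steady-state expression level, time
#' to half the steady-state level, and the activation-to-half interval (the
#' time from onset to half steady state, log(2)/degradation_rate, which
#' isolates the transcription-rate phenotype from the lag phenotype).
#'
#' @param fit A `kinetic_fit` or [kinetic_params()] object with positive
#'   production and degradation rates.
#' @param strain Strain label for the row.
#' @param condition `"primary"` (induction after long-term repression) or
#'   `"secondary"` (reinduction after short-term repression).
#' @return A one-row tibble with columns `strain`, `condition`,
#'   `activation_time`, `steady_state_level`, `time_to_half`,
#'   `activation_to_half`.
#' @export
derive_phenotypes <- function(fit, strain, condition = c("primary", "secondary")) {
  condition <- match.arg(condition)
  params <- if (inherits(fit, "kinetic_fit")) fit$params else fit
  stopifnot(inherits(params, "kinetic_params"))
  if (params$production_rate <= 0) {
    abort("Phenotypes are undefined for a zero production rate.")
  }
  if (params$degradation_rate <= 0) {
    abort("Phenotypes require a positive degradation rate.")
  }
  half <- half_steady_state_time(params)
  tibble::tibble(
    strain = strain,
    condition = condition,
    activation_time = params$onset_time,
    steady_state_level = steady_state_level(params),
    time_to_half = half,
    activation_to_half = half - params$onset_time
  )
}

phenotype_metrics <- c("activation_time", "steady_state_level",
                       "time_to_half", "activation_to_half")

pivot_phenotypes <- function(rows) {
  tidyr::pivot_longer(
    rows,
    cols = dplyr::all_of(intersect(phenotype_metrics, names(rows))),
    names_to = "metric", values_to = "value"
  )
}

#' Phenotypes relative to a reference strain
#'
#' Expresses every strain's metrics as a percentage of the reference
#' strain's, within each condition: 100 * strain / reference. The reference
#' strain therefore always reads 100.0. Values are reported rounded to one
#' decimal (half away from zero) alongside the unrounded ratio.
#'
#' @param rows A phenotype tibble as produced by [derive_phenotypes()]
#'   (one row per strain and condition).
#' @param reference Label of the reference strain; must be present and have
#'   strictly positive metrics.
#' @return A tibble with columns `strain`, `condition`, `metric`, `value`
#'   (rounded percent) and `raw` (unrounded), carrying attributes
#'   `reference_strain` and `mode = "relative_to_reference"`.
#' @export
relative_to_reference <- function(rows, reference) {
  if (!reference %in% rows$strain) {
    abort(paste0("Reference strain '", reference, "' not found."))
  }
  long <- pivot_phenotypes(rows)
  ref <- dplyr::filter(long, .data$strain == reference)
  if (any(ref$value <= 0)) {
    abort("Reference metrics must be strictly positive.")
  }
  ref <- dplyr::select(ref, "condition", "metric", ref_value = "value")
  out <- dplyr::inner_join(long, ref, by = c("condition", "metric"))
  out <- dplyr::mutate(
    out,
    raw = 100 * .data$value / .data$ref_value,
    value = round_away(.data$raw, 1)
  )
  out <- dplyr::select(out, "strain", "condition", "metric", "value", "raw")
  structure(out, reference_strain = reference, mode = "relative_to_reference")
}

#' Percent change between primary and secondary induction
#'
#' For each strain and metric, computes 100 * (secondary - primary) / primary:
#' the percentage change of the phenotype on reinduction after short-term
#' repression relative to first induction after long-term repression.
#' Negative values mean the reinduction phenotype is smaller (faster
#' induction); -100 means the metric vanished entirely.
#'
#' @param primary,secondary Phenotype tibbles ([derive_phenotypes()] rows)
#'   for the two conditions, matched by `strain`.
#' @return A tibble with columns `strain`, `metric`, `value` (rounded
#'   percent) and `raw`, with attribute `mode = "percent_change"`.
#' @export
percent_change <- function(primary, secondary) {
  p <- dplyr::select(pivot_phenotypes(primary), "strain", "metric",
                     primary = "value")
  s <- dplyr::select(pivot_phenotypes(secondary), "strain", "metric",
                     secondary = "value")
  out <- dplyr::inner_join(p, s, by = c("strain", "metric"))
  if (nrow(out) == 0) abort("No matching (strain, metric) pairs.")
  if (any(out$primary <= 0)) {
    abort("Primary metrics must be strictly positive for percent change.")
  }
  out <- dplyr::mutate(
    out,
    raw = 100 * (.data$secondary - .data$primary) / .data$primary,
    value = round_away(.data$raw, 1)
  )
  out <- dplyr::select(out, "strain", "metric", "value", "raw")
  structure(out, mode = "percent_change")
}

#' Bundled GAL1 induction phenotype metrics
#'
#' A small reference table of published quantitative GAL1 induction
#' phenotypes for wild-type and H2A.Z mutant yeast strains, under primary
#' induction (after long-term glucose repression) and secondary induction
#' (reinduction after 12 h of repression). Times are in minutes; steady-state
#' levels are GAL1/ACT1 expression ratios. Strain labels are ASCII-encoded:
#' `htz1_delta` is the H2A.Z deletion, `htz1_K3.8.10.14R` the unacetylatable
#' allele, and the `_CRY1` / `_DBY50` rows are the independent strain
#' background pair.
#'
#' Useful as a worked input for [relative_to_reference()] and
#' [percent_change()].
#'
#' @return A tibble with columns `strain`, `condition`, `activation_time`,
#'   `steady_state_level`, `time_to_half`, `activation_to_half`.
#' @export
gal1_reference_phenotypes <- function() {
  path <- system.file("extdata", "gal1_phenotypes.csv",
                      package = "galkinetics", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
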