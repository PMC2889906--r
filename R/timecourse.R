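#' Construct a replicate expression time course
#'
#' A time course is a tidy tibble with one row per (time, replicate)
#' measurement and columns `time`, `replicate`, `value`. Every replicate must
#' be observed on the same strictly increasing time grid, and all values must
#' be finite. The measurement time unit (`"minutes"` or `"hours"`) and an
#' optional sample label travel with the tibble as attributes so downstream
#' fits and reports can convert units explicitly.
#'
#' @param x A data frame with columns `time`, `replicate`, `value`.
#' @param time_unit Unit of the `time` column, `"minutes"` or `"hours"`.
#' @param label Optional sample identifier.
#' @return A tibble of class `timecourse`.
#' @examples
#' tc <- as_timecourse(
#'   data.frame(time = rep(c(0, 2, 4), 2), replicate = rep(1:2, each = 3),
#'              value = c(0, 1, 2, 0, 1.1, 1.9)),
#'   time_unit = "hours", label = "demo"
#' )
#' tc_times(tc)
#' @export
as_timecourse <- function(x, time_unit = c("hours", "minutes"), label = NULL) {
  time_unit <- match.arg(time_unit)
  x <- tibble::as_tibble(x)
  required <- c("time", "replicate", "value")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Time course is missing required column(s): ",
      paste(missing_cols, collapse = ", "), "."
    ))
  }
  if (!is.numeric(x$time) || !is.numeric(x$value)) {
    abort("Time course columns `time` and `value` must be numeric.")
  }
  if (anyNA(x$time) || any(!is.finite(x$value))) {
    abort("Time course times and values must be finite and non-missing.")
  }
  if (any(x$time < 0)) {
    abort("Time course times must be non-negative.")
  }
  dup <- duplicated(x[, c("time", "replicate")])
  if (any(dup)) {
    abort("Duplicate (time, replicate) pairs in time course.")
  }
  x <- dplyr::arrange(x, .data$replicate, .data$time)
  grids <- split(x$time, x$replicate)
  ref <- grids[[1]]
  if (any(diff(ref) <= 0)) {
    abort("Time grid must be strictly increasing.")
  }
  same <- vapply(grids, function(g) identical(g, ref), logical(1))
  if (!all(same)) {
    abort("All replicates must share the same time grid.")
  }
  structure(
    x,
    class = c("timecourse", class(tibble::tibble())),
    time_unit = time_unit,
    label = label
  )
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf(
    "<timecourse%s: %d time points x %d replicates, unit = %s>\n",
    if (is.null(attr(x, "label"))) "" else paste0(" '", attr(x, "label"), "'"),
    length(tc_times(x)), length(unique(x$replicate)), attr(x, "time_unit")
  ))
  NextMethod()
}

#' @rdname as_timecourse
#' @param tc A `timecourse` object.
#' @export
tc_times <- function(tc) sort(unique(tc$time))

#' @rdname as_timecourse
#' @export
tc_time_unit <- function(tc) attr(tc, "time_unit") %||% "hours"

#' Replicate-mean expression values on the time grid
#'
#' @param tc A `timecourse`.
#' @return A tibble with columns `time`, `mean`, `sd`, `n`.
#' @export
tc_summarise <- function(tc) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(tc), .data$time),
    mean = mean(.data$value),
    sd = if (dplyr::n() > 1) sd(.data$value) else 0,
    n = dplyr::n(),
    .groups = "drop"
  )
}

#' Convert a time course between minutes and hours
#'
#' @param tc A `timecourse`.
#' @param to Target unit, `"minutes"` or `"hours"`.
#' @return A `timecourse` in the requested unit.
#' @export
convert_time_unit <- function(tc, to = c("hours", "minutes")) {
  to <- match.arg(to)
  from <- tc_time_unit(tc)
  if (from == to) return(tc)
  factor <- if (from == "minutes") 1 / 60 else 60
  out <- tibble::as_tibble(tc)
  out$time <- out$time * factor
  as_timecourse(out, time_unit = to, label = attr(tc, "label"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
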