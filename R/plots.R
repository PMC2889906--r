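#' Plot a replicate time course with optional fitted curve
#'
#' Shows replicate means (points with standard-deviation bars) on the time
#' grid; [autoplot.kinetic_fit()] overlays the fitted induction trajectory.
#'
#' @param tc A [as_timecourse()] object.
#' @return A ggplot object.
#' @export
plot_timecourse <- function(tc) {
  stopifnot(inherits(tc, "timecourse"))
  avg <- tc_summarise(tc)
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$time, y = .data$mean)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.15, colour = "grey50"
    ) +
    ggplot2::geom_point(shape = 1, size = 2) +
    ggplot2::labs(
      x = paste0("Time (", tc_time_unit(tc), ")"),
      y = "Expression (relative units)",
      title = attr(tc, "label")
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot kinetic_fit
#' @export
autoplot.kinetic_fit <- function(object, n_curve = 200, ...) {
  tc <- object$data
  if (is.null(tc)) abort("This fit carries no data to plot.")
  grid <- seq(min(tc$time), max(tc$time), length.out = n_curve)
  curve <- tibble::tibble(time = grid,
                          value = predict_mrna(object$params, grid))
  plot_timecourse(tc) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$time, y = .data$value),
                       colour = "firebrick")
}

#' Histogram panels of snapshot intensity distributions
#'
#' One panel per snapshot time, on an asinh intensity scale (the cytometry
#' convention of plotting near-logarithmically while accommodating zeros and
#' small negatives).
#'
#' @param snapshots A tidy snapshot tibble (`time`, `intensity`, ...).
#' @param bins Number of histogram bins.
#' @param threshold Optional gate threshold drawn as a vertical line.
#' @return A ggplot object.
#' @export
plot_flow_histograms <- function(snapshots, bins = 64, threshold = NULL) {
  check_snapshot_frame(snapshots)
  p <- ggplot2::ggplot(snapshots,
                       ggplot2::aes(x = asinh(.data$intensity))) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::facet_wrap(~time, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "asinh(GFP intensity)", y = "Cells") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = asinh(threshold),
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' @method autoplot flow_fit
#' @export
autoplot.flow_fit <- function(object, n_cells = 20000, ...) {
  target <- object$target
  sim <- sample_population(object$params, n_cells = n_cells,
                           times = target$times,
                           seed = object$config$seed, sample = "model")
  if (target$mode == "histogram") {
    edges <- target$edges
    obs <- purrr::map_dfr(seq_along(target$times), function(j) {
      tibble::tibble(
        time = target$times[j],
        mid = (edges[-1] + edges[-length(edges)]) / 2,
        frequency = target$target[, j],
        source = "observed"
      )
    })
    simf <- purrr::map_dfr(seq_along(target$times), function(j) {
      v <- asinh(sim$intensity[sim$time == target$times[j]])
      counts <- bin_counts(v, edges)
      tibble::tibble(
        time = target$times[j],
        mid = (edges[-1] + edges[-length(edges)]) / 2,
        frequency = counts / max(sum(counts), 1),
        source = "model"
      )
    })
    ggplot2::ggplot(dplyr::bind_rows(obs, simf),
                    ggplot2::aes(x = .data$mid, y = .data$frequency,
                                 colour = .data$source)) +
      ggplot2::geom_step() +
      ggplot2::facet_wrap(~time, labeller = ggplot2::label_both) +
      ggplot2::labs(x = "asinh(GFP intensity)", y = "Frequency",
                    colour = NULL) +
      ggplot2::theme_minimal()
  } else {
    plot_flow_histograms(sim)
  }
}
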