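# broom-style tidiers and ggplot2 autoplot methods for the package's result
# objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a hypothesis-test result
#'
#' @param x A `neodev_test` from [mann_whitney_u()], [kruskal_dunn()], or
#'   [friedman_dunn()].
#' @param ... Unused.
#' @return For omnibus results a one-row tibble (`method`, `statistic`,
#'   `p.value`); rows for each pairwise comparison follow when a post-hoc
#'   table exists.
#' @export
tidy.neodev_test <- function(x, ...) {
  top <- tibble::tibble(method = x$method, term = "omnibus",
                        statistic = x$statistic, p.value = x$p_value,
                        p.adjusted = NA_real_)
  if (is.null(x$pairwise)) return(top)
  dplyr::bind_rows(top, tibble::tibble(
    method = x$method, term = x$pairwise$comparison,
    statistic = x$pairwise$z, p.value = x$pairwise$p_unadjusted,
    p.adjusted = x$pairwise$p_adjusted))
}

#' @rdname tidy.neodev_test
#' @export
glance.neodev_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 p.value = x$p_value,
                 n = sum(x$group_sizes), k_groups = length(x$group_sizes))
}

#' Tidy a cohort analysis result
#'
#' @param x A `neodev_cohort_result` from [run_cohort()].
#' @param ... Unused.
#' @return The per-feature stats table (unnested of its list columns).
#' @export
tidy.neodev_cohort_result <- function(x, ...) {
  dplyr::select(x$stats, "feature", "method", "statistic", "p_value",
                "n_excluded", "skipped_reason")
}

#' @rdname tidy.neodev_cohort_result
#' @export
glance.neodev_cohort_result <- function(x, ...) {
  tibble::tibble(n_animals = nrow(x$features),
                 n_features = length(x$config$features),
                 n_tested = sum(!is.na(x$stats$p_value)),
                 n_significant = sum(x$stats$p_value < 0.05, na.rm = TRUE))
}

#' Plot a power spectral density
#'
#' @param object A `neodev_psd`.
#' @param bands Optional [band_scheme()] whose borders are drawn as dotted
#'   lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.neodev_psd <- function(object, bands = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$freq_hz,
                                            y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = expression(PSD ~ (mu * V^2 / Hz)))
  if (!is.null(bands)) {
    p <- p + ggplot2::geom_vline(xintercept = unique(unlist(bands)),
                                 linetype = "dotted")
  }
  p
}

#' Plot a phase-amplitude comodulogram heatmap
#'
#' @param object A `neodev_comodulogram`.
#' @param ... Unused.
#' @return A ggplot heatmap of coupling over the phase x amplitude frequency
#'   grid.
#' @export
autoplot.neodev_comodulogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$phase_hz, y = .data$amp_hz,
                                       fill = .data$coupling)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "MI") +
    ggplot2::labs(x = "Phase frequency (Hz)", y = "Amplitude frequency (Hz)")
}

#' Plot detected active periods over the LFP trace
#'
#' @param rec A [recording()].
#' @param periods Tibble from [detect_active_periods()].
#' @param channel_id Channel to display (default: first).
#' @param xlim Optional time range (s).
#' @return A ggplot of the trace with detected periods shaded.
#' @export
plot_active_periods <- function(rec, periods, channel_id = NULL,
                                xlim = NULL) {
  id <- channel_id %||% rec$channels$channel_id[[1]]
  x <- channel_trace(rec, id)
  df <- tibble::tibble(t_s = (seq_along(x) - 1) / rec$fs, uV = x)
  per <- periods[periods$channel_id == id, ]
  if (!is.null(xlim)) {
    df <- df[df$t_s >= xlim[1] & df$t_s <= xlim[2], ]
    per <- per[per$end_s >= xlim[1] & per$start_s <= xlim[2], ]
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$uV)) +
    ggplot2::geom_rect(data = per,
                       ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                                    ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, fill = "orange", alpha = 0.3) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "Time (s)", y = sprintf("%s (%s)", id, rec$units))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
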