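# ggplot2 figures for tracks and conversion tables

#' Plot a depth-normalized RT-stop track
#'
#' @param track Tibble from [normalize_rpm()] (optionally with a `library`
#'   column for faceting/colour).
#' @param ref Reference to plot (default the first).
#' @param highlight Optional absolute positions to mark with vertical lines.
#' @return A ggplot object.
#' @export
plot_stop_track <- function(track, ref = track$ref[[1]], highlight = NULL) {
  d <- track[track$ref == ref, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$stop_rpm))
  if ("library" %in% names(d))
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$library))
  else p <- p + ggplot2::geom_line(colour = "steelblue")
  if (!is.null(highlight))
    p <- p + ggplot2::geom_vline(xintercept = highlight,
                                 linetype = "dashed", colour = "red3")
  p + ggplot2::labs(x = paste0(ref, " position (nt)"),
                    y = "RT stops (RPM)") +
    ggplot2::theme_minimal()
}

#' Plot the IP over SMInput coverage-ratio track
#'
#' @param track Tibble from [enrichment_track()].
#' @param ref Reference to plot.
#' @param windows Optional window tibble (e.g. significant rows of
#'   [window_enrichment()]) shaded under the curve.
#' @return A ggplot object.
#' @export
plot_enrichment_track <- function(track, ref = track$ref[[1]],
                                  windows = NULL) {
  d <- track[track$ref == ref, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$ratio)) +
    ggplot2::geom_line(colour = "grey25")
  if (!is.null(windows) && nrow(windows) > 0) {
    w <- windows[windows$ref == ref, ]
    if (nrow(w) > 0)
      p <- p + ggplot2::geom_rect(
        data = w, inherit.aes = FALSE,
        ggplot2::aes(xmin = .data$start, xmax = .data$end,
                     ymin = -Inf, ymax = Inf),
        fill = "orange", alpha = 0.2)
  }
  p + ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = paste0(ref, " position (nt)"),
                  y = "IP / SMInput (depth-normalized)") +
    ggplot2::theme_minimal()
}

#' Bar plot of per-cytosine conversion around a site
#'
#' Stacked converted/non-converted counts per cytosine, the standard way to
#' display amplicon bisulfite results around a candidate m5C.
#'
#' @param table A [conversion_table()] (optionally several, with a
#'   `condition` column).
#' @param center Optional absolute position to center a `window`-nt view on.
#' @param window Half-width in nt when `center` is given.
#' @return A ggplot object.
#' @export
plot_conversion <- function(table, center = NULL, window = 30) {
  d <- table
  if (!is.null(center))
    d <- d[abs(d$pos - center) <= window, ]
  d <- tidyr::pivot_longer(
    d, c("n_converted", "n_nonconverted"),
    names_to = "state", values_to = "count")
  d$state <- ifelse(d$state == "n_converted", "converted (C>T)",
                    "non-converted (m5C)")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$pos),
                                       y = .data$count,
                                       fill = .data$state)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = c("converted (C>T)" = "grey70",
                                          "non-converted (m5C)" = "red3")) +
    ggplot2::labs(x = "cytosine position", y = "reads", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  if ("condition" %in% names(table))
    p <- p + ggplot2::facet_wrap(~condition, ncol = 1)
  p
}

#' @rdname plot_conversion
#' @param object A `bisulfite_run`.
#' @param ... Passed to [plot_conversion()].
#' @export
autoplot.bisulfite_run <- function(object, ...) {
  plot_conversion(object$tables, ...)
}

#' @rdname plot_enrichment_track
#' @param object A `miclip_run`.
#' @param ... Passed to [plot_enrichment_track()].
#' @export
autoplot.miclip_run <- function(object, ...) {
  plot_enrichment_track(object$ratio_track,
                        windows = object$windows[object$windows$significant, ],
                        ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
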