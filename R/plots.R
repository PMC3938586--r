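#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a beat trace
#'
#' Membrane potential and calcium transient of one beat, as stacked panels.
#'
#' @param object An `apopcal_beat` (see [beat_trace()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot apopcal_beat
#' @export
autoplot.apopcal_beat <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"time_ms",
                              names_to = "signal", values_to = "value")
  long$signal <- factor(long$signal, levels = c("vm_mV", "cai_uM"),
                        labels = c("V[m]~(mV)", "Ca^{2+{}}~(mu*M)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ms, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y",
                        labeller = ggplot2::label_parsed) +
    ggplot2::labs(x = "time (ms)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a stack image
#'
#' Renders the dimensional stack as a raster, bottom-left pixel = all-minimum
#' grid point, with masked pixels blank.
#'
#' @param object A [stack_image()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stack_image
#' @export
autoplot.stack_image <- function(object, ...) {
  m <- object$img
  df <- tidyr::expand_grid(row = seq_len(nrow(m)) - 1L,
                           col = seq_len(ncol(m)) - 1L)
  df$value <- as.vector(m[cbind(df$row + 1L, df$col + 1L)])
  o <- object$order
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white",
                                  name = object$value_label) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = sprintf("%s within %s within %s", o[["x_low"]], o[["x_mid"]],
                  o[["x_high"]]),
      y = sprintf("%s within %s within %s", o[["y_low"]], o[["y_mid"]],
                  o[["y_high"]])) +
    ggplot2::theme_minimal()
}

#' Plot conductance-level distributions of a calibrated population
#'
#' Bar chart of how often each grid level of each conductance occurs among
#' the physiological parameter sets at one cycle length.
#'
#' @param calibration An [calibrate()] result (with grid information).
#' @param cl Cycle length whose distribution to plot.
#' @return A ggplot object.
#' @export
plot_level_distribution <- function(calibration, cl) {
  if (is.null(calibration$levels))
    .stop_input("calibration has no level distributions (no grid supplied)")
  dist <- calibration$levels[[as.character(cl)]]
  if (is.null(dist)) .stop_input(paste0("no distribution for CL = ", cl))
  dist$conductance <- factor(dist$conductance, levels = .axes)
  ggplot2::ggplot(dist, ggplot2::aes(x = factor(.data$level), y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~conductance, scales = "free_x") +
    ggplot2::labs(x = "conductance scale factor", y = "parameter sets",
                  title = paste0("CL = ", cl, " ms")) +
    ggplot2::theme_minimal()
}

#' Plot a population biomarker histogram
#'
#' @param records A sweep table.
#' @param biomarker One of [biomarker_names()].
#' @param bin_width Bin width in the biomarker's units.
#' @param range Optional [phys_ranges()]-style bounds drawn as a shaded
#'   band (only meaningful for `apd50` / `apd90`).
#' @param cl Cycle length used to look up `range` bounds.
#' @return A ggplot object.
#' @export
plot_biomarker_histogram <- function(records, biomarker, bin_width,
                                     range = NULL, cl = NULL) {
  h <- biomarker_histogram(records, biomarker, bin_width)
  p <- ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                       y = .data$n)) +
    ggplot2::geom_col(width = bin_width) +
    ggplot2::labs(x = biomarker, y = "parameter sets") +
    ggplot2::theme_minimal()
  if (!is.null(range) && !is.null(cl) && biomarker %in% c("apd50", "apd90")) {
    r <- .validate_ranges(range)
    r <- r[r$cl == cl, , drop = FALSE]
    if (nrow(r))
      p <- p + ggplot2::annotate(
        "rect", xmin = r[[paste0(biomarker, "_lo")]],
        xmax = r[[paste0(biomarker, "_hi")]],
        ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "blue")
  }
  p
}
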