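#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a calibration result
#'
#' One row per cycle length and CL combination with the number of
#' physiological parameter sets and the fraction of the population.
#'
#' @param x An [calibrate()] result.
#' @param ... Unused.
#' @return A tibble: `set`, `n`, `fraction`.
#' @method tidy apopcal_calibration
#' @export
tidy.apopcal_calibration <- function(x, ...) {
  out <- x$counts
  out$fraction <- out$n / x$n_population
  out
}

#' @rdname tidy.apopcal_calibration
#' @return `glance()`: one row with `n_population`, `n_cls`,
#'   `n_pass_all_cls` (size of the full intersection; equal to the
#'   single-CL count when only one CL was calibrated).
#' @method glance apopcal_calibration
#' @export
glance.apopcal_calibration <- function(x, ...) {
  all_key <- paste0("cl", paste(names(x$per_cl), collapse = "_"))
  n_all <- if (length(x$per_cl) == 1L) nrow(x$per_cl[[1L]])
           else nrow(x$intersections[[all_key]])
  tibble(n_population = x$n_population, n_cls = length(x$per_cl),
         n_pass_all_cls = n_all)
}

#' Tidy a stack-order optimisation
#'
#' @param x An [optimize_stack_order()] result.
#' @param ... Unused.
#' @return `tidy()`: all 720 slot assignments with costs, best first.
#'   `glance()`: one row with the optimal order and cost.
#' @method tidy cbdr_fit
#' @export
tidy.cbdr_fit <- function(x, ...) x$table

#' @rdname tidy.cbdr_fit
#' @method glance cbdr_fit
#' @export
glance.cbdr_fit <- function(x, ...) {
  o <- x$order
  tibble(x_low = o[["x_low"]], y_low = o[["y_low"]],
         x_mid = o[["x_mid"]], y_mid = o[["y_mid"]],
         x_high = o[["x_high"]], y_high = o[["y_high"]],
         cost = x$cost)
}

#' Tidy a parameter-set selection
#'
#' @param x An `apopcal_selection`.
#' @param ... Unused.
#' @return `tidy()`: the selected scale vectors. `glance()`: method,
#'   threshold and counts.
#' @method tidy apopcal_selection
#' @export
tidy.apopcal_selection <- function(x, ...) x$set

#' @rdname tidy.apopcal_selection
#' @method glance apopcal_selection
#' @export
glance.apopcal_selection <- function(x, ...) {
  tibble(method = x$method, threshold = x$threshold, count = x$count,
         target_count = x$target_count)
}
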