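#' Pacing protocol
#'
#' Settings for pacing a cell model to steady state: cycle length, sampling
#' interval, total pacing duration and the steady-state tolerance. The
#' defaults follow the reference protocol: 1,000 s of pacing, with the cell
#' considered at steady state when every point of the last AP differs from
#' the corresponding point of the previous AP by less than 5% of the AP
#' amplitude.
#'
#' @param cl Cycle length in ms (> 0).
#' @param dt Sample interval in ms (0 < dt < cl).
#' @param max_time Total pacing time in ms before the steady-state check.
#' @param steady_tol Steady-state tolerance as a fraction of AP amplitude,
#'   in (0, 1).
#' @return An object of class `pacing_protocol`.
#' @export
#' @examples
#' pacing_protocol(cl = 400)
pacing_protocol <- function(cl, dt = 1, max_time = 1e6, steady_tol = 0.05) {
  if (!is.numeric(cl) || length(cl) != 1L || cl <= 0)
    .stop_input("cl must be a single positive cycle length")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0 || dt >= cl)
    .stop_input("dt must satisfy 0 < dt < cl")
  if (!is.numeric(max_time) || length(max_time) != 1L || max_time < 2 * cl)
    .stop_input("max_time must cover at least two beats")
  if (!is.numeric(steady_tol) || length(steady_tol) != 1L ||
      steady_tol <= 0 || steady_tol >= 1)
    .stop_input("steady_tol must be in (0, 1)")
  structure(list(cl = cl, dt = dt, max_time = max_time,
                 steady_tol = steady_tol),
            class = "pacing_protocol")
}

#' Steady-state criterion on two consecutive beats
#'
#' Two consecutive APs are at steady state when the membrane potential of
#' the later beat differs pointwise from the earlier beat by less than
#' `tol` times the later beat's AP amplitude (max minus min Vm). The
#' criterion is applied to Vm only; the calcium transient is not checked.
#'
#' @param beat_n,beat_prev Beat traces (as returned by [beat_trace()]) of
#'   equal length and sampling interval.
#' @param tol Tolerance fraction of AP amplitude.
#' @return `TRUE` iff the criterion passes.
#' @export
#' @examples
#' b <- beat_trace(scale_vector(), 400, beat = 50)
#' is_steady_state(b, b)
is_steady_state <- function(beat_n, beat_prev, tol = 0.05) {
  bn <- .as_beat(beat_n)
  bp <- .as_beat(beat_prev)
  if (length(bn$vm_mV) != length(bp$vm_mV))
    .stop_input("beats have different lengths")
  if (is.finite(bn$dt) && is.finite(bp$dt) &&
      !isTRUE(all.equal(bn$dt, bp$dt)))
    .stop_input("beats have different sampling intervals")
  amp <- max(bn$vm_mV) - min(bn$vm_mV)
  max(abs(bn$vm_mV - bp$vm_mV)) < tol * amp
}

#' First beat at which pacing reaches steady state
#'
#' Paces the model beat by beat from rest and returns the first beat index
#' `n >= 2` at which beats `n` and `n - 1` satisfy [is_steady_state()].
#'
#' @inheritParams run_paced
#' @param max_beats Give up (returning `NA`) after this many beats.
#' @return Integer beat index, or `NA_integer_`.
#' @export
first_steady_beat <- function(model, scales, protocol, max_beats = 1000L) {
  st <- model$init(scales, protocol$cl, protocol$dt)
  a <- model$advance(st, 1, keep_trace = TRUE)
  prev <- a$trace
  for (n in 2:max_beats) {
    a <- model$advance(a$state, 1, keep_trace = TRUE)
    if (is_steady_state(a$trace, prev, protocol$steady_tol)) return(n)
    prev <- a$trace
  }
  NA_integer_
}

#' Pace one parameter set to steady state
#'
#' Paces the model for `protocol$max_time`, then compares the last two full
#' beats with the steady-state criterion. If the criterion fails, pacing is
#' extended in increments of 100 beats up to a hard cap of twice
#' `max_time`; if it still fails the result is flagged `steady = FALSE`.
#' A degenerate beat (an AP that does not repolarise within the cycle) is
#' recorded as a flagged result, not an error, so sweeps over a full grid
#' never abort.
#'
#' @param model A cell-model contract object (see [toy_cell_model()]).
#' @param scales A single-row data frame of conductance scale factors.
#' @param protocol A [pacing_protocol()].
#' @return An object of class `paced_result`: list with `final` and
#'   `penultimate` beat traces (internal form; `NULL` when degenerate),
#'   `steady`, `degenerate`, `beats_run` and `total_time` (ms).
#' @export
#' @examples
#' pr <- run_paced(toy_cell_model(), scale_vector(), pacing_protocol(400))
#' pr$steady
run_paced <- function(model, scales, protocol) {
  if (!inherits(protocol, "pacing_protocol"))
    .stop_input("protocol must be a pacing_protocol")
  n_target <- max(2L, floor(protocol$max_time / protocol$cl))
  n_cap <- max(n_target, floor(2 * protocol$max_time / protocol$cl))
  res <- tryCatch({
    st <- model$init(scales, protocol$cl, protocol$dt)
    a <- model$advance(st, n_target - 1L, keep_trace = TRUE)
    penult <- a$trace
    a <- model$advance(a$state, 1L, keep_trace = TRUE)
    final <- a$trace
    beats <- n_target
    steady <- is_steady_state(final, penult, protocol$steady_tol)
    while (!steady && beats < n_cap) {
      step <- min(100L, n_cap - beats)
      a <- model$advance(a$state, step - 1L, keep_trace = TRUE)
      penult <- a$trace
      a <- model$advance(a$state, 1L, keep_trace = TRUE)
      final <- a$trace
      beats <- beats + step
      steady <- is_steady_state(final, penult, protocol$steady_tol)
    }
    list(final = final, penultimate = penult, steady = steady,
         degenerate = FALSE, beats_run = beats,
         total_time = beats * protocol$cl)
  },
  apopcal_degenerate_beat = function(e) {
    list(final = NULL, penultimate = NULL, steady = FALSE,
         degenerate = TRUE, beats_run = 0L, total_time = 0)
  })
  structure(res, class = "paced_result")
}
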