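# Internal biomarker engine on plain vectors; returns a named list.
# Derivatives are first-order forward differences on the uniform grid,
# attributed to the left sample; dV/dt_max ties break to the earliest time.
# Threshold crossings (APD, CTD) are located by linear interpolation between
# the bracketing samples, searching for the first downward crossing after
# the maximum-upstroke point.
.biomarkers_core <- function(t, v, ca, dt) {
  n <- length(v)
  out <- list(
    dvdt_max = NA_real_, dvdt_time = NA_real_, v_rest = NA_real_,
    v_plat = NA_real_, v_plat_fallback = FALSE,
    apd50 = NA_real_, apd90 = NA_real_,
    ca_dia = NA_real_, ca_sys = NA_real_, cat_amp = NA_real_,
    ctd50 = NA_real_, ctd90 = NA_real_
  )
  if (n < 3L) return(out)

  d <- (v[-1L] - v[-n]) / dt          # length n-1, d[j] at time t[j]
  i0 <- which.max(d)                  # earliest tie by which.max
  out$dvdt_max <- d[i0]               # mV/ms == V/s
  out$dvdt_time <- t[i0]
  out$v_rest <- v[1L]
  vmax <- max(v)

  # plateau potential: the point after the activation spike at which dV/dt
  # reaches its smallest absolute value while still <= 0, searched between
  # the upstroke and the steepest repolarisation (the global minimum of
  # dV/dt), so the resting tail after full repolarisation is excluded.
  # For a notched AP this lands at the notch recovery; ties break earliest.
  jp <- NA_integer_
  jmin <- which.min(d)
  if (jmin > i0 + 1L) {
    win <- seq.int(i0 + 1L, jmin - 1L)
    cand <- win[d[win] <= 0]
    if (length(cand)) jp <- cand[which.min(abs(d[cand]))]
  }
  if (!is.na(jp)) {
    out$v_plat <- v[jp]
  } else {
    jf <- i0 + as.integer(round(20 / dt))
    out$v_plat <- v[min(jf, n)]
    out$v_plat_fallback <- TRUE
  }

  out$apd50 <- .cross_after(t, v, i0, out$v_rest + 0.5 * (vmax - out$v_rest)) - t[i0]
  out$apd90 <- .cross_after(t, v, i0, out$v_rest + 0.1 * (vmax - out$v_rest)) - t[i0]

  if (!is.null(ca)) {
    out$ca_dia <- ca[1L]
    out$ca_sys <- max(ca)
    out$cat_amp <- out$ca_sys - out$ca_dia
    dca <- (ca[-1L] - ca[-n]) / dt
    k0 <- which.max(dca)
    out$ctd50 <- .cross_after(t, ca, k0, out$ca_dia + 0.5 * out$cat_amp) - t[k0]
    out$ctd90 <- .cross_after(t, ca, k0, out$ca_dia + 0.1 * out$cat_amp) - t[k0]
  }
  out
}

# First downward crossing of `thr` strictly after index i0: first j > i0
# with x[j-1] > thr and x[j] <= thr, linearly interpolated. NA if none.
.cross_after <- function(t, x, i0, thr) {
  n <- length(x)
  if (i0 + 1L > n) return(NA_real_)
  idx <- seq.int(i0 + 1L, n)
  hit <- idx[x[idx - 1L] > thr & x[idx] <= thr]
  if (!length(hit)) return(NA_real_)
  j <- hit[1L]
  t[j - 1L] + (t[j] - t[j - 1L]) * (x[j - 1L] - thr) / (x[j - 1L] - x[j])
}

#' Maximum upstroke velocity
#'
#' Locates the maximum of the forward-difference derivative of the membrane
#' potential. 1 mV/ms equals 1 V/s. Ties are broken by the earliest time; a
#' flat trace reports rate 0 at the first sample.
#'
#' @param trace A beat trace (see [beat_trace()]).
#' @return A one-row tibble with `time_ms` and `dvdt_max` (V/s).
#' @export
dvdt_max_point <- function(trace) {
  b <- .as_beat(trace)
  if (length(b$vm_mV) < 3L) .stop_input("trace must have at least 3 samples")
  bm <- .biomarkers_core(b$time_ms, b$vm_mV, NULL, b$dt)
  tibble(time_ms = bm$dvdt_time, dvdt_max = bm$dvdt_max)
}

#' Action potential duration at a repolarisation fraction
#'
#' APD at fraction `frac` is the interval from the maximum-upstroke point to
#' the first time the membrane potential falls to or below
#' `V_rest + (1 - frac) * (V_max - V_rest)`, with the crossing linearly
#' interpolated between samples. Returns `NA` (an undefined biomarker) if
#' the trace never repolarises below the threshold.
#'
#' @param trace A beat trace.
#' @param frac Repolarisation fraction, typically 0.5 or 0.9.
#' @return APD in ms, or `NA_real_`.
#' @export
#' @examples
#' apd_at_fraction(beat_trace(scale_vector(), 400), 0.9)
apd_at_fraction <- function(trace, frac) {
  if (!is.numeric(frac) || length(frac) != 1L || frac <= 0 || frac >= 1)
    .stop_input("frac must be a single fraction in (0, 1)")
  b <- .as_beat(trace)
  n <- length(b$vm_mV)
  if (n < 3L) .stop_input("trace must have at least 3 samples")
  d <- (b$vm_mV[-1L] - b$vm_mV[-n]) / b$dt
  i0 <- which.max(d)
  thr <- b$vm_mV[1L] + (1 - frac) * (max(b$vm_mV) - b$vm_mV[1L])
  .cross_after(b$time_ms, b$vm_mV, i0, thr) - b$time_ms[i0]
}

#' Resting and plateau membrane potentials
#'
#' `v_rest()` is the membrane potential at the first sample of the beat
#' window (immediately before stimulus onset). `v_plat()` is the potential
#' at the post-upstroke sample where the derivative is non-positive and
#' closest to zero, searched between the upstroke and the steepest
#' repolarisation point (for a notched AP this lands at the notch
#' recovery); if no such point exists it falls back to the potential 20 ms
#' after the upstroke and the result carries attribute `fallback = TRUE`.
#'
#' @param trace A beat trace.
#' @return Potential in mV.
#' @export
v_rest <- function(trace) {
  b <- .as_beat(trace)
  b$vm_mV[1L]
}

#' @rdname v_rest
#' @export
v_plat <- function(trace) {
  b <- .as_beat(trace)
  bm <- .biomarkers_core(b$time_ms, b$vm_mV, NULL, b$dt)
  structure(bm$v_plat, fallback = bm$v_plat_fallback)
}

#' Calcium transient biomarkers
#'
#' Diastolic calcium is the level at the first sample, systolic calcium the
#' maximum over the beat, and the transient amplitude their difference.
#' CTD50/CTD90 are measured from the point of maximum rate of calcium rise
#' to the interpolated first time calcium recovers to within 50% / 10% of
#' the amplitude above the diastolic level; a transient that never recovers
#' yields `NA` durations.
#'
#' @param trace A beat trace with a `cai_uM` column.
#' @return One-row tibble: `ca_dia`, `ca_sys`, `cat_amp` (uM), `ctd50`,
#'   `ctd90` (ms).
#' @export
ca_biomarkers <- function(trace) {
  b <- .as_beat(trace)
  if (is.null(b$cai_uM)) .stop_input("trace has no calcium signal")
  bm <- .biomarkers_core(b$time_ms, b$vm_mV, b$cai_uM, b$dt)
  tibble(ca_dia = bm$ca_dia, ca_sys = bm$ca_sys, cat_amp = bm$cat_amp,
         ctd50 = bm$ctd50, ctd90 = bm$ctd90)
}

#' All biomarkers of one beat
#'
#' @param trace A beat trace.
#' @return A one-row tibble with the ten biomarker columns (see
#'   [biomarker_names()]) plus `v_plat_fallback`.
#' @export
#' @examples
#' compute_biomarkers(beat_trace(scale_vector(), 400))
compute_biomarkers <- function(trace) {
  b <- .as_beat(trace)
  bm <- .biomarkers_core(b$time_ms, b$vm_mV, b$cai_uM, b$dt)
  tibble(
    dvdt_max = bm$dvdt_max, v_rest = bm$v_rest, v_plat = bm$v_plat,
    apd50 = bm$apd50, apd90 = bm$apd90,
    ca_dia = bm$ca_dia, ca_sys = bm$ca_sys, cat_amp = bm$cat_amp,
    ctd50 = bm$ctd50, ctd90 = bm$ctd90,
    v_plat_fallback = bm$v_plat_fallback
  )
}

#' Biomarker record for one paced parameter set
#'
#' Applies every biomarker operation to the final beat of a paced result and
#' attaches the parameter-set provenance. Degenerate results yield a record
#' of `NA` biomarkers with `degenerate = TRUE`; such records are retained in
#' sweep tables but fail calibration.
#'
#' @param paced A [run_paced()] result.
#' @param scales The single-row scale vector that was paced.
#' @param cl Cycle length in ms.
#' @return A one-row tibble: scale columns, `cl`, the ten biomarkers,
#'   `steady`, `degenerate`, `v_plat_fallback`.
#' @export
compute_record <- function(paced, scales, cl) {
  scales <- validate_scales(scales)
  if (paced$degenerate || is.null(paced$final)) {
    bm <- as.list(rep(NA_real_, length(.biomarker_cols)))
    names(bm) <- .biomarker_cols
    bm$v_plat_fallback <- FALSE
  } else {
    f <- paced$final
    bm <- .biomarkers_core(f$time_ms, f$vm_mV, f$cai_uM, f$dt)
  }
  tibble(
    s_to = scales$s_to, s_Kr = scales$s_Kr, s_Ks = scales$s_Ks,
    s_K1 = scales$s_K1, s_CaL = scales$s_CaL, s_NaK = scales$s_NaK,
    cl = cl,
    dvdt_max = bm$dvdt_max, v_rest = bm$v_rest, v_plat = bm$v_plat,
    apd50 = bm$apd50, apd90 = bm$apd90,
    ca_dia = bm$ca_dia, ca_sys = bm$ca_sys, cat_amp = bm$cat_amp,
    ctd50 = bm$ctd50, ctd90 = bm$ctd90,
    steady = paced$steady, degenerate = paced$degenerate,
    v_plat_fallback = bm$v_plat_fallback
  )
}
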