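#' Constants of the phenomenological six-conductance cell model
#'
#' The bundled cell model is a closed-form phenomenological description of a
#' paced rabbit ventricular action potential and calcium transient whose
#' steady-state APD depends log-linearly on six conductance scaling factors.
#' It is not a biophysical reconstruction of any published ODE model; it
#' exists so that every stage of the sweep/calibration pipeline can be
#' exercised end-to-end with a model whose biomarkers have known closed
#' forms.
#'
#' The steady-state APD90 is
#' \deqn{APD_{90}^{\infty} = (A - B e^{-CL/\tau_{CL}}) \prod_i s_i^{c_i}}
#' with rate-dependence constants `A`, `B`, `tau_cl` (ms) and one signed
#' exponent per conductance. Beat-to-beat approach to steady state is
#' geometric: \eqn{APD_{90}(n) = APD_{90}^\infty (1 + \delta \rho^{n-1})}.
#'
#' @param ... Named overrides of individual constants.
#' @param overrides Optional named list of overrides (e.g. the `toy_model:`
#'   block of a YAML run configuration), applied before `...`.
#'
#' @return An object of class `toy_constants`: a named list with components
#'   `A`, `B`, `tau_cl` (ms), `exponents` (named vector over
#'   [conductance_axes()]), `r` (APD50/APD90 ratio), `delta`, `rho`
#'   (beat-transient amplitude and decay), `v_rest0`, `v_peak` (mV), `t_up`
#'   (ms), `a_to` (mV), `tau_to`, `tau_rise` (ms), `tau_dec_coeff`,
#'   `ca_dia0`, `amp0` (uM).
#' @export
#' @examples
#' k <- toy_constants()
#' k$exponents
toy_constants <- function(..., overrides = NULL) {
  k <- list(
    A = 230, B = 150, tau_cl = 600,
    exponents = c(to = -0.05, Kr = -0.20, Ks = -0.10, K1 = -0.15,
                  CaL = +0.30, NaK = -0.10),
    r = 0.78, delta = 0.08, rho = 0.90,
    v_rest0 = -85, v_peak = 35, t_up = 2,
    a_to = 6, tau_to = 12,
    tau_rise = 15, tau_dec_coeff = 0.35,
    ca_dia0 = 0.20, amp0 = 0.45
  )
  for (ov in list(overrides, list(...))) {
    if (is.null(ov) || length(ov) == 0L) next
    if (is.null(names(ov)) || any(names(ov) == ""))
      .stop_input("toy constant overrides must be named")
    bad <- setdiff(names(ov), names(k))
    if (length(bad))
      .stop_input(paste0("unknown toy constant(s): ", paste(bad, collapse = ", ")))
    if (!is.null(ov$exponents)) {
      e <- unlist(ov$exponents)
      k$exponents[names(e)] <- e
      ov$exponents <- NULL
    }
    k <- modifyList(k, ov)
  }
  k$exponents <- k$exponents[.axes]
  structure(k, class = "toy_constants")
}

#' Construct a conductance scale vector
#'
#' A scale vector holds the six dimensionless multipliers applied to the
#' maximal conductances of the transient outward, rapid/slow delayed
#' rectifier K+, inward rectifier K+, L-type Ca2+ and Na+/K+ pump currents.
#' `1.0` on every axis is the published control model.
#'
#' @param s_to,s_Kr,s_Ks,s_K1,s_CaL,s_NaK Positive multipliers (control = 1).
#' @return A one-row tibble with columns `s_to`, `s_Kr`, `s_Ks`, `s_K1`,
#'   `s_CaL`, `s_NaK`.
#' @export
#' @examples
#' scale_vector()                 # control
#' scale_vector(s_CaL = 0.7)      # 30% L-type Ca2+ block
scale_vector <- function(s_to = 1, s_Kr = 1, s_Ks = 1, s_K1 = 1,
                         s_CaL = 1, s_NaK = 1) {
  validate_scales(tibble(
    s_to = s_to, s_Kr = s_Kr, s_Ks = s_Ks,
    s_K1 = s_K1, s_CaL = s_CaL, s_NaK = s_NaK
  ))
}

#' @rdname scale_vector
#' @param scales A data frame containing the six `s_*` columns.
#' @export
validate_scales <- function(scales) {
  if (!is.data.frame(scales) || !all(.scale_cols %in% names(scales)))
    .stop_input(paste0("scales must be a data frame with columns ",
                       paste(.scale_cols, collapse = ", ")))
  cols <- scales[.scale_cols]
  if (!all(vapply(cols, is.numeric, logical(1))))
    .stop_input("all conductance scale factors must be numeric")
  m <- as.numeric(as.matrix(cols))
  if (anyNA(m) || any(!is.finite(m)) || any(m <= 0))
    .stop_input("all conductance scale factors must be finite and > 0")
  as_tibble(scales)
}

# scales row -> named numeric in canonical order (internal fast path)
.scales_num <- function(scales, i = 1L) {
  s <- as.numeric(scales[i, .scale_cols])
  names(s) <- .axes
  s
}

#' Steady-state APD90 of the phenomenological model
#'
#' Closed form for the asymptotic (fully rate-adapted) APD90 of the bundled
#' cell model: a saturating-exponential cycle-length dependence scaled by a
#' log-linear product over the six conductance multipliers. Increasing any
#' repolarising conductance (`s_to`, `s_Kr`, `s_Ks`, `s_K1`, `s_NaK`)
#' shortens the AP; increasing the L-type Ca2+ conductance prolongs it.
#'
#' @param scales Data frame of scale vectors (one row per parameter set).
#' @param cl Cycle length in ms (>= 200).
#' @param constants A [toy_constants()] object.
#' @return Numeric vector of steady-state APD90 values (ms), one per row.
#' @export
#' @examples
#' steady_apd90(scale_vector(), cl = 400)
steady_apd90 <- function(scales, cl, constants = toy_constants()) {
  scales <- validate_scales(scales)
  if (!is.numeric(cl) || length(cl) != 1L || is.na(cl) || cl < 200)
    .stop_input("cl must be a single cycle length >= 200 ms")
  base <- constants$A - constants$B * exp(-cl / constants$tau_cl)
  m <- as.matrix(scales[.scale_cols])
  base * exp(as.vector(log(m) %*% constants$exponents))
}

# Internal: one beat of the toy model as plain vectors.
# Returns list(time_ms, vm_mV, cai_uM, dt, cl, beat, apd90_n, apd50_n, v_rest)
# or raises apopcal_degenerate_beat if the AP does not fit in the cycle.
.toy_beat <- function(s, cl, beat, dt, k) {
  apd90_inf <- (k$A - k$B * exp(-cl / k$tau_cl)) * prod(s^k$exponents)
  shrink <- if (is.finite(beat)) k$delta * k$rho^(beat - 1) else 0
  apd90_n <- apd90_inf * (1 + shrink)
  if (apd90_n >= cl)
    .stop_degenerate(sprintf(
      "AP does not fit in the cycle: APD90(%s) = %.1f ms >= CL = %g ms",
      format(beat), apd90_n, cl))
  apd50_n <- k$r * apd90_n
  v_rest <- k$v_rest0 - 3 * log(s[["K1"]]) - 1 * log(s[["NaK"]])
  amp_v <- k$v_peak - v_rest

  t <- seq.int(0L, ceiling(cl / dt) - 1L) * dt
  ks <- (apd90_n - apd50_n) / log(9)
  sig <- 1 / (1 + exp((t - apd50_n) / ks))
  tn <- (t - k$t_up) / k$tau_to
  notch <- k$a_to * s[["to"]] * tn * exp(1 - tn)
  v <- v_rest + amp_v * sig - notch
  up <- t < k$t_up
  v[up] <- v_rest + amp_v * t[up] / k$t_up

  tau_dec <- k$tau_dec_coeff * apd90_inf
  ca_dia <- k$ca_dia0 * s[["CaL"]]^0.5 * s[["NaK"]]^-0.3
  amp_ca <- k$amp0 * s[["CaL"]] * s[["NaK"]]^-0.25
  w <- exp(-t / tau_dec) - exp(-t / k$tau_rise)
  t_pk <- log(tau_dec / k$tau_rise) * k$tau_rise * tau_dec / (tau_dec - k$tau_rise)
  w_max <- exp(-t_pk / tau_dec) - exp(-t_pk / k$tau_rise)
  ca <- ca_dia + amp_ca * w / w_max

  list(time_ms = t, vm_mV = v, cai_uM = ca, dt = dt, cl = cl, beat = beat,
       apd90_n = apd90_n, apd50_n = apd50_n, v_rest = v_rest)
}

#' Sample one paced beat of the phenomenological model
#'
#' Generates the membrane potential and intracellular calcium waveforms of
#' beat `beat` (counting from 1 at the first paced beat) on a uniform time
#' grid over one cycle `[0, cl)`. The waveform has a linear upstroke, a
#' notch proportional to `s_to`, a sigmoidal repolarisation whose midpoint
#' and steepness are set by the beat's APD50/APD90, and a double-exponential
#' calcium transient. Early beats are longer than the steady-state beat by a
#' geometrically decaying factor, emulating rate adaptation.
#'
#' @inheritParams steady_apd90
#' @param beat Beat index (integer >= 1, or `Inf` for the steady-state
#'   limiting beat).
#' @param dt Sample interval in ms.
#' @return A tibble of class `apopcal_beat` with columns `time_ms`, `vm_mV`,
#'   `cai_uM` and attributes `dt`, `cl`, `beat`.
#' @export
#' @examples
#' b <- beat_trace(scale_vector(), cl = 400, beat = Inf)
#' range(b$vm_mV)
beat_trace <- function(scales, cl, beat = Inf, dt = 1,
                       constants = toy_constants()) {
  scales <- validate_scales(scales)
  if (nrow(scales) != 1L) .stop_input("beat_trace expects a single scale vector")
  if (!is.numeric(cl) || length(cl) != 1L || cl < 200)
    .stop_input("cl must be a single cycle length >= 200 ms")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0 || dt >= cl)
    .stop_input("dt must satisfy 0 < dt < cl")
  if (!is.numeric(beat) || length(beat) != 1L || beat < 1)
    .stop_input("beat must be a beat index >= 1")
  b <- .toy_beat(.scales_num(scales), cl, beat, dt, constants)
  .beat_tibble(b)
}

.beat_tibble <- function(b) {
  out <- tibble(time_ms = b$time_ms, vm_mV = b$vm_mV, cai_uM = b$cai_uM)
  attr(out, "dt") <- b$dt
  attr(out, "cl") <- b$cl
  attr(out, "beat") <- b$beat
  class(out) <- c("apopcal_beat", class(out))
  out
}

# Normalise a beat (tibble or internal list) to the internal list form.
.as_beat <- function(x) {
  if (is.list(x) && !is.data.frame(x) && all(c("time_ms", "vm_mV") %in% names(x)))
    return(x)
  if (is.data.frame(x) && all(c("time_ms", "vm_mV") %in% names(x))) {
    dt <- attr(x, "dt")
    if (is.null(dt)) dt <- if (nrow(x) > 1L) x$time_ms[2] - x$time_ms[1] else NA_real_
    return(list(time_ms = x$time_ms, vm_mV = x$vm_mV,
                cai_uM = if ("cai_uM" %in% names(x)) x$cai_uM else NULL,
                dt = dt, cl = attr(x, "cl"), beat = attr(x, "beat")))
  }
  .stop_input("expected a beat trace with columns time_ms and vm_mV")
}

#' The phenomenological model as a paceable cell model
#'
#' Wraps the closed-form beat generator in the cell-model contract used by
#' [run_paced()] and [run_sweep()]. A contract object is a list with fields:
#' \describe{
#'   \item{`name`}{Model identifier.}
#'   \item{`init(scales, cl, dt)`}{Returns an opaque pacing state at beat 0.}
#'   \item{`advance(state, n_beats, keep_trace)`}{Paces `n_beats` further
#'     beats and returns `list(state, trace)`, where `trace` is the last
#'     completed beat (internal list form) when `keep_trace` is `TRUE`.
#'     Advancing twice by `n/2` must equal advancing once by `n`.}
#'   \item{`tolerances`}{For ODE-based adapters, the declared relative and
#'     absolute solver tolerances (`NULL` for closed-form models).}
#' }
#' External ODE models (e.g. biophysically detailed rabbit ventricular
#' models) can be plugged into the pipeline by implementing this contract;
#' adapters should resample solver output onto the uniform `dt` grid and
#' declare their tolerances (the reference protocol used relative/absolute
#' tolerances of 1e-7/1e-9).
#'
#' @param constants A [toy_constants()] object.
#' @return A `cell_model` contract object.
#' @export
#' @examples
#' m <- toy_cell_model()
#' st <- m$init(scale_vector(), cl = 400, dt = 1)
#' st <- m$advance(st, 10)$state
toy_cell_model <- function(constants = toy_constants()) {
  k <- constants
  structure(list(
    name = "toy",
    tolerances = NULL,
    init = function(scales, cl, dt) {
      s <- if (is.numeric(scales)) scales[.axes]
           else .scales_num(validate_scales(scales))
      if (anyNA(s) || any(s <= 0)) .stop_input("invalid scale vector")
      list(s = s, cl = cl, dt = dt, beat = 0)
    },
    advance = function(state, n_beats, keep_trace = FALSE) {
      if (n_beats < 0) .stop_input("cannot advance by a negative beat count")
      state$beat <- state$beat + n_beats
      trace <- NULL
      if (keep_trace && state$beat >= 1)
        trace <- .toy_beat(state$s, state$cl, state$beat, state$dt, k)
      list(state = state, trace = trace)
    }
  ), class = "cell_model")
}

#' Generate a steady-state population over a grid
#'
#' Paces the model at every grid point and collects the steady final beat,
#' giving a deterministic fixture population for downstream stages.
#'
#' @param grid A [grid_spec()] or a data frame of scale vectors.
#' @param cl Cycle length in ms.
#' @param model A cell-model contract object.
#' @param protocol A [pacing_protocol()]; its `cl` is overridden by `cl`.
#' @return A tibble with the six scale columns, a `steady` flag and a `trace`
#'   list-column of `apopcal_beat` tibbles.
#' @export
make_population <- function(grid, cl, model = toy_cell_model(),
                            protocol = pacing_protocol(cl)) {
  pts <- if (is.data.frame(grid)) validate_scales(grid) else build_grid(grid)
  protocol$cl <- cl
  res <- map(seq_len(nrow(pts)), function(i) {
    pr <- run_paced(model, pts[i, ], protocol)
    list(steady = pr$steady,
         trace = if (is.null(pr$final)) NULL else .beat_tibble(pr$final))
  })
  out <- pts
  out$steady <- map_lgl(res, "steady")
  out$trace <- map(res, "trace")
  out
}
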