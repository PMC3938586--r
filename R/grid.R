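#' Specify a factorial grid over the six conductance axes
#'
#' A grid specification holds, for each conductance, the ordered list of
#' scale levels to sweep. The default grid varies every conductance by 0%,
#' +/-15% and +/-30% around control. The `expanded_mahajan` preset is the
#' published expanded search window used when the default window yields no
#' physiological parameter sets at long cycle lengths: each axis keeps five
#' levels in 15% steps but the window is shifted along the trend of the
#' near-miss parameter sets (to -15..+45%, CaL +30..+90%, Kr -15..+45%,
#' Ks +45..+105%, K1 -15..+45%, NaK -45..+15%).
#'
#' @param to,Kr,Ks,K1,CaL,NaK Strictly increasing positive level vectors.
#' @return An object of class `grid_spec`: a named list of level vectors in
#'   canonical axis order.
#' @export
#' @examples
#' default_grid()
#' grid_spec(to = 1, Kr = c(0.85, 1.15))
grid_spec <- function(to = c(0.70, 0.85, 1.00, 1.15, 1.30),
                      Kr = c(0.70, 0.85, 1.00, 1.15, 1.30),
                      Ks = c(0.70, 0.85, 1.00, 1.15, 1.30),
                      K1 = c(0.70, 0.85, 1.00, 1.15, 1.30),
                      CaL = c(0.70, 0.85, 1.00, 1.15, 1.30),
                      NaK = c(0.70, 0.85, 1.00, 1.15, 1.30)) {
  levels <- list(to = to, Kr = Kr, Ks = Ks, K1 = K1, CaL = CaL, NaK = NaK)
  for (ax in .axes) {
    lv <- levels[[ax]]
    if (length(lv) == 0L)
      .stop_input(paste0("axis ", ax, " has no levels"))
    if (!is.numeric(lv) || anyNA(lv) || any(lv <= 0))
      .stop_input(paste0("axis ", ax, " levels must be positive numbers"))
    if (is.unsorted(lv, strictly = TRUE))
      .stop_input(paste0("axis ", ax, " levels must be strictly increasing"))
  }
  structure(levels[.axes], class = "grid_spec")
}

#' @rdname grid_spec
#' @export
default_grid <- function() grid_spec()

#' @rdname grid_spec
#' @export
expanded_mahajan_grid <- function() {
  grid_spec(
    to  = c(0.85, 1.00, 1.15, 1.30, 1.45),
    Kr  = c(0.85, 1.00, 1.15, 1.30, 1.45),
    Ks  = c(1.45, 1.60, 1.75, 1.90, 2.05),
    K1  = c(0.85, 1.00, 1.15, 1.30, 1.45),
    CaL = c(1.30, 1.45, 1.60, 1.75, 1.90),
    NaK = c(0.55, 0.70, 0.85, 1.00, 1.15)
  )
}

#' Look up a named grid preset
#'
#' @param name `"default"` or `"expanded_mahajan"`.
#' @return A `grid_spec`.
#' @export
grid_preset <- function(name = c("default", "expanded_mahajan")) {
  switch(match.arg(name),
         default = default_grid(),
         expanded_mahajan = expanded_mahajan_grid())
}

#' Enumerate the full factorial grid
#'
#' Expands a grid specification into one scale vector per grid point, in the
#' canonical enumeration order: axes ordered to, Kr, Ks, K1, CaL, NaK with
#' the last axis (NaK) varying fastest. The order is a pure function of the
#' specification, so sweep outputs keyed by row are reproducible.
#'
#' @param spec A [grid_spec()].
#' @return A tibble with columns `s_to` ... `s_NaK`, one row per grid point.
#' @export
#' @examples
#' nrow(build_grid(default_grid()))   # 5^6 = 15625
build_grid <- function(spec) {
  if (!inherits(spec, "grid_spec"))
    .stop_input("spec must be a grid_spec")
  g <- tidyr::expand_grid(
    s_to = spec$to, s_Kr = spec$Kr, s_Ks = spec$Ks,
    s_K1 = spec$K1, s_CaL = spec$CaL, s_NaK = spec$NaK
  )
  as_tibble(g)
}

# 0-based level index of each grid point on one axis; errors if a value is
# not (numerically) a grid level.
.level_index <- function(values, levels, axis) {
  idx <- match(round(values, 10), round(levels, 10))
  if (anyNA(idx))
    .stop_input(paste0("value not on the ", axis, " axis of the grid"))
  idx - 1L
}
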