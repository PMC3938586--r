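#' Sweep a factorial grid of conductance scalings
#'
#' Paces the model at every grid point and cycle length, measures the
#' biomarkers of the final (steady) beat and returns one record per
#' (parameter set, cycle length). Records are keyed by their position in
#' the canonical grid enumeration, so the output is independent of worker
#' count and scheduling order; per-entry failures (degenerate beats) are
#' recorded in the table, never abort the sweep.
#'
#' @param model A cell-model contract object (see [toy_cell_model()]).
#' @param grid A [grid_spec()] or a data frame of scale vectors.
#' @param cls Numeric vector of cycle lengths in ms (at least one).
#' @param dt Sample interval in ms.
#' @param max_time Total pacing time in ms before the steady-state check.
#' @param steady_tol Steady-state tolerance fraction.
#' @param workers Number of parallel workers (forked; results are
#'   reassembled in grid order).
#' @return A tibble of class `sweep_result` with the six scale columns,
#'   `cl`, the ten biomarkers, `steady`, `degenerate` and
#'   `v_plat_fallback`; attributes `grid_spec` (when a spec was given),
#'   `cls`, `dt`.
#' @export
#' @examples
#' g <- grid_spec(to = 1, Kr = c(0.7, 1.3), Ks = 1, K1 = 1, CaL = 1, NaK = 1)
#' run_sweep(toy_cell_model(), g, cls = 400)
run_sweep <- function(model, grid, cls, dt = 1, max_time = 1e6,
                      steady_tol = 0.05, workers = 1L) {
  if (length(cls) < 1L || !is.numeric(cls) || anyNA(cls))
    .stop_input("cls must contain at least one cycle length")
  pts <- if (is.data.frame(grid)) validate_scales(grid) else build_grid(grid)
  n <- nrow(pts)
  S <- as.matrix(pts[.scale_cols])          # numeric fast path
  bm_cols <- c(.biomarker_cols, "steady", "degenerate", "v_plat_fallback")

  one_cl <- function(cl) {
    protocol <- pacing_protocol(cl, dt = dt, max_time = max_time,
                                steady_tol = steady_tol)
    run_chunk <- function(idx) {
      res <- matrix(NA_real_, nrow = length(idx), ncol = length(bm_cols),
                    dimnames = list(NULL, bm_cols))
      for (k in seq_along(idx)) {
        s <- S[idx[k], ]
        names(s) <- .axes
        pr <- run_paced(model, s, protocol)
        if (!pr$degenerate) {
          f <- pr$final
          bm <- .biomarkers_core(f$time_ms, f$vm_mV, f$cai_uM, f$dt)
          res[k, 1:10] <- unlist(bm[.biomarker_cols], use.names = FALSE)
          res[k, "v_plat_fallback"] <- as.numeric(bm$v_plat_fallback)
        } else {
          res[k, "v_plat_fallback"] <- 0
        }
        res[k, "steady"] <- as.numeric(pr$steady)
        res[k, "degenerate"] <- as.numeric(pr$degenerate)
      }
      res
    }
    parts <- if (workers > 1L && n > 1L) {
      chunks <- split(seq_len(n), cut(seq_len(n), min(workers, n), labels = FALSE))
      parallel::mclapply(chunks, run_chunk, mc.cores = workers)
    } else {
      list(run_chunk(seq_len(n)))
    }
    res <- do.call(rbind, parts)
    out <- as_tibble(cbind(as.data.frame(S), cl = cl,
                           as.data.frame(res[, .biomarker_cols, drop = FALSE])))
    out$steady <- res[, "steady"] == 1
    out$degenerate <- res[, "degenerate"] == 1
    out$v_plat_fallback <- res[, "v_plat_fallback"] == 1
    out
  }

  out <- bind_rows(map(cls, one_cl))
  if (!is.data.frame(grid)) attr(out, "grid_spec") <- grid
  attr(out, "cls") <- cls
  attr(out, "dt") <- dt
  class(out) <- c("sweep_result", class(out))
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  cls <- attr(x, "cls")
  cat("# Conductance sweep: ", nrow(x), " records",
      if (!is.null(cls)) paste0(" (CLs: ", paste(cls, collapse = ", "), " ms)"),
      "\n", sep = "")
  NextMethod()
}
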