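#' Physiological APD ranges per cycle length
#'
#' Inclusive bounds on APD50 and APD90 for rabbit epicardium, per cycle
#' length, used to calibrate the model population. The `"table1"` preset is
#' the experimentally derived normal range at CLs of 400, 600 and 1,000 ms
#' (APD50 104-135 / 116-159 / 137-188 ms; APD90 142-185 / 160-220 /
#' 167-230 ms).
#'
#' @param preset Currently only `"table1"`.
#' @return A tibble of class `phys_ranges` with columns `cl`, `apd50_lo`,
#'   `apd50_hi`, `apd90_lo`, `apd90_hi` (ms).
#' @export
#' @examples
#' phys_ranges()
phys_ranges <- function(preset = c("table1")) {
  preset <- match.arg(preset)
  out <- tibble(
    cl = c(400, 600, 1000),
    apd50_lo = c(104, 116, 137), apd50_hi = c(135, 159, 188),
    apd90_lo = c(142, 160, 167), apd90_hi = c(185, 220, 230)
  )
  .validate_ranges(out)
}

.validate_ranges <- function(ranges) {
  need <- c("cl", "apd50_lo", "apd50_hi", "apd90_lo", "apd90_hi")
  if (!is.data.frame(ranges) || !all(need %in% names(ranges)))
    .stop_input(paste0("ranges must have columns ", paste(need, collapse = ", ")))
  if (any(ranges$apd50_lo >= ranges$apd50_hi) ||
      any(ranges$apd90_lo >= ranges$apd90_hi))
    .stop_input("range lower bounds must be below upper bounds")
  if (any(ranges$apd50_lo < 0) || any(ranges$apd90_lo < 0))
    .stop_input("range bounds must be non-negative")
  out <- as_tibble(ranges)[need]
  class(out) <- unique(c("phys_ranges", class(out)))
  out
}

#' Filter a sweep to physiological parameter sets
#'
#' A record passes calibration iff it reached steady state, all four APD
#' biomarkers are defined, and both APD50 and APD90 lie within the
#' (inclusive) physiological bounds for its cycle length. Non-steady,
#' degenerate and undefined-biomarker records always fail.
#'
#' @param records A sweep table (see [run_sweep()]).
#' @param ranges A [phys_ranges()] table.
#' @param cl Cycle length to filter at; must be present in `ranges`. If
#'   `NULL`, records of every CL present in `ranges` are filtered against
#'   their own CL's bounds.
#' @return The passing records as a tibble (same columns as `records`).
#' @export
#' @examples
#' g <- grid_spec(to = 1, Kr = c(0.7, 1, 1.3), Ks = 1, K1 = 1, CaL = 1, NaK = 1)
#' sw <- run_sweep(toy_cell_model(), g, cls = 400)
#' filter_physiological(sw, phys_ranges(), cl = 400)
filter_physiological <- function(records, ranges, cl = NULL) {
  ranges <- .validate_ranges(ranges)
  if (!is.null(cl)) {
    if (!cl %in% ranges$cl)
      .stop_input(paste0("no physiological range defined for CL = ", cl, " ms"))
    records <- records[records$cl == cl, , drop = FALSE]
    ranges <- ranges[ranges$cl == cl, , drop = FALSE]
  }
  rec <- inner_join(as_tibble(records), ranges, by = "cl")
  ok <- rec$steady & !is.na(rec$apd50) & !is.na(rec$apd90) &
    rec$apd50 >= rec$apd50_lo & rec$apd50 <= rec$apd50_hi &
    rec$apd90 >= rec$apd90_lo & rec$apd90 <= rec$apd90_hi
  rec[ok, setdiff(names(rec), c("apd50_lo", "apd50_hi", "apd90_lo", "apd90_hi")),
      drop = FALSE]
}

#' Intersect per-CL passing sets
#'
#' Given the set of passing parameter sets at each cycle length, computes
#' the exact intersections for every combination of two or more CLs, keyed
#' by the sorted CLs joined with underscores (e.g. `cl400_600_1000`).
#'
#' @param sets Named list (names = CLs) of data frames of scale vectors.
#' @return Named list of scale-vector tibbles, one per CL combination.
#' @export
intersect_across_cls <- function(sets) {
  if (length(sets) < 2L)
    .stop_input("need passing sets for at least two cycle lengths")
  cls <- sort(as.numeric(names(sets)))
  sets <- map(as.character(cls), function(nm)
    distinct(as_tibble(sets[[nm]])[.scale_cols]))
  names(sets) <- as.character(cls)
  out <- list()
  for (k in 2:length(cls)) {
    for (combo in utils::combn(as.character(cls), k, simplify = FALSE)) {
      acc <- sets[[combo[1L]]]
      for (nm in combo[-1L]) acc <- semi_join(acc, sets[[nm]], by = .scale_cols)
      out[[paste0("cl", paste(combo, collapse = "_"))]] <- acc
    }
  }
  out
}

#' Calibrate a swept population against physiological APD ranges
#'
#' Filters the sweep at every cycle length, intersects the passing sets
#' across CLs, and tabulates per-conductance level distributions among the
#' passers. The result supports [generics::tidy()] (per-CL and
#' per-intersection counts) and [generics::glance()].
#'
#' @inheritParams filter_physiological
#' @param grid The [grid_spec()] swept (recovered from the sweep attributes
#'   if absent) -- used for the level distributions.
#' @return An object of class `apopcal_calibration`: list with `per_cl`
#'   (named list of passing scale-vector tibbles), `intersections`,
#'   `counts` (tibble of set sizes), `levels` (level distributions) and
#'   `n_population`.
#' @export
#' @examples
#' g <- grid_spec(to = 1, Kr = c(0.7, 1, 1.3), Ks = 1, K1 = 1, CaL = 1, NaK = 1)
#' sw <- run_sweep(toy_cell_model(), g, cls = c(400, 600))
#' cal <- calibrate(sw, phys_ranges())
#' generics::tidy(cal)
calibrate <- function(records, ranges = phys_ranges(), grid = NULL) {
  ranges <- .validate_ranges(ranges)
  if (is.null(grid)) grid <- attr(records, "grid_spec")
  cls <- sort(intersect(unique(records$cl), ranges$cl))
  if (!length(cls)) .stop_input("no record CL has a physiological range")
  per_cl <- setNames(map(cls, function(cl)
    distinct(filter_physiological(records, ranges, cl)[.scale_cols])),
    as.character(cls))
  inter <- if (length(cls) >= 2L) intersect_across_cls(per_cl) else list()
  counts <- bind_rows(
    tibble(set = paste0("cl", names(per_cl)),
           n = map_dbl(per_cl, nrow)),
    tibble(set = names(inter), n = map_dbl(inter, nrow))
  )
  levels <- if (!is.null(grid)) {
    setNames(map(as.character(cls), function(nm)
      level_distribution(per_cl[[nm]], grid)), as.character(cls))
  } else NULL
  structure(list(per_cl = per_cl, intersections = inter, counts = counts,
                 levels = levels, ranges = ranges,
                 n_population = length(unique(
                   do.call(paste, as_tibble(records)[.scale_cols])))),
            class = "apopcal_calibration")
}

#' @export
print.apopcal_calibration <- function(x, ...) {
  cat("# Population calibration against physiological APD ranges\n")
  cat("Population size:", x$n_population, "parameter sets\n")
  print(x$counts)
  invisible(x)
}

#' Distribution of conductance levels among passing sets
#'
#' Counts how often each grid level of each conductance occurs in a set of
#' passing parameter sets. Levels absent from the set are reported with
#' zero counts; each axis's counts sum to the set size.
#'
#' @param passing A data frame of scale vectors.
#' @param grid The [grid_spec()] the vectors were drawn from.
#' @return A tibble with columns `conductance`, `level`, `n`.
#' @export
level_distribution <- function(passing, grid) {
  if (!inherits(grid, "grid_spec")) .stop_input("grid must be a grid_spec")
  passing <- if (nrow(as_tibble(passing)) > 0)
    validate_scales(passing) else as_tibble(passing)
  bind_rows(map(.axes, function(ax) {
    lv <- grid[[ax]]
    vals <- if (nrow(passing)) passing[[paste0("s_", ax)]] else numeric(0)
    idx <- .level_index(vals, lv, ax)
    tibble(conductance = ax, level = lv,
           n = as.numeric(tabulate(idx + 1L, nbins = length(lv))))
  }))
}

#' Extend physiological APD ranges
#'
#' Moderately widens the calibration ranges, used as the first step when a
#' conductance window yields no physiological parameter sets. Two readings
#' are available: scaling each bound away from zero (lower x (1 - frac),
#' upper x (1 + frac); the default) or widening the interval about its
#' midpoint by the same fraction of its half-width.
#'
#' @param ranges A [phys_ranges()] table.
#' @param frac Extension fraction (default 0.10).
#' @param about `"bounds"` (default) or `"midpoint"`.
#' @return A `phys_ranges` tibble. With `frac >= 1` and `about = "bounds"`
#'   lower bounds are clamped at 0 with a warning.
#' @export
#' @examples
#' extend_apd_ranges(phys_ranges())
extend_apd_ranges <- function(ranges, frac = 0.10,
                              about = c("bounds", "midpoint")) {
  about <- match.arg(about)
  ranges <- .validate_ranges(ranges)
  if (!is.numeric(frac) || length(frac) != 1L || frac < 0)
    .stop_input("frac must be a single non-negative fraction")
  out <- ranges
  clamped <- FALSE
  for (bm in c("apd50", "apd90")) {
    lo <- ranges[[paste0(bm, "_lo")]]
    hi <- ranges[[paste0(bm, "_hi")]]
    if (about == "bounds") {
      new_lo <- lo * (1 - frac)
      new_hi <- hi * (1 + frac)
    } else {
      mid <- (lo + hi) / 2
      half <- (hi - lo) / 2 * (1 + frac)
      new_lo <- mid - half
      new_hi <- mid + half
    }
    if (any(new_lo <= 0)) {
      clamped <- TRUE
      new_lo <- pmax(new_lo, 0)
    }
    out[[paste0(bm, "_lo")]] <- new_lo
    out[[paste0(bm, "_hi")]] <- new_hi
  }
  if (clamped)
    warn("extension pushed a lower bound to 0 or below; clamping to 0")
  .validate_ranges(out)
}

#' Propose an expanded conductance grid from near-miss passers
#'
#' Shifts each conductance's five-level window along the trend of the
#' parameter sets that pass an extended-range calibration: for each axis
#' the mean level-index offset of the passers from the window centre is
#' computed and the window is translated by `round(gain * offset)` steps of
#' size `step`. This is a concrete rendering of expanding each range "by
#' following the underlying trend"; the published expanded search window is
#' available verbatim as [expanded_mahajan_grid()].
#'
#' @param passing Non-empty data frame of passing scale vectors.
#' @param grid The [grid_spec()] they were drawn from.
#' @param step Level spacing of the shift, as a scale-factor increment.
#' @param gain Multiplier on the mean index offset before rounding.
#' @return A new `grid_spec` with each axis shifted.
#' @export
propose_expanded_grid <- function(passing, grid, step = 0.15, gain = 2) {
  if (!inherits(grid, "grid_spec")) .stop_input("grid must be a grid_spec")
  passing <- validate_scales(passing)
  if (nrow(passing) == 0L)
    .stop_input(paste0("no passing parameter sets to follow; extend the APD ",
                       "ranges first (see extend_apd_ranges)"))
  new_levels <- map(.axes, function(ax) {
    lv <- grid[[ax]]
    idx <- .level_index(passing[[paste0("s_", ax)]], lv, ax)
    centre <- (length(lv) - 1) / 2
    shift <- round(gain * (mean(idx) - centre))
    lv + shift * step
  })
  names(new_levels) <- .axes
  do.call(grid_spec, new_levels)
}

#' Histogram of a biomarker across the population
#'
#' Bins one biomarker over all records into fixed-width bins anchored at
#' zero, for population-level distribution summaries.
#'
#' @param records A sweep table.
#' @param biomarker One of [biomarker_names()].
#' @param bin_width Bin width in the biomarker's units.
#' @return A tibble with `bin_lo`, `bin_hi`, `n`; counts sum to the number
#'   of records with a defined value.
#' @export
biomarker_histogram <- function(records, biomarker, bin_width) {
  if (!biomarker %in% .biomarker_cols)
    .stop_input(paste0("unknown biomarker: ", biomarker))
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    .stop_input("bin_width must be a single positive number")
  x <- records[[biomarker]]
  x <- x[!is.na(x)]
  if (!length(x)) return(tibble(bin_lo = numeric(), bin_hi = numeric(),
                                n = numeric()))
  b <- floor(x / bin_width)
  tab <- table(b)
  lo <- as.numeric(names(tab)) * bin_width
  tibble(bin_lo = lo, bin_hi = lo + bin_width, n = as.numeric(tab))
}
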