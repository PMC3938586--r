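#' Normalised root-mean-square deviation between two signals
#'
#' \deqn{NRMSD = \frac{\sqrt{\frac{1}{N}\sum_j (M_{comb}(j) - M_{orig}(j))^2}}
#'   {M_{max} - M_{min}}}
#' where the normalising range is the maximum minus minimum of the
#' *reference* signal. The normalisation makes voltage and calcium
#' deviations dimensionless and directly comparable.
#'
#' @param candidate,reference Equal-length numeric vectors (or beat traces;
#'   for traces the Vm signal is compared -- see [beat_nrmsd()] for both
#'   signals).
#' @param ref_range Optional `c(min, max)` of the reference used for
#'   normalisation; defaults to the range of `reference`.
#' @return Non-negative dimensionless scalar; 0 iff the signals are
#'   identical.
#' @export
#' @examples
#' nrmsd(c(1, 1, 1, 1), c(0, 2, 0, 2))   # 0.5
nrmsd <- function(candidate, reference, ref_range = NULL) {
  if (is.data.frame(candidate)) candidate <- .as_beat(candidate)$vm_mV
  if (is.data.frame(reference)) reference <- .as_beat(reference)$vm_mV
  if (!is.numeric(candidate) || !is.numeric(reference))
    .stop_input("signals must be numeric")
  if (length(candidate) != length(reference))
    .stop_input("signals must have equal length")
  if (is.null(ref_range)) ref_range <- range(reference)
  span <- ref_range[2] - ref_range[1]
  if (span <= 0)
    .stop_input("reference signal has zero range; NRMSD undefined")
  sqrt(mean((candidate - reference)^2)) / span
}

#' Voltage and calcium NRMSD of one beat against a reference beat
#'
#' @param candidate,reference Beat traces on the same sample grid.
#' @return One-row tibble: `v_nrmsd`, `ca_nrmsd`, `combined`.
#' @export
beat_nrmsd <- function(candidate, reference) {
  cb <- .as_beat(candidate)
  rb <- .as_beat(reference)
  v <- nrmsd(cb$vm_mV, rb$vm_mV)
  ca <- if (!is.null(cb$cai_uM) && !is.null(rb$cai_uM))
    nrmsd(cb$cai_uM, rb$cai_uM) else NA_real_
  tibble(v_nrmsd = v, ca_nrmsd = ca,
         combined = if (is.na(ca)) v else v + ca)
}

#' NRMSD of every grid point against the control model
#'
#' Paces the model at every grid point and at the reference scale vector,
#' and computes the voltage and calcium NRMSD of each steady final beat
#' against the reference final beat (all on the same uniform sample grid).
#' Degenerate parameter sets get `NA` NRMSD.
#'
#' @inheritParams run_sweep
#' @param cl Single cycle length in ms.
#' @param reference Scale vector of the original (control) model.
#' @return A tibble with the scale columns, `v_nrmsd`, `ca_nrmsd` and
#'   `combined`.
#' @export
sweep_nrmsd <- function(model, grid, cl, reference = scale_vector(),
                        dt = 1, max_time = 1e6, steady_tol = 0.05) {
  pts <- if (is.data.frame(grid)) validate_scales(grid) else build_grid(grid)
  protocol <- pacing_protocol(cl, dt = dt, max_time = max_time,
                              steady_tol = steady_tol)
  ref <- run_paced(model, reference, protocol)
  if (ref$degenerate) .stop_input("reference parameter set is degenerate")
  rv <- ref$final$vm_mV
  rca <- ref$final$cai_uM
  v_span <- diff(range(rv))
  ca_span <- if (!is.null(rca)) diff(range(rca)) else NA_real_
  n <- nrow(pts)
  S <- as.matrix(pts[.scale_cols])
  vn <- can <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- S[i, ]
    names(s) <- .axes
    pr <- run_paced(model, s, protocol)
    if (pr$degenerate) next
    vn[i] <- sqrt(mean((pr$final$vm_mV - rv)^2)) / v_span
    if (!is.null(rca) && !is.null(pr$final$cai_uM))
      can[i] <- sqrt(mean((pr$final$cai_uM - rca)^2)) / ca_span
  }
  out <- pts
  out$v_nrmsd <- vn
  out$ca_nrmsd <- can
  out$combined <- ifelse(is.na(can), vn, vn + can)
  out
}

.selection <- function(set, method, threshold, target_count, extra = list()) {
  structure(c(list(set = distinct(as_tibble(set)[.scale_cols]),
                   method = method, threshold = threshold,
                   count = nrow(distinct(as_tibble(set)[.scale_cols])),
                   target_count = target_count), extra),
            class = "apopcal_selection")
}

#' @export
print.apopcal_selection <- function(x, ...) {
  cat("# Parameter-set selection (", x$method, "): ", x$count,
      " sets (target ", x$target_count, "), threshold ",
      format(x$threshold), "\n", sep = "")
  invisible(x)
}

#' Select the parameter sets closest to the reference by NRMSD
#'
#' Ranks parameter sets by combined voltage-plus-calcium NRMSD (ascending)
#' and keeps the `target_count` smallest. Ties at the cutoff are broken by
#' the canonical scale-tuple order (lexicographic over the axis order), so
#' the selection is deterministic. `NA` scores rank last.
#'
#' @param nrmsd_tbl Output of [sweep_nrmsd()].
#' @param target_count Number of sets to keep (default 250).
#' @return An `apopcal_selection`: list with `set` (scale-vector tibble),
#'   `method`, `threshold` (combined NRMSD at the cutoff), `count`.
#' @export
select_by_nrmsd <- function(nrmsd_tbl, target_count = 250) {
  if (!all(c(.scale_cols, "combined") %in% names(nrmsd_tbl)))
    .stop_input("nrmsd_tbl must come from sweep_nrmsd()")
  k <- min(target_count, sum(!is.na(nrmsd_tbl$combined)))
  ord <- do.call(order, c(list(nrmsd_tbl$combined),
                          as.list(nrmsd_tbl[.scale_cols])))
  sel <- nrmsd_tbl[ord[seq_len(k)], , drop = FALSE]
  .selection(sel, "nrmsd",
             threshold = if (k) max(sel$combined) else NA_real_,
             target_count = target_count)
}

#' Select parameter sets by biomarker agreement with the reference
#'
#' A parameter set matches at tolerance `theta` (in percent) iff, for every
#' biomarker in the combination, its relative difference from the reference
#' value is at most `theta` percent. The tolerance is swept upward from 0
#' in steps of `theta_step` and the value whose match count is closest to
#' `target_count` is kept (ties resolved toward the smaller, stricter
#' tolerance). Records with an undefined biomarker in the combination never
#' match.
#'
#' @param records A sweep table at one cycle length.
#' @param reference_record One-row record of the reference (control) model,
#'   e.g. the control row of the same sweep.
#' @param combination Character vector of biomarker names (subset of
#'   [biomarker_names()]).
#' @param target_count Desired selection size (default 250).
#' @param theta_step Sweep granularity in percentage points (default 0.1).
#' @param theta_max Upper end of the sweep (default 100).
#' @return An `apopcal_selection` with `threshold` = the chosen theta.
#' @export
select_by_biomarkers <- function(records, reference_record, combination,
                                 target_count = 250, theta_step = 0.1,
                                 theta_max = 100) {
  bad <- setdiff(combination, .biomarker_cols)
  if (length(bad) || !length(combination))
    .stop_input(paste0("combination must be a non-empty subset of biomarker ",
                       "names; unknown: ", paste(bad, collapse = ", ")))
  for (bm in combination) {
    ref <- reference_record[[bm]]
    if (is.null(ref) || length(ref) != 1L || is.na(ref))
      .stop_input(paste0("reference record has no value for ", bm))
    if (ref == 0)
      .stop_input(paste0("reference biomarker ", bm,
                         " is zero; relative difference undefined"))
  }
  m <- rep(0, nrow(records))
  for (bm in combination) {
    ref <- reference_record[[bm]]
    rel <- 100 * abs(records[[bm]] - ref) / abs(ref)
    rel[is.na(rel)] <- Inf
    m <- pmax(m, rel)
  }
  thetas <- seq(0, theta_max, by = theta_step)
  counts <- findInterval(thetas, sort(m[is.finite(m)]))
  # count at theta = number of m <= theta; findInterval gives <=, matching
  # the inclusive match rule
  best <- which.min(abs(counts - target_count))   # earliest tie -> smaller theta
  theta <- thetas[best]
  sel <- records[m <= theta, , drop = FALSE]
  .selection(sel, "biomarkers", threshold = theta,
             target_count = target_count,
             extra = list(combination = combination))
}

#' Percentage overlap of two selections
#'
#' `100 * |A intersect B| / |B|`, with the denominator taken from the
#' NRMSD-selected (gold-standard) set by default. Alternative denominators
#' (`"a"`, `"union"`, `"mean"` set size) are available because the
#' published definition of percentage overlap is ambiguous.
#'
#' @param a,b `apopcal_selection` objects (or scale-vector data frames);
#'   conventionally `a` is the biomarker selection and `b` the NRMSD one.
#' @param denominator `"b"` (default), `"a"`, `"union"` or `"mean"`.
#' @return Percentage in `[0, 100]`.
#' @export
percent_overlap <- function(a, b, denominator = c("b", "a", "union", "mean")) {
  denominator <- match.arg(denominator)
  set_a <- if (inherits(a, "apopcal_selection")) a$set else
    distinct(validate_scales(a)[.scale_cols])
  set_b <- if (inherits(b, "apopcal_selection")) b$set else
    distinct(validate_scales(b)[.scale_cols])
  n_int <- nrow(semi_join(set_a, set_b, by = .scale_cols))
  den <- switch(denominator,
                b = nrow(set_b),
                a = nrow(set_a),
                union = nrow(set_a) + nrow(set_b) - n_int,
                mean = (nrow(set_a) + nrow(set_b)) / 2)
  if (den == 0) return(0)
  100 * n_int / den
}

#' Default biomarker combinations for goodness-of-fit ranking
#'
#' A curated list of biomarker combinations spanning voltage-only and
#' voltage-plus-calcium information, of the kind compared when asking which
#' cheap biomarker combination best reproduces the full-waveform NRMSD
#' selection.
#'
#' @return Named list of character vectors.
#' @export
default_biomarker_combinations <- function() {
  combos <- list(
    c("apd50", "apd90", "cat_amp"),
    c("apd50", "apd90"),
    c("apd90", "cat_amp"),
    c("apd50", "cat_amp"),
    c("apd50", "apd90", "ctd50", "ctd90"),
    c("apd50", "apd90", "ca_dia", "ca_sys"),
    c("apd50", "apd90", "cat_amp", "ctd90"),
    c("cat_amp", "ctd50", "ctd90"),
    c("apd90"),
    c("apd50"),
    c("cat_amp"),
    c("dvdt_max", "apd50", "apd90"),
    c("v_rest", "v_plat", "apd50", "apd90")
  )
  setNames(combos, map_chr(combos, paste, collapse = "+"))
}

#' All non-empty biomarker combinations
#'
#' @param biomarkers Biomarker names to combine (default all ten).
#' @param max_size Largest combination size to enumerate.
#' @return Named list of character vectors.
#' @export
all_biomarker_combinations <- function(biomarkers = biomarker_names(),
                                       max_size = length(biomarkers)) {
  combos <- list()
  for (k in seq_len(min(max_size, length(biomarkers))))
    combos <- c(combos, utils::combn(biomarkers, k, simplify = FALSE))
  setNames(combos, map_chr(combos, paste, collapse = "+"))
}

#' Rank biomarker combinations by overlap with the NRMSD selection
#'
#' For each candidate combination, selects ~`target_count` parameter sets
#' by biomarker agreement with the reference and measures the percentage
#' overlap with the NRMSD-based selection. Returns the combinations ranked
#' by overlap (descending), ties broken by combination name.
#'
#' @inheritParams select_by_biomarkers
#' @param nrmsd_selection An [select_by_nrmsd()] result (or a
#'   [sweep_nrmsd()] table, which is selected internally).
#' @param combinations Named list of biomarker-name vectors; defaults to
#'   [default_biomarker_combinations()].
#' @param denominator Passed to [percent_overlap()].
#' @return A tibble: `combination`, `n_biomarkers`, `theta`, `n_selected`,
#'   `overlap_pct`.
#' @export
rank_combinations <- function(records, nrmsd_selection, reference_record,
                              combinations = default_biomarker_combinations(),
                              target_count = 250, theta_step = 0.1,
                              denominator = "b") {
  if (!inherits(nrmsd_selection, "apopcal_selection"))
    nrmsd_selection <- select_by_nrmsd(nrmsd_selection, target_count)
  rows <- imap(combinations, function(combo, nm) {
    sel <- select_by_biomarkers(records, reference_record, combo,
                                target_count = target_count,
                                theta_step = theta_step)
    tibble(combination = nm, n_biomarkers = length(combo),
           theta = sel$threshold, n_selected = sel$count,
           overlap_pct = percent_overlap(sel, nrmsd_selection,
                                         denominator = denominator))
  })
  out <- bind_rows(rows)
  out[order(-out$overlap_pct, out$combination), , drop = FALSE]
}
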