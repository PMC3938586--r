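# On-disk sweep store format version. Bump when the layout changes.
.store_version <- "1"

#' Save and load a sweep store
#'
#' A sweep store is a directory holding the biomarker table as CSV
#' (`biomarkers.csv`) plus a JSON metadata sidecar (`meta.json`: format
#' version, cycle lengths, sampling interval, grid levels). The round trip
#' is lossless for the table (numbers are written in full precision) and
#' byte-stable: saving a loaded store reproduces identical files.
#'
#' @param records A sweep table (see [run_sweep()]).
#' @param path Store directory (created if needed).
#' @return `save_sweep()`: `path`, invisibly. `load_sweep()`: the sweep
#'   table with its attributes restored.
#' @export
save_sweep <- function(records, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  grid <- attr(records, "grid_spec")
  meta <- list(
    format = "apopcal-sweep",
    version = .store_version,
    cls = attr(records, "cls"),
    dt = attr(records, "dt"),
    grid = if (!is.null(grid)) unclass(grid)
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_table_csv(as_tibble(records), file.path(path, "biomarkers.csv"))
  invisible(path)
}

# Byte-stable CSV: doubles are written as %.17g, which re-parses to the
# identical double and re-formats to the identical string, so
# save -> load -> save reproduces the file exactly.
.write_table_csv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    col <- out[[nm]]
    if (is.double(col)) {
      s <- sprintf("%.17g", col)
      s[is.na(col)] <- "NA"
      out[[nm]] <- s
    }
  }
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_sweep
#' @export
load_sweep <- function(path) {
  meta_path <- file.path(path, "meta.json")
  csv_path <- file.path(path, "biomarkers.csv")
  if (!file.exists(meta_path) || !file.exists(csv_path))
    .stop_input(paste0(path, " is not a sweep store"))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format, "apopcal-sweep") ||
      !identical(as.character(meta$version), .store_version))
    abort(paste0("sweep store version mismatch: found ",
                 meta$version %||% "<none>", ", expected ", .store_version),
          class = "apopcal_store_version")
  out <- as_tibble(utils::read.csv(csv_path))
  for (nm in intersect(c("steady", "degenerate", "v_plat_fallback"),
                       names(out)))
    out[[nm]] <- as.logical(out[[nm]])
  for (nm in intersect(c(.scale_cols, "cl", .biomarker_cols), names(out)))
    out[[nm]] <- as.numeric(out[[nm]])
  if (!is.null(meta$grid))
    attr(out, "grid_spec") <- do.call(grid_spec,
                                      lapply(as.list(meta$grid), as.numeric))
  attr(out, "cls") <- meta$cls
  attr(out, "dt") <- meta$dt
  class(out) <- c("sweep_result", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a beat trace as CSV
#'
#' Columns `time_ms`, `vm_mV`, `cai_uM`.
#'
#' @param trace A beat trace.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_beat_csv <- function(trace, path) {
  b <- .as_beat(trace)
  readr::write_csv(tibble(time_ms = b$time_ms, vm_mV = b$vm_mV,
                          cai_uM = b$cai_uM %||% NA_real_), path)
  invisible(path)
}

#' Run configuration
#'
#' Bundles everything needed to reproduce a pipeline run: grid preset or
#' explicit levels, cycle lengths, model choice, pacing settings, range
#' preset, worker count and toy-model constant overrides. Round-trips
#' losslessly through YAML via [write_run_config()] / [read_run_config()];
#' the `toy_model:` block of the file overrides individual model constants.
#'
#' @param grid Grid preset name or a [grid_spec()].
#' @param cls Cycle lengths in ms.
#' @param model Model name (`"toy"`).
#' @param dt,max_time,steady_tol Pacing settings (see [pacing_protocol()]).
#' @param ranges Range preset name (`"table1"`).
#' @param workers Worker count for sweeps.
#' @param seed Reserved; the pipeline itself is deterministic.
#' @param toy_model Named list of [toy_constants()] overrides.
#' @return An object of class `run_config`.
#' @export
run_config <- function(grid = "default", cls = c(400, 600, 1000),
                       model = "toy", dt = 1, max_time = 1e6,
                       steady_tol = 0.05, ranges = "table1", workers = 1,
                       seed = NULL, toy_model = NULL) {
  structure(list(grid = grid, cls = cls, model = model, dt = dt,
                 max_time = max_time, steady_tol = steady_tol,
                 ranges = ranges, workers = workers, seed = seed,
                 toy_model = toy_model),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  if (inherits(x$grid, "grid_spec")) x$grid <- unclass(x$grid)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.list(x$grid)) x$grid <- do.call(grid_spec, x$grid)
  do.call(run_config, x)
}

# resolve config fields into live objects
.config_grid <- function(cfg) {
  if (inherits(cfg$grid, "grid_spec")) cfg$grid else grid_preset(cfg$grid)
}
.config_model <- function(cfg) {
  if (!identical(cfg$model, "toy"))
    .stop_input(paste0("unknown model '", cfg$model,
                       "'; external models plug in via the cell-model ",
                       "contract (see ?toy_cell_model)"))
  toy_cell_model(toy_constants(overrides = cfg$toy_model))
}

#' Summarise a pipeline run as a report
#'
#' Collects the headline quantities of a run -- population size, per-CL and
#' intersection calibration counts (in the layout of a per-model results
#' table), optionally the biomarker-combination ranking and the optimal
#' stack orders -- into a JSON-serialisable list.
#'
#' @param records A sweep table.
#' @param calibration An [calibrate()] result.
#' @param fitrank Optional [rank_combinations()] table.
#' @param cbdr Optional named list of [optimize_stack_order()] fits.
#' @return A list of class `apopcal_report`.
#' @export
pipeline_report <- function(records, calibration, fitrank = NULL,
                            cbdr = NULL) {
  counts <- setNames(as.list(calibration$counts$n), calibration$counts$set)
  rep <- list(
    population = list(
      n_parameter_sets = calibration$n_population,
      n_records = nrow(records),
      cls = sort(unique(records$cl)),
      n_not_steady = sum(!records$steady),
      n_degenerate = sum(records$degenerate)
    ),
    physiological_counts = counts
  )
  if (!is.null(fitrank))
    rep$biomarker_combination_ranking <- map(seq_len(nrow(fitrank)),
      function(i) as.list(fitrank[i, ]))
  if (!is.null(cbdr))
    rep$stack_orders <- imap(cbdr, function(fit, nm)
      list(order = paste(sprintf("(%s,%s)",
             fit$order[c("x_low", "x_mid", "x_high")],
             fit$order[c("y_low", "y_mid", "y_high")]), collapse = " "),
           cost = fit$cost))
  structure(rep, class = c("apopcal_report", "list"))
}

#' @rdname pipeline_report
#' @param report An `apopcal_report`.
#' @param path Output JSON file.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
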