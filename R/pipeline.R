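#' Process one leaf from balance log to report row
#'
#' Runs the full EFM chain on a single leaf: (balance log ->) weight to
#' flow by rolling-window slopes -> background-evaporation correction ->
#' area normalization -> penalized segmentation -> sub-minute segment
#' merging -> steadiness classification -> (if steady) E extraction,
#' K_leaf computation and viscosity normalization -> one report row.
#' Non-steady leaves still yield a report row, carrying their curve class
#' and NA in the E/K_leaf columns.
#'
#' @param x A balance-log path (read via [read_balance_log()]) or a
#'   [flow_trace()]. A trace with a weight series is converted to flow; a
#'   trace that already carries area-normalized flow is used as-is.
#' @param leaf A [leaf_record()] with the leaf's metadata; `psi_final_MPa`
#'   must be present (non-NA) to compute K_leaf.
#' @param leaf_id Identifier used in the report and raw-flow table.
#' @param config A [segmentation_config()].
#' @param evap An [evaporation_setting()].
#' @param window_s Rolling slope window for [weight_to_flow()].
#' @param raw_flow_path If non-NULL, the area-normalized raw flow table is
#'   conserved there via [write_raw_flow_table()] and referenced from the
#'   report row.
#' @param ... Extra arguments passed to [read_balance_log()] when `x` is a
#'   path.
#' @return An object of class `efm_result`: list with `trace` (processed),
#'   `segments` (post-merge), `steadiness`, `kleaf` (NULL when
#'   non-steady), `report` (a [report_record()]).
#' @examples
#' sim <- simulate_flow(trace_spec(seed = 7))
#' leaf <- leaf_record("Oryza sativa", leaf_area_m2 = 2.5e-3,
#'                     psi_final_MPa = -0.31)
#' res <- process_leaf(sim$trace, leaf, leaf_id = "leaf1")
#' res$report$K_leaf_mmol_m2_s_MPa
#' @export
process_leaf <- function(x, leaf, leaf_id = "leaf",
                         config = segmentation_config(),
                         evap = evaporation_setting(), window_s = 60,
                         raw_flow_path = NULL, ...) {
  validate_leaf_record(leaf)
  trace <- if (is.character(x)) read_balance_log(x, ...) else x
  stopifnot(inherits(trace, "flow_trace"))
  if (!.has_flow(trace)) {
    trace <- weight_to_flow(trace, window_s = window_s)
    trace <- correct_evaporation(trace, evap)
    trace <- area_normalize(trace, leaf$leaf_area_m2)
  } else {
    .require_flow(trace, "mmol m-2 s-1")
  }
  segments <- merge_invalid_segments(dp_segment(trace, config), trace, config)
  steadiness <- classify_steadiness(segments, trace, config)
  kleaf <- NULL
  if (steadiness$steady) {
    if (is.na(leaf$psi_final_MPa))
      stop(sprintf("leaf '%s': missing required field 'psi_final_MPa'",
                   leaf_id), call. = FALSE)
    E <- extract_E(trace, steadiness)
    kleaf <- compute_kleaf(E, leaf$psi_final_MPa, leaf$T_leaf_C)
  }
  uri <- NA_character_
  if (!is.null(raw_flow_path)) {
    write_raw_flow_table(trace, leaf_id, raw_flow_path)
    uri <- raw_flow_path
  }
  structure(list(trace = trace, segments = segments,
                 steadiness = steadiness, kleaf = kleaf,
                 report = report_record(leaf, steadiness, kleaf, leaf_id,
                                        raw_flow_uri = uri)),
            class = "efm_result")
}

#' @export
print.efm_result <- function(x, ...) {
  print(x$steadiness)
  if (!is.null(x$kleaf)) print(x$kleaf)
  invisible(x)
}

#' Process a batch of leaves from a manifest
#'
#' One leaf per balance log. The manifest (a `data.frame` or a CSV path)
#' needs one row per leaf with at least `leaf_id`, `log_path`, `species`,
#' `leaf_area_m2` and `psi_final_MPa`; any further [leaf_record()] fields
#' (`psi_initial_MPa`, `T_leaf_C`, `PARa_umol_m2_s`, `T_air_C`,
#' `airflow_m_s`, `sampling_time`, `storage`, `degassed`,
#' `height_offset_cm`) are picked up when present. Writes the standardized
#' report (with the thresholds used echoed in its footer) plus one
#' conserved raw-flow table per leaf.
#'
#' @param manifest `data.frame` or CSV path.
#' @param output_dir Directory for `report.csv` and `rawflow_<id>.csv`.
#' @param config,evap,window_s As in [process_leaf()].
#' @param time_col,weight_col Column names inside each balance log.
#' @return Invisibly, the list of `efm_result`s (named by leaf_id).
#' @export
process_batch <- function(manifest, output_dir,
                          config = segmentation_config(),
                          evap = evaporation_setting(), window_s = 60,
                          time_col = "time_s", weight_col = "weight_g") {
  if (is.character(manifest))
    manifest <- utils::read.table(manifest, header = TRUE, sep = ",",
                                  stringsAsFactors = FALSE)
  for (col in c("leaf_id", "log_path", "species", "leaf_area_m2",
                "psi_final_MPa"))
    if (!col %in% names(manifest))
      stop(sprintf("manifest is missing required column '%s'", col),
           call. = FALSE)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  records <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    id <- as.character(row$leaf_id)
    extra <- intersect(names(manifest),
                       c("psi_initial_MPa", "T_leaf_C", "PARa_umol_m2_s",
                         "T_air_C", "airflow_m_s", "sampling_time",
                         "storage", "degassed", "height_offset_cm"))
    leaf <- do.call(leaf_record,
                    c(list(species = row$species,
                           leaf_area_m2 = row$leaf_area_m2,
                           psi_final_MPa = row$psi_final_MPa),
                      as.list(row[extra])))
    res <- tryCatch(
      process_leaf(row$log_path, leaf, leaf_id = id, config = config,
                   evap = evap, window_s = window_s,
                   raw_flow_path = file.path(output_dir,
                                             paste0("rawflow_", id, ".csv")),
                   time_col = time_col, weight_col = weight_col),
      error = function(e)
        stop(sprintf("leaf '%s' failed during processing: %s", id,
                     conditionMessage(e)), call. = FALSE))
    results[[id]] <- res
    records[[id]] <- res$report
  }
  write_report(unname(records), file.path(output_dir, "report.csv"),
               thresholds = list(
                 penalty_P = attr(results[[1]]$segments, "penalty_P"),
                 penalty_scale = config$penalty_scale,
                 min_seg_points = config$min_seg_points,
                 merge_window_s = config$merge_window_s,
                 steady_min_duration_s = config$steady_min_duration_s,
                 steady_window_s = config$steady_window_s,
                 slope_alpha = config$slope_alpha,
                 slope_window_s = window_s,
                 blank_rate_mmol_s = evap$blank_rate_mmol_s,
                 evaporation_prevention = evap$prevention))
  invisible(results)
}

#' Read a key = value run configuration file
#'
#' Plain-text configuration (`key = value` per line, `#` comments) mapping
#' onto [segmentation_config()], [evaporation_setting()] and the flow
#' window. Unknown keys error so typos cannot silently fall back to
#' defaults.
#'
#' @param path Config file path.
#' @return List with `config` (a [segmentation_config()]), `evap` (an
#'   [evaporation_setting()]) and `window_s`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad))
    stop("malformed config line: ", lines[bad][1], call. = FALSE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  seg_keys <- c("penalty_P", "penalty_scale", "min_seg_points",
                "merge_window_s", "steady_min_duration_s",
                "steady_window_s", "slope_alpha")
  other <- setdiff(names(vals),
                   c(seg_keys, "blank_rate_mmol_s", "prevention", "window_s"))
  if (length(other))
    stop("unknown config key(s): ", paste(other, collapse = ", "),
         call. = FALSE)
  seg <- lapply(vals[intersect(names(vals), seg_keys)], as.numeric)
  list(config = do.call(segmentation_config, seg),
       evap = evaporation_setting(
         blank_rate_mmol_s =
           if ("blank_rate_mmol_s" %in% names(vals))
             as.numeric(vals[["blank_rate_mmol_s"]]) else 0,
         prevention = if ("prevention" %in% names(vals))
           vals[["prevention"]] else "none"),
       window_s = if ("window_s" %in% names(vals))
         as.numeric(vals[["window_s"]]) else 60)
}
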