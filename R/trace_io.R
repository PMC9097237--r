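#' Read a balance log into a flow trace
#'
#' Parses a delimited text log written by balance software during an EFM
#' run. The log must contain a time column and a weight and/or flow column.
#' Time is accepted either as elapsed seconds or as wall-clock timestamps
#' (anything [as.POSIXct()] understands), which are converted to elapsed
#' seconds from the first sample. Rows with unparseable numerics are dropped
#' (with a warning giving the count), and duplicated timestamps are
#' collapsed by averaging their values (with a warning).
#'
#' @param path Path to a delimited text file with a header row.
#' @param time_col,weight_col,flow_col Column names in the file; set
#'   `flow_col` when the log already contains flow (e.g. a raw-flow table
#'   written by [write_raw_flow_table()]). At least one of `weight_col`,
#'   `flow_col` must be present in the file.
#' @param flow_units Units of the flow column, if any.
#' @param sep Field separator (default comma).
#' @param sampling_interval_s Nominal logging interval; default `NULL`
#'   infers the median time step.
#' @return A [flow_trace()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("t,w", "0,100.000", "3,99.998", "6,99.996"), f)
#' read_balance_log(f, time_col = "t", weight_col = "w")
#' @export
read_balance_log <- function(path, time_col = "time_s",
                             weight_col = "weight_g", flow_col = NULL,
                             flow_units = "mmol m-2 s-1", sep = ",",
                             sampling_interval_s = NULL) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#", quote = "\"")
  if (!time_col %in% names(raw))
    stop(sprintf("format error: time column '%s' not found in %s",
                 time_col, path), call. = FALSE)
  has_w <- weight_col %in% names(raw)
  has_f <- !is.null(flow_col) && flow_col %in% names(raw)
  if (!has_w && !has_f)
    stop(sprintf("format error: neither weight column '%s' nor a flow column found in %s",
                 weight_col, path), call. = FALSE)

  tm <- .parse_time(raw[[time_col]])
  w <- if (has_w) suppressWarnings(as.numeric(raw[[weight_col]])) else NULL
  fl <- if (has_f) suppressWarnings(as.numeric(raw[[flow_col]])) else NULL

  bad <- is.na(tm)
  if (has_w) bad <- bad | is.na(w)
  if (has_f) bad <- bad | is.na(fl)
  if (any(bad)) {
    warning(sprintf("dropped %d row(s) with unparseable numerics", sum(bad)),
            call. = FALSE)
    tm <- tm[!bad]
    if (has_w) w <- w[!bad]
    if (has_f) fl <- fl[!bad]
  }
  if (length(tm) < 2L)
    stop("empty trace: fewer than 2 valid rows", call. = FALSE)

  o <- order(tm)
  tm <- tm[o]
  if (has_w) w <- w[o]
  if (has_f) fl <- fl[o]
  if (anyDuplicated(tm)) {
    ndup <- length(tm) - length(unique(tm))
    warning(sprintf("collapsed %d duplicated timestamp(s) by mean", ndup),
            call. = FALSE)
    key <- factor(tm, levels = unique(tm))
    if (has_w) w <- as.numeric(tapply(w, key, mean))
    if (has_f) fl <- as.numeric(tapply(fl, key, mean))
    tm <- unique(tm)
  }
  if (is.null(sampling_interval_s))
    sampling_interval_s <- stats::median(diff(tm))
  flow_trace(tm, weight_g = w, flow = fl, flow_units = flow_units,
             sampling_interval_s = sampling_interval_s)
}

# elapsed seconds from numeric or wall-clock time column
.parse_time <- function(x) {
  tm <- suppressWarnings(as.numeric(x))
  if (all(is.na(tm))) {
    ts <- as.POSIXct(as.character(x), tz = "UTC",
                     tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
                                    "%H:%M:%OS", "%d/%m/%Y %H:%M:%OS"))
    if (all(is.na(ts)))
      stop("format error: time column is neither numeric nor a recognizable timestamp",
           call. = FALSE)
    tm <- as.numeric(ts) - as.numeric(ts[which(!is.na(ts))[1]])
  }
  tm
}

#' Write the raw flow table for a leaf
#'
#' Long-format conservation of the raw flow-rate-versus-time data, one row
#' per sample (`leaf_id`, `time_s`, `flow_mmol_m2_s`). Keeping this table
#' next to the summary report lets later readers re-examine whether flow
#' truly stabilized. [read_balance_log()] on the output (with
#' `flow_col = "flow_mmol_m2_s"`) reconstructs the series; values are
#' written with 15 significant digits.
#'
#' @param trace A [flow_trace()] with computed, area-normalized flow.
#' @param leaf_id Non-empty identifier for the leaf.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_raw_flow_table <- function(trace, leaf_id, path) {
  .require_flow(trace, "mmol m-2 s-1")
  if (!is.character(leaf_id) || length(leaf_id) != 1L || !nzchar(leaf_id) ||
      is.na(leaf_id))
    stop("validation error: leaf_id must be a non-empty string", call. = FALSE)
  df <- data.frame(leaf_id = leaf_id,
                   time_s = format(trace$time_s, digits = 15, trim = TRUE),
                   flow_mmol_m2_s = format(trace$flow, digits = 15, trim = TRUE),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Leaf and environment metadata for one EFM measurement
#'
#' Collects everything the measurement report needs about the leaf and its
#' environment: identity, area, water potentials before/after the run, leaf
#' and air temperature, radiation, airflow, plus sampling/storage/degassing
#' provenance and the height offset between the water surface and the leaf.
#'
#' @param species Species (and optionally genotype) name.
#' @param leaf_area_m2 One-sided leaf area (m^2), > 0.
#' @param psi_final_MPa Leaf water potential after the run (MPa, <= 0; must
#'   be < 0 for a defined K_leaf).
#' @param psi_initial_MPa Leaf water potential before the run (MPa, <= 0).
#' @param T_leaf_C Leaf temperature (deg C) during the run.
#' @param PARa_umol_m2_s Photosynthetically active radiation at the leaf
#'   surface (umol m-2 s-1).
#' @param T_air_C Air temperature (deg C).
#' @param airflow_m_s Airflow speed around the leaf (m s-1).
#' @param sampling_time Free-text sampling time (e.g. "05:30 previous night").
#' @param storage Free-text storage description (e.g. "overnight, sterile
#'   ultra-pure water").
#' @param degassed Logical: was the reservoir water degassed?
#' @param height_offset_cm Signed height of the water surface relative to
#'   the leaf (cm; negative = water below leaf).
#' @return An object of class `leaf_record` (named list).
#' @export
leaf_record <- function(species, leaf_area_m2, psi_final_MPa,
                        psi_initial_MPa = NA_real_, T_leaf_C = 25,
                        PARa_umol_m2_s = NA_real_, T_air_C = NA_real_,
                        airflow_m_s = NA_real_, sampling_time = NA_character_,
                        storage = NA_character_, degassed = NA,
                        height_offset_cm = 0) {
  rec <- list(species = as.character(species),
              leaf_area_m2 = as.numeric(leaf_area_m2),
              psi_initial_MPa = as.numeric(psi_initial_MPa),
              psi_final_MPa = as.numeric(psi_final_MPa),
              T_leaf_C = as.numeric(T_leaf_C),
              PARa_umol_m2_s = as.numeric(PARa_umol_m2_s),
              T_air_C = as.numeric(T_air_C),
              airflow_m_s = as.numeric(airflow_m_s),
              sampling_time = as.character(sampling_time),
              storage = as.character(storage),
              degassed = as.logical(degassed),
              height_offset_cm = as.numeric(height_offset_cm))
  class(rec) <- "leaf_record"
  validate_leaf_record(rec)
  rec
}

#' @rdname leaf_record
#' @param rec A `leaf_record`.
#' @export
validate_leaf_record <- function(rec) {
  stopifnot(inherits(rec, "leaf_record"))
  if (!is.finite(rec$leaf_area_m2) || rec$leaf_area_m2 <= 0)
    stop("validation error in field 'leaf_area_m2': must be > 0", call. = FALSE)
  for (f in c("psi_initial_MPa", "psi_final_MPa"))
    if (!is.na(rec[[f]]) && rec[[f]] > 0)
      stop(sprintf("validation error in field '%s': water potential must be <= 0 MPa", f),
           call. = FALSE)
  invisible(rec)
}

# fixed, unit-annotated column order of the measurement report
.report_columns <- c(
  "leaf_id", "species", "leaf_area_m2", "psi_initial_MPa", "psi_final_MPa",
  "T_leaf_C", "PARa_umol_m2_s", "T_air_C", "airflow_m_s", "sampling_time",
  "storage", "degassed", "height_offset_cm", "E_mmol_m2_s",
  "K_leaf_mmol_m2_s_MPa", "K_leaf25_mmol_m2_s_MPa", "viscosity_factor",
  "steadiness_class", "last_segment_duration_s", "slope_p_value",
  "raw_flow_uri")

#' Assemble one report row for a measured leaf
#'
#' Combines leaf metadata, the steadiness verdict and (for steady runs) the
#' K_leaf result into a single tidy row of the standardized measurement
#' report. A leaf whose trace was classified non-steady (class A, B or C)
#' carries `NA` in the E and K_leaf columns: a conductance computed from a
#' non-steady flow is not reported.
#'
#' @param leaf A [leaf_record()].
#' @param steadiness A `steadiness_result` from [classify_steadiness()].
#' @param kleaf A `kleaf_result` from [compute_kleaf()]; required when
#'   steady, forbidden otherwise.
#' @param leaf_id Identifier used to link this row to its raw flow table.
#' @param raw_flow_uri Pointer (path or URI) to the conserved raw flow table.
#' @return A one-row `data.frame` of class `report_record`.
#' @export
report_record <- function(leaf, steadiness, kleaf = NULL, leaf_id,
                          raw_flow_uri = NA_character_) {
  validate_leaf_record(leaf)
  stopifnot(inherits(steadiness, "steadiness_result"))
  if (steadiness$steady && is.null(kleaf))
    stop("steady leaf requires a kleaf result", call. = FALSE)
  if (!steadiness$steady && !is.null(kleaf))
    stop("validation error in field 'K_leaf_mmol_m2_s_MPa': non-steady leaf must not carry a K_leaf value",
         call. = FALSE)
  row <- data.frame(
    leaf_id = as.character(leaf_id),
    species = leaf$species,
    leaf_area_m2 = leaf$leaf_area_m2,
    psi_initial_MPa = leaf$psi_initial_MPa,
    psi_final_MPa = leaf$psi_final_MPa,
    T_leaf_C = leaf$T_leaf_C,
    PARa_umol_m2_s = leaf$PARa_umol_m2_s,
    T_air_C = leaf$T_air_C,
    airflow_m_s = leaf$airflow_m_s,
    sampling_time = leaf$sampling_time,
    storage = leaf$storage,
    degassed = leaf$degassed,
    height_offset_cm = leaf$height_offset_cm,
    E_mmol_m2_s = if (is.null(kleaf)) NA_real_ else kleaf$E_mmol_m2_s,
    K_leaf_mmol_m2_s_MPa = if (is.null(kleaf)) NA_real_ else kleaf$K_raw,
    K_leaf25_mmol_m2_s_MPa = if (is.null(kleaf)) NA_real_ else kleaf$K_25,
    viscosity_factor = if (is.null(kleaf)) NA_real_ else kleaf$viscosity_factor,
    steadiness_class = steadiness$curve_class,
    last_segment_duration_s = steadiness$last_segment_duration_s,
    slope_p_value = steadiness$slope_p_value,
    raw_flow_uri = as.character(raw_flow_uri),
    stringsAsFactors = FALSE)
  class(row) <- c("report_record", "data.frame")
  row
}

.validate_report_row <- function(row) {
  for (col in .report_columns)
    if (!col %in% names(row))
      stop(sprintf("validation error in field '%s': missing from report record", col),
           call. = FALSE)
  if (!row$steadiness_class %in% c("A", "B", "C", "D"))
    stop("validation error in field 'steadiness_class': must be A, B, C or D",
         call. = FALSE)
  if (row$steadiness_class != "D" &&
      (!is.na(row$K_leaf_mmol_m2_s_MPa) || !is.na(row$K_leaf25_mmol_m2_s_MPa)))
    stop("validation error in field 'K_leaf_mmol_m2_s_MPa': non-steady leaf must not carry a K_leaf value",
         call. = FALSE)
  if (!is.na(row$leaf_area_m2) && row$leaf_area_m2 <= 0)
    stop("validation error in field 'leaf_area_m2': must be > 0", call. = FALSE)
  if (!is.na(row$psi_final_MPa) && row$psi_final_MPa > 0)
    stop("validation error in field 'psi_final_MPa': must be <= 0", call. = FALSE)
  invisible(row)
}

#' Write the standardized measurement report
#'
#' One tidy row per leaf, fixed column order, units encoded in the headers
#' (`psi_final_MPa`, `E_mmol_m2_s`, ...), missing values as the literal
#' token `NA`. When `thresholds` is supplied, the analysis settings
#' (segmentation penalty, merge window, steadiness duration and alpha, ...)
#' are appended as `# key = value` comment lines so the report is
#' self-describing; [read_report()] skips them.
#'
#' @param records A `report_record`, or a list of them. An empty list writes
#'   a header-only file.
#' @param path Output CSV path.
#' @param thresholds Optional named list echoed into the report footer.
#' @return Invisibly, `path`.
#' @export
write_report <- function(records, path, thresholds = NULL) {
  if (inherits(records, "report_record")) records <- list(records)
  stopifnot(is.list(records))
  if (length(records)) {
    rows <- lapply(records, function(r) {
      .validate_report_row(r)
      as.data.frame(r)[, .report_columns]
    })
    tab <- do.call(rbind, rows)
  } else {
    tab <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(.report_columns)), .report_columns))
  }
  utils::write.table(tab, path, sep = ",", row.names = FALSE, na = "NA",
                     qmethod = "double", fileEncoding = "UTF-8")
  if (!is.null(thresholds)) {
    con <- file(path, open = "a", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(sprintf("# %s = %s", names(thresholds),
                       vapply(thresholds, function(v) paste(format(v), collapse = " "),
                              character(1))), con)
  }
  invisible(path)
}

#' Read a measurement report written by [write_report()]
#'
#' @param path Report CSV path.
#' @return A `data.frame`, one row per leaf; footer comment lines ignored.
#' @export
read_report <- function(path) {
  utils::read.table(path, header = TRUE, sep = ",", na.strings = "NA",
                    comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"")
}

#' Audit a measurement report for internal consistency
#'
#' Checks that the report carries the required unit-annotated columns, that
#' non-steady rows carry no K_leaf, and that every reported K_leaf is
#' re-derivable from its own row's `E_mmol_m2_s`, `psi_final_MPa` and
#' `T_leaf_C` through the public formulas (`K = E / (0 - psi_final)`,
#' viscosity normalization to 25 deg C).
#'
#' @param path Report CSV path.
#' @param tol Relative tolerance of the re-derivation check.
#' @return Invisibly `TRUE`; errors describe the first violation found.
#' @export
validate_report <- function(path, tol = 1e-6) {
  tab <- read_report(path)
  missing_cols <- setdiff(.report_columns, names(tab))
  if (length(missing_cols))
    stop("report is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    if (!row$steadiness_class %in% c("A", "B", "C", "D"))
      stop(sprintf("row %d: invalid steadiness_class '%s'", i,
                   row$steadiness_class), call. = FALSE)
    if (row$steadiness_class != "D") {
      if (!is.na(row$K_leaf_mmol_m2_s_MPa) || !is.na(row$E_mmol_m2_s))
        stop(sprintf("row %d: non-steady leaf carries E or K_leaf", i),
             call. = FALSE)
      next
    }
    k <- compute_kleaf(row$E_mmol_m2_s, row$psi_final_MPa, row$T_leaf_C)
    if (abs(k$K_raw - row$K_leaf_mmol_m2_s_MPa) >
        tol * max(1, abs(k$K_raw)) ||
        abs(k$K_25 - row$K_leaf25_mmol_m2_s_MPa) > tol * max(1, abs(k$K_25)))
      stop(sprintf("row %d: reported K_leaf is not re-derivable from E, psi_final and T_leaf", i),
           call. = FALSE)
  }
  invisible(TRUE)
}
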