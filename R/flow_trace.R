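#' Construct a flow trace
#'
#' A `flow_trace` is the pipeline's central container: a timestamped record
#' from one evaporative-flux (EFM) run holding elapsed time in seconds,
#' the cumulative water weight of the reservoir on the balance (g), and/or
#' the derived transpirational flow series. Flow may be per leaf
#' (`"mmol s-1"`, as it comes off the balance before area normalization) or
#' area-normalized (`"mmol m-2 s-1"`, the unit in which steady flow E and
#' K_leaf are expressed).
#'
#' @param time_s Numeric vector of elapsed seconds since the start of
#'   recording; strictly increasing, length at least 2.
#' @param weight_g Optional cumulative reservoir weight (g), same length as
#'   `time_s`.
#' @param flow Optional flow series, same length as `time_s`.
#' @param flow_units Units of `flow`: `"mmol m-2 s-1"` (area-normalized) or
#'   `"mmol s-1"` (per leaf). Ignored when `flow` is `NULL`.
#' @param sampling_interval_s Nominal balance logging interval (s); EFM
#'   balances typically log every 3 s.
#' @param smooth_window_s Width (s) of the rolling window used to derive
#'   `flow` from weight, or 0 when flow was recorded directly. Consumers
#'   (notably the steadiness slope test) use this to account for the
#'   autocorrelation that overlapping-window differentiation induces.
#' @param flags Character vector of data-quality flags (e.g.
#'   `"negative_flow"` after background-evaporation correction).
#'
#' @return An object of class `flow_trace`: a list with elements `time_s`,
#'   `weight_g`, `flow`, `flow_units`, `sampling_interval_s`,
#'   `smooth_window_s`, `flags`.
#' @seealso [read_balance_log()], [weight_to_flow()], [dp_segment()]
#' @examples
#' t <- seq(0, 30, by = 3)
#' flow_trace(t, weight_g = 100 - 1e-4 * t)
#' @export
flow_trace <- function(time_s, weight_g = NULL, flow = NULL,
                       flow_units = c("mmol m-2 s-1", "mmol s-1"),
                       sampling_interval_s = 3, smooth_window_s = 0,
                       flags = character()) {
  time_s <- as.numeric(time_s)
  if (length(time_s) < 2L)
    stop("empty trace: a flow trace needs at least 2 samples", call. = FALSE)
  if (anyNA(time_s))
    stop("time_s contains missing values", call. = FALSE)
  if (any(diff(time_s) <= 0))
    stop("time_s must be strictly increasing", call. = FALSE)
  if (!is.null(weight_g)) {
    weight_g <- as.numeric(weight_g)
    if (length(weight_g) != length(time_s))
      stop("weight_g and time_s lengths differ", call. = FALSE)
  }
  if (!is.null(flow)) {
    flow <- as.numeric(flow)
    if (length(flow) != length(time_s))
      stop("flow and time_s lengths differ", call. = FALSE)
    flow_units <- match.arg(flow_units)
  } else {
    flow_units <- NULL
  }
  if (is.null(weight_g) && is.null(flow))
    stop("a flow trace needs a weight or a flow series", call. = FALSE)
  stopifnot(sampling_interval_s > 0, smooth_window_s >= 0)
  structure(
    list(time_s = time_s, weight_g = weight_g, flow = flow,
         flow_units = flow_units,
         sampling_interval_s = as.numeric(sampling_interval_s),
         smooth_window_s = as.numeric(smooth_window_s),
         flags = as.character(flags)),
    class = "flow_trace")
}

#' Number of samples in a flow trace
#' @param trace A [flow_trace()].
#' @return Integer sample count.
#' @export
n_samples <- function(trace) {
  stopifnot(inherits(trace, "flow_trace"))
  length(trace$time_s)
}

.has_flow <- function(trace) !is.null(trace$flow)
.has_weight <- function(trace) !is.null(trace$weight_g)

.require_flow <- function(trace, units = NULL) {
  if (!inherits(trace, "flow_trace"))
    stop("not a flow_trace", call. = FALSE)
  if (!.has_flow(trace))
    stop("trace has no computed flow series; run weight_to_flow() first",
         call. = FALSE)
  if (!is.null(units) && !identical(trace$flow_units, units))
    stop(sprintf("flow is in '%s' but '%s' is required here",
                 trace$flow_units, units), call. = FALSE)
  invisible(trace)
}

#' @export
print.flow_trace <- function(x, ...) {
  cat(sprintf("<flow_trace> %d samples, %.0f s span (interval %g s)\n",
              n_samples(x), diff(range(x$time_s)), x$sampling_interval_s))
  if (.has_weight(x))
    cat(sprintf("  weight_g: %.6g .. %.6g g\n",
                x$weight_g[1], x$weight_g[length(x$weight_g)]))
  if (.has_flow(x))
    cat(sprintf("  flow: mean %.4g [%s]%s\n", mean(x$flow), x$flow_units,
                if (x$smooth_window_s > 0)
                  sprintf(" (derived, %g s window)", x$smooth_window_s)
                else ""))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.flow_trace <- function(x, ...) {
  out <- data.frame(time_s = x$time_s)
  if (.has_weight(x)) out$weight_g <- x$weight_g
  if (.has_flow(x)) {
    col <- if (identical(x$flow_units, "mmol m-2 s-1"))
      "flow_mmol_m2_s" else "flow_mmol_s"
    out[[col]] <- x$flow
  }
  out
}

#' Plot a flow trace, optionally with its segmentation
#'
#' @param x A [flow_trace()].
#' @param segments Optional segmentation (from [dp_segment()] or
#'   [merge_invalid_segments()]) drawn as colored fitted lines.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.flow_trace <- function(x, segments = NULL, ...) {
  if (.has_flow(x)) {
    graphics::plot(x$time_s, x$flow, type = "l", col = "grey40",
                   xlab = "time (s)", ylab = paste0("flow (", x$flow_units, ")"),
                   ...)
    if (!is.null(segments)) {
      cols <- grDevices::hcl.colors(max(3L, nrow(segments)), "Dark 3")
      for (k in seq_len(nrow(segments))) {
        idx <- segments$start_idx[k]:segments$end_idx[k]
        graphics::lines(x$time_s[idx],
                        segments$intercept[k] + segments$slope[k] * x$time_s[idx],
                        col = cols[k], lwd = 2)
      }
    }
  } else {
    graphics::plot(x$time_s, x$weight_g, type = "l",
                   xlab = "time (s)", ylab = "weight (g)", ...)
  }
  invisible(x)
}
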