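#' Convert a weight series to flow by rolling-window OLS slopes
#'
#' At each sample, fits an ordinary-least-squares line to reservoir weight
#' versus time over a centered window and converts the negative slope
#' (g s-1; the reservoir loses weight as the leaf takes water up) to molar
#' flow in mmol s-1. Windows are truncated (asymmetric) at the trace edges
#' so the output has the same length as the input, which keeps segmentation
#' indices aligned with the raw log. The default 60 s window smooths the
#' 3-s balance jitter while preserving structure on the 15-min scale that
#' the steadiness criteria probe. The window width is recorded on the
#' returned trace (`smooth_window_s`) because overlapping windows induce
#' autocorrelation that the steadiness slope test must account for.
#'
#' The result is per-leaf flow, not yet area-normalized: background
#' evaporation is a property of the reservoir and must be subtracted
#' ([correct_evaporation()]) before dividing by leaf area
#' ([area_normalize()]).
#'
#' @param trace A [flow_trace()] with a weight series.
#' @param window_s Full width (s) of the centered slope window; at least
#'   2 sampling intervals.
#' @param molar_mass_g_mmol Molar mass of water (g mmol-1).
#' @return A [flow_trace()] with `flow` in `"mmol s-1"` (weight retained).
#' @examples
#' t <- seq(0, 600, by = 3)
#' tr <- flow_trace(t, weight_g = 100 - 1e-4 * t)
#' f <- weight_to_flow(tr)
#' range(f$flow)  # constant 1e-4 / 0.018015 mmol s-1
#' @export
weight_to_flow <- function(trace, window_s = 60,
                           molar_mass_g_mmol = 0.018015) {
  stopifnot(inherits(trace, "flow_trace"))
  if (!.has_weight(trace))
    stop("trace has no weight series", call. = FALSE)
  t <- trace$time_s
  if (any(diff(t) <= 0)) stop("non-monotone time", call. = FALSE)
  if (window_s < 2 * trace$sampling_interval_s)
    stop("parameter error: window_s must cover at least 2 sampling intervals",
         call. = FALSE)
  w <- trace$weight_g
  half <- window_s / 2
  lo <- findInterval(t - half, t, left.open = TRUE) + 1L
  hi <- findInterval(t + half, t)
  # prefix sums -> per-window OLS slope in O(n); computed on globally
  # centered series so the sums cancel without losing precision
  tc <- t - mean(t)
  wc <- w - mean(w)
  c1 <- c(0, cumsum(rep(1, length(t))))
  cx <- c(0, cumsum(tc)); cy <- c(0, cumsum(wc))
  cxx <- c(0, cumsum(tc * tc)); cxy <- c(0, cumsum(tc * wc))
  n <- c1[hi + 1L] - c1[lo]
  sx <- cx[hi + 1L] - cx[lo]; sy <- cy[hi + 1L] - cy[lo]
  sxx <- cxx[hi + 1L] - cxx[lo] - sx * sx / n
  sxy <- cxy[hi + 1L] - cxy[lo] - sx * sy / n
  if (any(n < 2))
    stop("parameter error: slope window contains fewer than 2 samples",
         call. = FALSE)
  slope <- sxy / sxx
  flow_trace(t, weight_g = w, flow = -slope / molar_mass_g_mmol,
             flow_units = "mmol s-1",
             sampling_interval_s = trace$sampling_interval_s,
             smooth_window_s = window_s, flags = trace$flags)
}

#' Background-evaporation settings for the reservoir
#'
#' The water reservoir loses weight by evaporation even with no leaf
#' attached; with no prevention this background is about 0.115e-3 mmol s-1,
#' and covering the surface with liquid wax and/or humidifying the balance
#' chamber suppresses it. When prevention is in place (the recommended
#' practice) the residual rate is taken as 0 and no numeric correction is
#' applied.
#'
#' @param blank_rate_mmol_s Background evaporation rate (mmol s-1, >= 0)
#'   measured on a blank (leafless) run; default 0.
#' @param prevention Which physical prevention was in place.
#' @return An object of class `evaporation_setting`.
#' @export
evaporation_setting <- function(blank_rate_mmol_s = 0,
                                prevention = c("none", "wax", "humid_chamber",
                                               "wax_plus_humid")) {
  if (!is.finite(blank_rate_mmol_s) || blank_rate_mmol_s < 0)
    stop("blank_rate_mmol_s must be >= 0", call. = FALSE)
  structure(list(blank_rate_mmol_s = as.numeric(blank_rate_mmol_s),
                 prevention = match.arg(prevention)),
            class = "evaporation_setting")
}

#' Subtract background reservoir evaporation from per-leaf flow
#'
#' Applied uniformly to the per-leaf (`"mmol s-1"`) flow, before area
#' normalization. Corrected values that fall below zero are retained, not
#' clipped, and the trace is flagged `"negative_flow"`: negative flow after
#' correction usually means the blank rate was overestimated or the leaf
#' was barely transpiring, and the analyst should see it.
#'
#' @param trace A [flow_trace()] with flow in `"mmol s-1"`.
#' @param setting An [evaporation_setting()].
#' @return The corrected [flow_trace()].
#' @export
correct_evaporation <- function(trace, setting = evaporation_setting()) {
  .require_flow(trace, "mmol s-1")
  stopifnot(inherits(setting, "evaporation_setting"))
  out <- trace
  out$flow <- trace$flow - setting$blank_rate_mmol_s
  if (any(out$flow < 0) && !"negative_flow" %in% out$flags)
    out$flags <- c(out$flags, "negative_flow")
  out
}

#' Normalize per-leaf flow by leaf area
#'
#' Converts flow from mmol s-1 to mmol m-2 s-1, the unit in which the
#' steady flow E and K_leaf are expressed.
#'
#' @param trace A [flow_trace()] with flow in `"mmol s-1"`.
#' @param leaf_area_m2 One-sided leaf area (m^2), > 0.
#' @return The area-normalized [flow_trace()].
#' @export
area_normalize <- function(trace, leaf_area_m2) {
  .require_flow(trace, "mmol s-1")
  if (!is.finite(leaf_area_m2) || leaf_area_m2 <= 0)
    stop("parameter error: leaf_area_m2 must be > 0", call. = FALSE)
  out <- trace
  out$flow <- trace$flow / leaf_area_m2
  out$flow_units <- "mmol m-2 s-1"
  out
}
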