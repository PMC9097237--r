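#' Settings for segmentation and steady-state identification
#'
#' @param penalty_P Break-point penalty. Each additional breakpoint costs
#'   `penalty_P` in the segmentation objective, so larger values yield
#'   fewer, longer segments that are allowed higher residual variance.
#'   Default `NULL` auto-scales the penalty to
#'   `penalty_scale * var(flow)`, which makes it dimensionally consistent
#'   across traces and invariant to flow rescaling.
#' @param penalty_scale Multiplier of the global flow variance used when
#'   `penalty_P` is `NULL` (default 0.05). At this scale the dynamic
#'   program separates the initial rise from the rest of the trace but
#'   keeps an oscillating or declining stretch as one long segment, which
#'   is what the classification contract requires: the duration of the
#'   *last* segment decides class C, so oscillation must not be shredded
#'   into short half-period segments.
#' @param min_seg_points Minimum points per segment (>= 3, so every segment
#'   supports a slope and a residual variance).
#' @param merge_window_s Segments shorter than this (default 60 s) are
#'   deemed invalid -- typically a few outliers splitting one real segment
#'   -- and dissolved into a neighbor by [merge_invalid_segments()].
#' @param steady_min_duration_s Minimum duration of the final segment for a
#'   trace to qualify as steady (default 900 s = 15 min).
#' @param steady_window_s Width of the trailing window on which the slope
#'   t-test is run (default 900 s; about 300 points at 3-s sampling).
#' @param slope_alpha Significance threshold of the trailing-window slope
#'   t-test; the trace is steady when p > `slope_alpha` (default 0.001).
#' @return An object of class `segmentation_config`.
#' @seealso [dp_segment()], [classify_steadiness()]
#' @export
segmentation_config <- function(penalty_P = NULL, penalty_scale = 0.05,
                                min_seg_points = 3, merge_window_s = 60,
                                steady_min_duration_s = 900,
                                steady_window_s = 900, slope_alpha = 0.001) {
  stopifnot(is.null(penalty_P) || (is.finite(penalty_P) && penalty_P >= 0),
            penalty_scale >= 0,
            min_seg_points >= 3, merge_window_s > 0,
            steady_min_duration_s > 0, steady_window_s > 0,
            slope_alpha > 0, slope_alpha < 1)
  structure(list(penalty_P = penalty_P, penalty_scale = penalty_scale,
                 min_seg_points = as.integer(min_seg_points),
                 merge_window_s = merge_window_s,
                 steady_min_duration_s = steady_min_duration_s,
                 steady_window_s = steady_window_s,
                 slope_alpha = slope_alpha),
            class = "segmentation_config")
}

# prefix sums over (t, flow); any segment's OLS fit is then O(1)
.seg_prefix <- function(x, y) {
  list(cx = c(0, cumsum(x)), cy = c(0, cumsum(y)),
       cxx = c(0, cumsum(x * x)), cyy = c(0, cumsum(y * y)),
       cxy = c(0, cumsum(x * y)))
}

# OLS stats of segments [i, j] (inclusive, vectorized over i or j)
.seg_stats <- function(p, i, j) {
  n <- j - i + 1
  sx <- p$cx[j + 1] - p$cx[i]
  sy <- p$cy[j + 1] - p$cy[i]
  sxx <- p$cxx[j + 1] - p$cxx[i] - sx * sx / n
  syy <- p$cyy[j + 1] - p$cyy[i] - sy * sy / n
  sxy <- p$cxy[j + 1] - p$cxy[i] - sx * sy / n
  slope <- sxy / sxx
  rss <- pmax(syy - sxy * sxy / sxx, 0)
  list(n = n, sxx = sxx, syy = syy, slope = slope,
       intercept = (sy - slope * sx) / n, rss = rss)
}

#' Variance score of one candidate segment
#'
#' The segmentation objective scores each segment by the negative mean
#' residual variance of its OLS line fit, `-rss/n`. Summing this over
#' segments and charging `penalty_P` per breakpoint restricts segment
#' lengths by explicitly allowing high within-segment variance: a higher
#' penalty tolerates more residual variance before a break pays off.
#' Computed from prefix sums, so after linear preprocessing any `(i, j)`
#' evaluation is constant-time.
#'
#' @param trace A [flow_trace()] with computed flow.
#' @param i,j Inclusive sample indices of the candidate segment.
#' @param min_seg_points Minimum admissible segment length.
#' @return The scalar score `-rss/n` (<= 0; 0 for a perfectly linear
#'   segment).
#' @export
segment_score <- function(trace, i, j, min_seg_points = 3) {
  .require_flow(trace)
  stopifnot(length(i) == 1, length(j) == 1)
  if (j - i + 1 < min_seg_points)
    stop("segment shorter than min_seg_points", call. = FALSE)
  x <- trace$time_s[i:j]
  if (max(x) == min(x))
    stop("data error: degenerate time range in segment", call. = FALSE)
  p <- .seg_prefix(x, trace$flow[i:j])
  st <- .seg_stats(p, 1, length(x))
  -st$rss / st$n
}

#' Optimal penalized piecewise-linear segmentation of a flow trace
#'
#' Dynamic programming over all segmentations whose segments have at least
#' `min_seg_points` points, maximizing the sum of per-segment variance
#' scores ([segment_score()]) minus `penalty_P` per breakpoint:
#' `S(i) = max_j S(j) + score(j+1, i) - P`. Segments tile the trace with no
#' gaps or overlaps. Ties are broken toward fewer segments (and then toward
#' a longer final segment), so the output is deterministic.
#'
#' @param trace A [flow_trace()] with computed flow.
#' @param config A [segmentation_config()].
#' @return A `data.frame` of class `segmentation`, one row per segment:
#'   `start_idx`, `end_idx`, `n`, `start_s`, `end_s`, `duration_s`,
#'   `slope`, `intercept`, `rss`. The penalty actually used is attached as
#'   attribute `penalty_P`.
#' @examples
#' sim <- simulate_flow(trace_spec(duration_s = 1800, seed = 1))
#' seg <- dp_segment(sim$trace)
#' seg
#' @export
dp_segment <- function(trace, config = segmentation_config()) {
  .require_flow(trace)
  stopifnot(inherits(config, "segmentation_config"))
  x <- trace$time_s
  y <- trace$flow
  n <- length(y)
  m <- config$min_seg_points
  if (n < m)
    stop("data error: trace shorter than min_seg_points", call. = FALSE)
  P <- if (is.null(config$penalty_P)) config$penalty_scale * stats::var(y)
       else config$penalty_P
  p <- .seg_prefix(x, y)
  S <- rep(-Inf, n + 1); S[1] <- 0
  nseg <- integer(n + 1)
  prev <- integer(n + 1)
  for (i in m:n) {
    js <- c(0L, if (i >= 2L * m) m:(i - m))      # admissible previous ends
    st <- .seg_stats(p, js + 1L, i)
    val <- S[js + 1L] - st$rss / st$n - ifelse(js == 0L, 0, P)
    best <- max(val)
    cand <- which(val >= best - 1e-9 * (abs(best) + 1))
    k <- cand[order(nseg[js[cand] + 1L], js[cand])][1L]
    S[i + 1L] <- val[k]
    prev[i + 1L] <- js[k]
    nseg[i + 1L] <- nseg[js[k] + 1L] + 1L
  }
  ends <- integer(0); b <- n
  while (b > 0) { ends <- c(b, ends); b <- prev[b + 1L] }
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  .segment_table(p, x, starts, ends, P, config)
}

.segment_table <- function(p, x, starts, ends, P, config) {
  st <- .seg_stats(p, starts, ends)
  out <- data.frame(start_idx = starts, end_idx = ends, n = st$n,
                    start_s = x[starts], end_s = x[ends],
                    duration_s = x[ends] - x[starts],
                    slope = st$slope, intercept = st$intercept, rss = st$rss)
  class(out) <- c("segmentation", "data.frame")
  attr(out, "penalty_P") <- P
  attr(out, "config") <- config
  out
}

#' Dissolve sub-minute segments into their neighbors
#'
#' Distinct segments shorter than `merge_window_s` (default 1 min) are
#' usually artifacts of a few outliers splitting one real segment and are
#' deemed invalid. Each such segment is dissolved into whichever neighbor
#' yields the smaller combined mean residual variance, the merged segment
#' is refitted, and the rule is repeated until no sub-minute segment
#' remains (or a single segment is left).
#'
#' @param segments A `segmentation` from [dp_segment()].
#' @param trace The [flow_trace()] the segmentation was computed on.
#' @param config A [segmentation_config()].
#' @return The merged `segmentation`.
#' @export
merge_invalid_segments <- function(segments, trace,
                                   config = segmentation_config()) {
  .require_flow(trace)
  stopifnot(inherits(segments, "segmentation"))
  x <- trace$time_s
  p <- .seg_prefix(x, trace$flow)
  starts <- segments$start_idx
  ends <- segments$end_idx
  repeat {
    if (length(starts) <= 1L) break
    dur <- x[ends] - x[starts]
    bad <- which(dur < config$merge_window_s)
    if (!length(bad)) break
    k <- bad[which.min(dur[bad])]
    mvar <- function(i, j) { s <- .seg_stats(p, i, j); s$rss / s$n }
    left <- if (k > 1L) mvar(starts[k - 1L], ends[k]) else Inf
    right <- if (k < length(starts)) mvar(starts[k], ends[k + 1L]) else Inf
    if (left <= right) {
      ends[k - 1L] <- ends[k]
      starts <- starts[-k]; ends <- ends[-k]
    } else {
      starts[k + 1L] <- starts[k]
      starts <- starts[-k]; ends <- ends[-k]
    }
  }
  .segment_table(p, x, starts, ends, attr(segments, "penalty_P"), config)
}

#' Two-sided t-test p-value of the flow slope in a window
#'
#' Tests H0: slope = 0 for the OLS line of flow versus time over the given
#' samples, using the t statistic with n - 2 degrees of freedom. When
#' `thin_by > 1` only every `thin_by`-th sample enters the test; this is
#' how the steadiness classifier handles flow series derived by
#' overlapping-window differentiation of weight, whose smoothing-induced
#' autocorrelation would otherwise make the naive test reject a true
#' plateau far more often than its nominal level (thinning by the smoothing
#' width restores independence and exact calibration).
#'
#' Conventions for degenerate windows: zero residual variance with a
#' nonzero slope gives p = 0; a window of identical values (zero slope,
#' zero variance) gives p = 1.
#'
#' @param trace A [flow_trace()] with computed flow.
#' @param window Integer vector of sample indices (at least 3 after
#'   thinning).
#' @param thin_by Integer decimation step (>= 1).
#' @return The two-sided p-value.
#' @export
slope_p_value <- function(trace, window, thin_by = 1L) {
  .require_flow(trace)
  window <- as.integer(window)
  if (thin_by > 1L) window <- window[seq(1L, length(window), by = thin_by)]
  if (length(window) < 3L)
    stop("slope test window has fewer than 3 points", call. = FALSE)
  x <- trace$time_s[window]
  y <- trace$flow[window]
  n <- length(y)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("data error: degenerate time range", call. = FALSE)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  if (syy <= 0) return(1)                    # flat window of identical values
  slope <- sxy / sxx
  rss <- max(syy - sxy^2 / sxx, 0)
  if (rss / syy < 1e-12)                     # exact line
    return(if (abs(slope) < 1e-15) 1 else 0)
  se <- sqrt(rss / (n - 2) / sxx)
  2 * stats::pt(-abs(slope / se), df = n - 2)
}

#' Number of balance samples in a steady window
#'
#' A 15-min window at the usual 3-s logging interval holds about 300
#' points, the sample size the trailing slope t-test operates on.
#'
#' @param duration_s Window duration (s), default 900.
#' @param interval_s Sampling interval (s), default 3.
#' @return Integer point count, `round(duration_s / interval_s)`.
#' @export
steady_window_points <- function(duration_s = 900, interval_s = 3) {
  stopifnot(duration_s > 0, interval_s > 0)
  as.integer(round(duration_s / interval_s))
}

#' Classify a flow trace as steady or non-steady
#'
#' Applies the steadiness criteria to a post-merge segmentation:
#' \describe{
#'   \item{class C}{the final segment lasts less than
#'     `steady_min_duration_s` (15 min): the run ended before a plateau of
#'     the required length formed. Non-steady.}
#'   \item{class D}{the final segment is long enough and the slope of the
#'     trailing `steady_window_s` flow window is statistically
#'     indistinguishable from zero (t-test p > `slope_alpha`). Steady; the
#'     trailing window is recorded as the E-extraction window.}
#'   \item{class A}{final slope significantly nonzero and the post-rise
#'     trajectory is non-monotone (at least 2 sign changes among
#'     significant local slopes after the rise): oscillating flow,
#'     typically stomatal oscillation. Non-steady.}
#'   \item{class B}{final slope significantly nonzero, trajectory monotone
#'     (usually declining after a peak). Non-steady.}
#' }
#'
#' The post-rise region starts where the piecewise-linear fit first
#' reaches 90% of its global span. Non-monotonicity is judged on OLS
#' slopes of consecutive non-overlapping sub-windows
#' (`steady_window_s / 6`, i.e. 2.5 min by default -- shorter than any
#' oscillation worth the name, longer than balance jitter) rather than on
#' the segments themselves, whose number depends on the break-point
#' penalty; a local slope only counts when it exceeds twice its standard
#' error, so noise-level wiggles on a plateau cannot masquerade as
#' oscillation. For flow derived from weight by overlapping windows the
#' trailing slope test is thinned to one sample per smoothing window (see
#' [slope_p_value()]).
#'
#' @param segments A post-merge `segmentation`.
#' @param trace The [flow_trace()] the segmentation was computed on.
#' @param config A [segmentation_config()].
#' @return An object of class `steadiness_result`: list with `steady`,
#'   `curve_class` ("A", "B", "C" or "D"), `last_segment_duration_s`,
#'   `slope_p_value` (NA for class C), `steady_window` (index range, class
#'   D only), `sign_changes`, `thin_by`.
#' @export
classify_steadiness <- function(segments, trace,
                                config = segmentation_config()) {
  .require_flow(trace)
  stopifnot(inherits(segments, "segmentation"))
  x <- trace$time_s
  last <- nrow(segments)
  last_dur <- segments$duration_s[last]
  res <- list(steady = FALSE, curve_class = NA_character_,
              last_segment_duration_s = last_dur,
              slope_p_value = NA_real_, steady_window = NULL,
              sign_changes = NA_integer_, thin_by = 1L)
  class(res) <- "steadiness_result"
  if (last_dur < config$steady_min_duration_s) {
    res$curve_class <- "C"
    return(res)
  }
  t_end <- x[length(x)]
  win <- which(x > t_end - config$steady_window_s)
  thin <- if (trace$smooth_window_s > trace$sampling_interval_s)
    max(1L, as.integer(round(trace$smooth_window_s / trace$sampling_interval_s)))
  else 1L
  res$thin_by <- thin
  res$slope_p_value <- slope_p_value(trace, win, thin_by = thin)
  if (res$slope_p_value > config$slope_alpha) {
    res$steady <- TRUE
    res$curve_class <- "D"
    res$steady_window <- range(win)
    return(res)
  }
  res$sign_changes <- .post_rise_sign_changes(segments, trace,
                                              config$steady_window_s / 6)
  res$curve_class <- if (res$sign_changes >= 2L) "A" else "B"
  res
}

# sign changes among significant local slopes after the end of the rise
.post_rise_sign_changes <- function(segments, trace, sub_window_s) {
  x <- trace$time_s
  y <- trace$flow
  yhat <- numeric(length(x))
  for (k in seq_len(nrow(segments))) {
    idx <- segments$start_idx[k]:segments$end_idx[k]
    yhat[idx] <- segments$intercept[k] + segments$slope[k] * x[idx]
  }
  span <- range(yhat)
  i0 <- which(yhat >= span[1] + 0.9 * diff(span))[1]
  if (is.na(i0)) return(0L)
  breaks <- seq(x[i0], x[length(x)] + sub_window_s, by = sub_window_s)
  grp <- findInterval(x, breaks, rightmost.closed = TRUE)
  sig_sign <- integer(0)
  for (g in unique(grp[grp >= 1])) {
    idx <- which(grp == g)
    if (length(idx) < 4L) next
    xs <- x[idx]; ys <- y[idx]
    sxx <- sum((xs - mean(xs))^2)
    sxy <- sum((xs - mean(xs)) * (ys - mean(ys)))
    syy <- sum((ys - mean(ys))^2)
    sl <- sxy / sxx
    rss <- max(syy - sxy^2 / sxx, 0)
    se <- sqrt(rss / (length(idx) - 2) / sxx)
    if ((se == 0 && sl != 0) || (se > 0 && abs(sl) > 2 * se))
      sig_sign <- c(sig_sign, sign(sl))
  }
  if (length(sig_sign) < 2L) return(0L)
  sum(diff(sig_sign) != 0)
}

#' @export
print.steadiness_result <- function(x, ...) {
  cat(sprintf("<steadiness> class %s (%s)\n", x$curve_class,
              if (x$steady) "steady" else "non-steady"))
  cat(sprintf("  last segment: %.0f s; trailing-window slope p = %s\n",
              x$last_segment_duration_s,
              if (is.na(x$slope_p_value)) "NA" else
                format(x$slope_p_value, digits = 3)))
  if (!is.null(x$steady_window))
    cat(sprintf("  E window: samples %d..%d\n",
                x$steady_window[1], x$steady_window[2]))
  invisible(x)
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d segment(s), penalty P = %.4g\n",
              nrow(x), attr(x, "penalty_P")))
  print.data.frame(x, digits = 4)
  invisible(x)
}
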