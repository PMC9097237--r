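#' Specification of a synthetic EFM flow trace
#'
#' Defines the deterministic shape and noise of a simulated
#' evaporative-flux run. The mean curve is an exponential rise to a
#' plateau, optionally modulated by a multiplicative sinusoid (stomatal
#' oscillation) and an exponential post-peak decline:
#' \deqn{flow(t) = E (1 - e^{-t/\tau}) (1 + a \sin(2\pi t/T))
#'   e^{-r \max(0, t - 5\tau)} + \epsilon_t}
#' with Gaussian noise `epsilon_t` (optionally AR(1)-correlated, since real
#' balance-derived flow readings are serially correlated). Defaults match
#' the magnitudes observed on rice under 1000 umol m-2 s-1 PARa: plateau
#' E = 8.75 mmol m-2 s-1, psi_final = -0.31 MPa, ~25 cm2 leaves, 1-h runs
#' logged every 3 s.
#'
#' @param duration_s Run length (s), default 3600.
#' @param interval_s Logging interval (s), default 3.
#' @param E_plateau Target steady flow (mmol m-2 s-1), default 8.75.
#' @param rise_tau_s Time constant of the exponential approach (s);
#'   default 120 (plateau effectively reached within ~8 min).
#' @param osc_amplitude Oscillation amplitude as a fraction of the plateau
#'   (0 = none).
#' @param osc_period_s Oscillation period (s), default 600 (stomatal
#'   oscillations run on a scale of minutes to tens of minutes).
#' @param decline_rate Fractional decay per second after the peak
#'   (0 = none); the peak is taken at `5 * rise_tau_s`, where the rise is more than
#'   99% complete.
#' @param noise_sd Gaussian noise SD in flow units; default 0.175 (2% of
#'   the default plateau, typical of a well-damped balance signal).
#' @param ar1 AR(1) coefficient of the noise (0 = white). The stationary
#'   SD stays `noise_sd`.
#' @param blank_evap_mmol_s Background reservoir evaporation (mmol s-1)
#'   added when integrating flow to weight; default 0 (prevention in
#'   place).
#' @param leaf_area_m2 Leaf area used by [flow_to_weight()], default
#'   2.5e-3.
#' @param psi_final_MPa Ground-truth final water potential, default -0.31.
#' @param seed RNG seed for reproducibility (`NULL` = leave RNG alone).
#' @return An object of class `trace_spec`.
#' @export
trace_spec <- function(duration_s = 3600, interval_s = 3, E_plateau = 8.75,
                       rise_tau_s = 120, osc_amplitude = 0,
                       osc_period_s = 600, decline_rate = 0,
                       noise_sd = 0.175, ar1 = 0, blank_evap_mmol_s = 0,
                       leaf_area_m2 = 2.5e-3, psi_final_MPa = -0.31,
                       seed = NULL) {
  stopifnot(interval_s > 0, duration_s >= 2 * interval_s,
            E_plateau >= 0, rise_tau_s > 0, osc_amplitude >= 0,
            osc_period_s > 0, decline_rate >= 0, noise_sd >= 0,
            abs(ar1) < 1, blank_evap_mmol_s >= 0, leaf_area_m2 > 0)
  structure(as.list(environment()), class = "trace_spec")
}

# deterministic mean flow curve of a spec
.mean_flow_curve <- function(spec, t) {
  peak_t <- 5 * spec$rise_tau_s
  spec$E_plateau * (1 - exp(-t / spec$rise_tau_s)) *
    (1 + spec$osc_amplitude * sin(2 * pi * t / spec$osc_period_s)) *
    exp(-spec$decline_rate * pmax(0, t - peak_t))
}

#' Simulate a flow trace with analytic ground truth
#'
#' Draws a noisy flow trace from a [trace_spec()] and labels it with the
#' steadiness class the trace *should* receive under the steady-state
#' criteria, derived analytically from the spec (not by running the
#' classifier):
#' \itemize{
#'   \item `decline_rate > 0` -- class B (declining after peak);
#'   \item otherwise, an oscillation whose deterministic trailing-window
#'     slope is detectable by the t-test at the given noise level -- class
#'     A;
#'   \item otherwise, plateau reached (within 2%, i.e. `tau * log(50)`
#'     elapsed) with at least 15 min remaining -- class D (steady);
#'   \item otherwise -- class C (plateau too short).
#' }
#' Detectability means the expected t statistic of the noise-free slope
#' over the trailing 15-min window exceeds the two-sided critical value at
#' alpha = 0.001.
#'
#' @param spec A [trace_spec()].
#' @return An object of class `efm_simulation`: list with `trace` (a
#'   [flow_trace()] carrying area-normalized flow), `truth` (list:
#'   `curve_class`, `steady`, `E_true`, `K_true`, `psi_final_MPa`,
#'   `t_reach_s`), and `spec`.
#' @examples
#' sim <- simulate_flow(trace_spec(seed = 42))
#' sim$truth$curve_class
#' @export
simulate_flow <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  t <- seq(0, spec$duration_s, by = spec$interval_s)
  mu <- .mean_flow_curve(spec, t)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- length(t)
  eps <- if (spec$noise_sd == 0) numeric(n)
  else if (spec$ar1 == 0) stats::rnorm(n, sd = spec$noise_sd)
  else as.numeric(stats::arima.sim(list(ar = spec$ar1), n,
                                   sd = spec$noise_sd * sqrt(1 - spec$ar1^2)))
  trace <- flow_trace(t, flow = mu + eps, flow_units = "mmol m-2 s-1",
                      sampling_interval_s = spec$interval_s)
  structure(list(trace = trace, truth = .ground_truth(spec, t, mu),
                 spec = spec),
            class = "efm_simulation")
}

.ground_truth <- function(spec, t, mu, steady_window_s = 900,
                          alpha = 0.001) {
  t_reach <- spec$rise_tau_s * log(50)
  win <- which(t > max(t) - steady_window_s)
  cls <- if (spec$decline_rate > 0) "B"
  else if (spec$osc_amplitude > 0 &&
           .slope_detectable(t[win], mu[win], spec$noise_sd, alpha)) "A"
  else if (spec$duration_s - t_reach >= steady_window_s) "D"
  else "C"
  E_true <- spec$E_plateau
  list(curve_class = cls, steady = cls == "D", E_true = E_true,
       K_true = if (spec$psi_final_MPa < 0) E_true / (-spec$psi_final_MPa)
                else NA_real_,
       psi_final_MPa = spec$psi_final_MPa, t_reach_s = t_reach)
}

# expected t statistic of the noise-free slope vs the alpha critical value;
# the expected residual variance includes the deterministic lack-of-fit
# (e.g. the sinusoid itself), which the real test also sees as residual
.slope_detectable <- function(x, mu, noise_sd, alpha) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (mu - mean(mu)))
  slope <- sxy / sxx
  rss_mu <- max(sum((mu - mean(mu))^2) - sxy^2 / sxx, 0)
  res_var <- rss_mu / (n - 2) + noise_sd^2
  if (res_var == 0) return(abs(slope) > 1e-12)
  abs(slope) / sqrt(res_var / sxx) > stats::qt(1 - alpha / 2, n - 2)
}

#' @export
print.efm_simulation <- function(x, ...) {
  cat(sprintf("<efm_simulation> true class %s (E = %.3g mmol m-2 s-1)\n",
              x$truth$curve_class, x$truth$E_true))
  print(x$trace)
  invisible(x)
}

#' Integrate a simulated flow trace into a balance weight log
#'
#' Inverse of [weight_to_flow()]: the reservoir weight is the initial
#' weight minus the molar mass of water times the trapezoid-rule integral
#' of total molar uptake (area x area-normalized flow + background
#' evaporation). On noiseless input, [weight_to_flow()] on the result
#' recovers the flow to within discretization error away from the trace
#' edges.
#'
#' @param trace A [flow_trace()] with area-normalized flow (e.g. from
#'   [simulate_flow()]).
#' @param spec The [trace_spec()] supplying `leaf_area_m2` and
#'   `blank_evap_mmol_s`.
#' @param w0_g Initial reservoir weight (g).
#' @return A weight-only [flow_trace()] emulating a raw balance log.
#' @export
flow_to_weight <- function(trace, spec, w0_g = 250) {
  .require_flow(trace, "mmol m-2 s-1")
  stopifnot(inherits(spec, "trace_spec"))
  t <- trace$time_s
  q <- spec$leaf_area_m2 * trace$flow + spec$blank_evap_mmol_s  # mmol s-1
  n <- length(t)
  cum <- c(0, cumsum((q[-1] + q[-n]) / 2 * diff(t)))            # mmol
  flow_trace(t, weight_g = w0_g - 0.018015 * cum,
             sampling_interval_s = trace$sampling_interval_s)
}

#' Simulate a blank (leafless) evaporation run
#'
#' A reservoir with no leaf attached loses weight only by evaporation:
#' weight declines at `rate_mmol_s * 18.015e-3` g s-1 plus balance noise.
#' Used to calibrate the blank rate fed to [correct_evaporation()].
#'
#' @param duration_s Run length (s).
#' @param rate_mmol_s Evaporation rate (mmol s-1, >= 0); the no-prevention
#'   default is 0.115e-3.
#' @param noise_sd_g Balance noise SD on weight (g).
#' @param seed RNG seed (`NULL` = leave RNG alone).
#' @param interval_s Logging interval (s).
#' @param w0_g Initial reservoir weight (g).
#' @return A weight-only [flow_trace()].
#' @export
simulate_blank <- function(duration_s = 3600, rate_mmol_s = 0.115e-3,
                           noise_sd_g = 0, seed = NULL, interval_s = 3,
                           w0_g = 250) {
  stopifnot(rate_mmol_s >= 0, noise_sd_g >= 0)
  t <- seq(0, duration_s, by = interval_s)
  if (!is.null(seed)) set.seed(seed)
  w <- w0_g - rate_mmol_s * 0.018015 * t +
    if (noise_sd_g > 0) stats::rnorm(length(t), sd = noise_sd_g) else 0
  flow_trace(t, weight_g = w, sampling_interval_s = interval_s)
}
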