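#' Extract the steady transpirational flow E
#'
#' E is the mean area-normalized flow over the steady window identified by
#' [classify_steadiness()] (the trailing 15-min window of a class-D trace).
#' The mean over the window, rather than the last-segment OLS intercept, is
#' used because it is robust to small residual structure and matches the
#' operational definition of a flow that is stable for a period of time.
#' For any non-steady class (A, B, C) there is no defensible E and the
#' function refuses.
#'
#' @param trace A [flow_trace()] with area-normalized flow.
#' @param steadiness A `steadiness_result` from [classify_steadiness()].
#' @return E in mmol m-2 s-1.
#' @export
extract_E <- function(trace, steadiness) {
  .require_flow(trace, "mmol m-2 s-1")
  stopifnot(inherits(steadiness, "steadiness_result"))
  if (!isTRUE(steadiness$steady) || is.null(steadiness$steady_window))
    stop(sprintf(
      "refusal: trace is non-steady (class %s); no E can be extracted",
      steadiness$curve_class), call. = FALSE)
  w <- steadiness$steady_window
  mean(trace$flow[w[1]:w[2]])
}

#' Dynamic viscosity of pure water
#'
#' Vogel-type correlation for liquid water,
#' `eta(T) = exp(A + B / (C + T_K))` mPa s with A = -3.7188, B = 578.919,
#' C = -137.546 and T_K in kelvin (coefficients as tabulated in Reid,
#' Prausnitz & Poling, The Properties of Gases and Liquids). Over the
#' 15-40 deg C range relevant to leaf measurements, published pure-water
#' correlations agree to well under 0.5%, below EFM measurement error.
#' Exposed so the normalization applied by [normalize_to_25C()] can be
#' inspected directly.
#'
#' @param T_C Water temperature, deg C, in (0, 100).
#' @return Dynamic viscosity in mPa s.
#' @examples
#' water_viscosity(25)          # ~0.891 mPa s
#' water_viscosity(20) / water_viscosity(25)
#' @export
water_viscosity <- function(T_C) {
  if (any(!is.finite(T_C)) || any(T_C <= 0) || any(T_C >= 100))
    stop("parameter error: T_C must lie in (0, 100) deg C", call. = FALSE)
  exp(-3.7188 + 578.919 / (T_C + 273.15 - 137.546))
}

#' Viscosity factor for normalizing conductance to 25 deg C
#'
#' `eta(T_leaf) / eta(25 deg C)`: equals 1 at 25 deg C, falls below 1 for
#' warmer leaves (water is less viscous, so the same leaf conducts more and
#' its conductance is corrected downward).
#'
#' @param T_leaf_C Leaf temperature, deg C.
#' @return The dimensionless factor.
#' @export
viscosity_factor_25C <- function(T_leaf_C) {
  water_viscosity(T_leaf_C) / water_viscosity(25)
}

#' Normalize a conductance to the 25 deg C reference
#'
#' Standard viscosity normalization of hydraulic conductance:
#' `K_25 = K_raw * eta(T_leaf) / eta(25)`. This removes the purely physical
#' effect of temperature on water viscosity so that conductances measured
#' at different leaf temperatures are comparable.
#'
#' @param K_raw Conductance at leaf temperature
#'   (mmol m-2 s-1 MPa-1).
#' @param T_leaf_C Leaf temperature, deg C.
#' @return The normalized conductance.
#' @export
normalize_to_25C <- function(K_raw, T_leaf_C) {
  K_raw * viscosity_factor_25C(T_leaf_C)
}

#' Compute leaf hydraulic conductance from steady flow
#'
#' The evaporative flux method estimates leaf hydraulic conductance as the
#' steady transpirational flow divided by the water-potential driving
#' force, `K_leaf = E / (0 - psi_final)`, with `psi_final` the leaf water
#' potential at the end of the run (the reservoir water is at 0 MPa). The
#' raw value is additionally normalized to 25 deg C by the water-viscosity
#' ratio ([normalize_to_25C()]).
#'
#' @param E_mmol_m2_s Steady flow E (mmol m-2 s-1, >= 0).
#' @param psi_final_MPa Final leaf water potential (MPa, < 0).
#' @param T_leaf_C Leaf temperature (deg C) during the run.
#' @return An object of class `kleaf_result`: list with `E_mmol_m2_s`,
#'   `psi_final_MPa`, `T_leaf_C`, `K_raw`, `K_25`, `viscosity_factor`.
#' @examples
#' compute_kleaf(8.7, -0.31)   # K_raw = K_25 = 28.06 at 25 deg C
#' @export
compute_kleaf <- function(E_mmol_m2_s, psi_final_MPa, T_leaf_C = 25) {
  if (!is.finite(psi_final_MPa) || psi_final_MPa >= 0)
    stop("domain error: psi_final_MPa must be < 0 (undefined driving force otherwise)",
         call. = FALSE)
  if (!is.finite(E_mmol_m2_s) || E_mmol_m2_s < 0)
    stop("domain error: E_mmol_m2_s must be >= 0", call. = FALSE)
  K_raw <- E_mmol_m2_s / (0 - psi_final_MPa)
  vf <- viscosity_factor_25C(T_leaf_C)
  structure(list(E_mmol_m2_s = E_mmol_m2_s, psi_final_MPa = psi_final_MPa,
                 T_leaf_C = T_leaf_C, K_raw = K_raw, K_25 = K_raw * vf,
                 viscosity_factor = vf),
            class = "kleaf_result")
}

#' @export
print.kleaf_result <- function(x, ...) {
  cat(sprintf("<kleaf> E = %.4g mmol m-2 s-1, psi_final = %.3g MPa, T_leaf = %.3g C\n",
              x$E_mmol_m2_s, x$psi_final_MPa, x$T_leaf_C))
  cat(sprintf("  K_raw = %.4g, K_25 = %.4g mmol m-2 s-1 MPa-1 (viscosity factor %.4f)\n",
              x$K_raw, x$K_25, x$viscosity_factor))
  invisible(x)
}

#' Hydrostatic pressure of a water-column height offset
#'
#' `rho * g * h` in kPa, signed by the offset direction. In a typical EFM
#' setup the water surface sits about 2 cm below the leaf, which
#' corresponds to 0.196 kPa -- three orders of magnitude below typical
#' driving forces (tenths of MPa), which is why small height offsets do not
#' bias K_leaf.
#'
#' @param height_offset_m Signed height of the water surface relative to
#'   the leaf (m).
#' @param rho_kg_m3 Water density (kg m-3).
#' @param g_m_s2 Gravitational acceleration (m s-2).
#' @return Pressure in kPa.
#' @examples
#' hydrostatic_pressure_kPa(0.02)   # 0.196 kPa
#' @export
hydrostatic_pressure_kPa <- function(height_offset_m, rho_kg_m3 = 1000,
                                     g_m_s2 = 9.8) {
  rho_kg_m3 * g_m_s2 * height_offset_m / 1000
}

#' Sensitivity of K_leaf to its two inputs
#'
#' Evaluates `K_leaf = E / (0 - psi_final)` while varying one input at a
#' time over a relative-offset grid around a reference point: K is exactly
#' linear in E at fixed psi_final, and hyperbolic (proportional to
#' `1/|psi_final|`) in psi_final at fixed E. Because psi_final is typically
#' small in magnitude (above -0.5 MPa), a small absolute error in
#' psi_final moves K_leaf a lot -- the practical reason accurate water
#' potential measurement matters as much as accurate flow.
#'
#' @param E_ref Reference steady flow (mmol m-2 s-1).
#' @param psi_ref Reference final water potential (MPa, < 0).
#' @param rel_range Numeric grid of relative offsets (e.g.
#'   `seq(-0.5, 0.5, by = 0.1)`); the psi grid must not reach 0 MPa.
#' @return A `data.frame` with columns `parameter` ("E" or "psi_final"),
#'   `rel_offset`, `value` (the varied input), `K_leaf`.
#' @export
sensitivity_grid <- function(E_ref, psi_ref,
                             rel_range = seq(-0.5, 0.5, by = 0.05)) {
  if (!is.finite(psi_ref) || psi_ref >= 0)
    stop("domain error: psi_ref must be < 0", call. = FALSE)
  psi_grid <- psi_ref * (1 + rel_range)
  if (any(psi_grid >= 0))
    stop("domain error: psi_final grid crosses 0 MPa", call. = FALSE)
  e_grid <- E_ref * (1 + rel_range)
  rbind(
    data.frame(parameter = "E", rel_offset = rel_range, value = e_grid,
               K_leaf = e_grid / (0 - psi_ref)),
    data.frame(parameter = "psi_final", rel_offset = rel_range,
               value = psi_grid, K_leaf = E_ref / (0 - psi_grid)))
}

#' Percent decrease from a to b
#'
#' `100 * (a - b) / a`: the convention in which a conductance dropping from
#' 26.8 to 16.0 mmol m-2 s-1 MPa-1 is a 40% decrease.
#'
#' @param a Reference (nonzero) value.
#' @param b Comparison value.
#' @return Percent change (positive = decrease).
#' @export
percent_change <- function(a, b) {
  if (any(a == 0)) stop("domain error: reference value a must be nonzero",
                        call. = FALSE)
  100 * (a - b) / a
}
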