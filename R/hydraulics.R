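# Raw-measurement hydraulics: stem-specific conductivity, loss of
# conductivity from flow or conductance times, and xylem water balance.

M_WATER_KG_PER_MOL <- 0.018015

#' Stem-specific hydraulic conductivity
#'
#' \eqn{K_s = L \, (m/t) / (A \, p)}: mass flow rate per unit pressure
#' gradient, normalised by segment length and cross-sectional area.
#' All arguments are vectorised.
#'
#' @param length_m Segment length, m, `> 0`.
#' @param area_m2 Average cross-sectional area of both segment ends, m^2,
#'   `> 0`.
#' @param mass_kg Mass of water passed through the segment, kg, `>= 0`.
#' @param time_s Duration of the conductance measurement, s, `> 0`.
#' @param pressure_mpa Pressure difference driving the flow, MPa, `> 0`.
#' @return Conductivity in kg m^-1 s^-1 MPa^-1.
#' @examples
#' specific_conductivity(0.30, 1e-5, 6e-5, 60, 0.003)  # 10
#' @export
specific_conductivity <- function(length_m, area_m2, mass_kg, time_s,
                                  pressure_mpa) {
  if (any(length_m <= 0) || any(area_m2 <= 0))
    stop("segment length and area must be > 0", call. = FALSE)
  if (any(time_s <= 0) || any(pressure_mpa <= 0))
    stop("measurement time and pressure must be > 0", call. = FALSE)
  if (any(mass_kg < 0))
    stop("water mass must be >= 0", call. = FALSE)
  length_m * (mass_kg / time_s) / (area_m2 * pressure_mpa)
}

#' Loss of conductivity from conductivity measurements
#'
#' \eqn{LC_i = (K_m - K_{s,i}) / K_m}, the fractional drop of measured
#' conductivity below the flushed maximum.  Values below zero (measured
#' conductivity above the flushed maximum) are retained but flagged with a
#' warning: measurement quality control belongs to the caller.
#'
#' @param k_max Maximum (flushed) conductivity `K_m`, `> 0`.
#' @param k_s Measured conductivities, same units as `k_max`, `>= 0`.
#' @return Numeric vector of loss fractions.
#' @export
lc_from_conductivities <- function(k_max, k_s) {
  if (!is.numeric(k_max) || length(k_max) != 1L || k_max <= 0)
    stop("`k_max` must be a single value > 0", call. = FALSE)
  if (any(k_s < 0))
    stop("`k_s` must be >= 0", call. = FALSE)
  lc <- (k_max - k_s) / k_max
  if (any(lc < 0))
    warning("negative loss of conductivity: measured conductivity exceeds ",
            "the flushed maximum", call. = FALSE)
  lc
}

#' Loss of conductivity from conductance times
#'
#' With the hydraulic head and segment geometry held fixed across an
#' air-injection series, conductivity is inversely proportional to the time
#' a conductance measurement takes, so the loss of conductivity reduces to
#' \eqn{LC_i = 1 - T/t_i}, where `T` is the conductance time at the flushed
#' maximum.  Algebraically identical to [lc_from_conductivities()] applied
#' to [specific_conductivity()] outputs.
#'
#' Raw values are never clamped: a time shorter than the reference
#' (conductance above the flushed maximum) gives a negative LC, which is
#' flagged in the `supra_maximal` column and warned about.
#'
#' @param time_s Per-step conductance times, s, `> 0`.
#' @param reference_time_s Conductance time `T` at the flushed maximum
#'   `K_m`, s, `> 0`.
#' @param pressure_mpa Optional injection pressures paired with `time_s`,
#'   carried through to the output.
#' @return Data frame with columns `pressure_mpa` (if supplied), `time_s`,
#'   `lc`, and logical `supra_maximal`.
#' @examples
#' lc_from_times(c(120, 480), reference_time_s = 120)
#' @export
lc_from_times <- function(time_s, reference_time_s, pressure_mpa = NULL) {
  if (!is.numeric(reference_time_s) || length(reference_time_s) != 1L ||
      reference_time_s <= 0)
    stop("`reference_time_s` must be a single value > 0", call. = FALSE)
  if (any(time_s <= 0))
    stop("all conductance times must be > 0", call. = FALSE)
  lc <- 1 - reference_time_s / time_s
  flag <- lc < 0
  if (any(flag))
    warning(sum(flag), " step(s) with conductance above the flushed ",
            "maximum (negative LC)", call. = FALSE)
  out <- data.frame(time_s = time_s, lc = lc, supra_maximal = flag)
  if (!is.null(pressure_mpa)) {
    if (length(pressure_mpa) != length(time_s))
      stop("`pressure_mpa` and `time_s` lengths differ", call. = FALSE)
    out <- cbind(data.frame(pressure_mpa = pressure_mpa), out)
  }
  out
}

#' Xylem water gain
#'
#' Water mass per unit time that the xylem gains from the soil through its
#' remaining functional conduits:
#' \eqn{WG = K_m \, \Delta\Psi \, A \, (1 - LC) / L}.
#'
#' @param k_max Flushed maximum conductivity, kg m^-1 s^-1 MPa^-1.
#' @param delta_psi_mpa Magnitude of the soil-to-stem water-potential
#'   difference, MPa, `>= 0`.
#' @param area_m2 Stem cross-sectional area, m^2.
#' @param lc Current loss-of-conductivity fraction in `[0, 1]`.
#' @param length_m Segment length, m, `> 0`.
#' @return Water gain in kg s^-1.
#' @export
water_gain <- function(k_max, delta_psi_mpa, area_m2, lc, length_m) {
  if (any(lc < 0) || any(lc > 1))
    stop("`lc` must be a fraction in [0, 1]", call. = FALSE)
  if (any(length_m <= 0))
    stop("`length_m` must be > 0", call. = FALSE)
  if (any(delta_psi_mpa < 0))
    stop("`delta_psi_mpa` is a magnitude and must be >= 0", call. = FALSE)
  k_max * delta_psi_mpa * area_m2 * (1 - lc) / length_m
}

#' Xylem water loss through transpiration
#'
#' \eqn{WL = E \times LA}.  Transpiration is measured in mol m^-2 s^-1, so
#' by default the product is converted to a mass flow with the molar mass
#' of water (0.018015 kg mol^-1), giving kg s^-1 on the same scale as
#' [water_gain()]; `convert_to_kg = FALSE` returns the bare molar flux in
#' mol s^-1.
#'
#' @param e_mol Transpiration rate, mol m^-2 s^-1, `>= 0`.
#' @param leaf_area_m2 Total leaf area, m^2, `>= 0`.
#' @param convert_to_kg Multiply by the molar mass of water (default).
#' @return Water loss in kg s^-1 (default) or mol s^-1.
#' @export
water_loss <- function(e_mol, leaf_area_m2, convert_to_kg = TRUE) {
  if (any(e_mol < 0) || any(leaf_area_m2 < 0))
    stop("transpiration rate and leaf area must be >= 0", call. = FALSE)
  wl <- e_mol * leaf_area_m2
  if (isTRUE(convert_to_kg)) wl * M_WATER_KG_PER_MOL else wl
}

#' Net xylem water balance
#'
#' Convenience wrapper returning water gain, water loss, and their
#' difference (`net = WG - WL`), the net water resource the xylem gains
#' from the soil.
#'
#' @inheritParams water_gain
#' @inheritParams water_loss
#' @return A list with `wg`, `wl` and `net`, all in kg s^-1.
#' @export
water_balance <- function(k_max, delta_psi_mpa, area_m2, lc, length_m,
                          e_mol, leaf_area_m2, convert_to_kg = TRUE) {
  wg <- water_gain(k_max, delta_psi_mpa, area_m2, lc, length_m)
  wl <- water_loss(e_mol, leaf_area_m2, convert_to_kg)
  list(wg = wg, wl = wl, net = wg - wl)
}

#' Hydrostatic pressure of a water column
#'
#' \eqn{p = \rho g h \times 10^{-6}} MPa with \eqn{\rho} = 1000 kg m^-3 and
#' \eqn{g} = 9.81 m s^-2; converts the hydraulic head driving a
#' conductivity measurement into MPa.
#'
#' @param height_m Head height, m, `>= 0`.
#' @return Pressure in MPa.
#' @examples
#' head_to_pressure(0.30)  # ~0.0029 MPa for a 30 cm head
#' @export
head_to_pressure <- function(height_m) {
  if (any(height_m < 0))
    stop("`height_m` must be >= 0", call. = FALSE)
  1000 * 9.81 * height_m * 1e-6
}
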