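# Intravital-microscopy scalar quantities: vessel permeability from
# fluorescence line-profile time series, and the microvessel-density-ratio
# blood volume.

#' Fluorescence trace around a vessel
#'
#' @param times Acquisition times in s, increasing.
#' @param f_vessel Plasma fluorescence inside the vessel (`F_v`), one value
#'   per time point (or a constant).
#' @param f_outside Fluorescence immediately outside the vessel (`F_i`).
#' @param positions Line-profile sample positions in um, perpendicular to
#'   the flow axis, centered on the vessel (0 at the vessel axis).
#' @param profile Matrix `length(times) x length(positions)` of
#'   fluorescence intensities `F(x, t)`.
#' @param vessel_radius Vessel radius in um.
#' @export
fluorescence_trace <- function(times, f_vessel, f_outside, positions, profile,
                               vessel_radius) {
  times <- as.numeric(times)
  if (length(times) < 3L) stop_domain("fluorescence_trace: need >= 3 time points")
  if (any(diff(times) <= 0)) stop_domain("fluorescence_trace: times must increase")
  if (vessel_radius <= 0) stop_domain("fluorescence_trace: vessel_radius must be > 0")
  f_vessel <- rep_len(as.numeric(f_vessel), length(times))
  f_outside <- rep_len(as.numeric(f_outside), length(times))
  profile <- as.matrix(profile)
  if (!all(dim(profile) == c(length(times), length(positions))))
    stop_domain("fluorescence_trace: profile must be times x positions")
  if (any(profile < 0) || any(f_vessel < 0) || any(f_outside < 0))
    stop_domain("fluorescence_trace: intensities must be >= 0")
  structure(list(times = times, f_vessel = f_vessel, f_outside = f_outside,
                 positions = as.numeric(positions), profile = profile,
                 vessel_radius = vessel_radius),
            class = "fluorescence_trace")
}

#' Vessel permeability from a fluorescence trace
#'
#' Line-profile permeability estimate
#'
#'   `P = h * (r/2) * d/dt [ (1/r) * integral_{|x|>r} F(x,t) dx ] / (Fv - Fi)`
#'
#' i.e. the slope (by linear regression over time) of the lumen-excluded,
#' radius-normalized extravascular line integral, scaled by the
#' plasma-to-interstitium contrast `Fv - Fi`; the explicit radius cancels
#' against the normalization, leaving units of um/s when positions are in
#' um. The optional hematocrit multiplier `h = (1 - HT)` defaults to 1.
#' The estimate is invariant to affine intensity recalibration applied
#' uniformly (a gain cancels in the ratio; a constant offset adds a
#' time-constant term with zero slope and cancels in `Fv - Fi`).
#'
#' @param trace A [fluorescence_trace()].
#' @param hematocrit_factor Multiplier `(1 - HT)`, default 1.
#' @return List with `p` (um/s), `slope` (raw integral slope), and a
#'   `negative_slope` flag (a negative leak estimate is reported, flagged,
#'   rather than clamped).
#' @export
permeability_from_trace <- function(trace, hematocrit_factor = 1) {
  contrast <- mean(trace$f_vessel - trace$f_outside)
  if (contrast <= 0)
    stop_domain("permeability_from_trace: contrast error - F_v must exceed F_i")
  left <- trace$positions < -trace$vessel_radius
  right <- trace$positions > trace$vessel_radius
  if (sum(left) + sum(right) < 2L)
    stop_domain("permeability_from_trace: no extravascular samples on the line")
  # integrate the two extravascular sides separately (no bridge across the lumen)
  f_tot <- vapply(seq_along(trace$times), function(i)
    trapz(trace$positions[left], trace$profile[i, left]) +
      trapz(trace$positions[right], trace$profile[i, right]), 0)
  slope <- stats::coef(stats::lm(f_tot ~ trace$times))[[2]]
  p <- hematocrit_factor * slope / (2 * contrast)
  list(p = p, slope = slope, negative_slope = p < 0)
}

#' Microvessel-density pair
#' @param mvd_tumor,mvd_cortex Vessel counts per unit area, both `> 0`.
#' @export
mvd_pair <- function(mvd_tumor, mvd_cortex) {
  if (mvd_cortex <= 0) stop_domain("mvd_pair: domain error - cortex MVD must be > 0")
  if (mvd_tumor <= 0) stop_domain("mvd_pair: domain error - tumor MVD must be > 0")
  structure(list(mvd_tumor = mvd_tumor, mvd_cortex = mvd_cortex),
            class = "mvd_pair")
}

#' IVM relative cerebral blood volume
#'
#' Ratio of tumor to contralateral-cortex microvessel density — the optical
#' counterpart of the MRI rCBV.
#'
#' @param pair An [mvd_pair()].
#' @return Dimensionless ratio.
#' @export
rcbv_ivm <- function(pair) pair$mvd_tumor / pair$mvd_cortex
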