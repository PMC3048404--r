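# Relative vessel caliber index from delta-R2*, delta-R2 and ADC.

#' Relative vessel caliber index
#'
#' The vessel caliber index scales with the average vessel diameter through
#' the ratio of the delta-R2*-weighted (all-caliber) to delta-R2-weighted
#' (microvessel) blood volumes. Per ROI it is computed from ROI means as
#'
#'   `VCI = ADC^e_adc * (dR2*)^e_star * (dR2)^e_r2`
#'
#' with default exponents `(0.5, 1.5, -1.5)`, the vessel-size-index power
#' law; proportionality constants (susceptibility, field strength) cancel in
#' the tumor-over-cortex ratio `rVCI = VCI_tumor / VCI_cortex`. Setting the
#' exponents to `(0, 1, -1)` selects the pure blood-volume-ratio variant
#' `Q = dR2*/dR2`. ROI means are taken before the power law (not voxelwise)
#' to avoid noise amplification by the delta-R2 denominator; a voxelwise
#' mode is available behind `voxelwise = TRUE`.
#'
#' @param bv A `blood_volume_maps` from [relative_blood_volumes()].
#' @param adc An `adc_map` from [fit_adc()].
#' @param rois A [roi_set].
#' @param exponents Named list/vector with `adc`, `dr2_star`, `dr2`.
#' @param voxelwise Compute voxelwise VCI and then average per ROI.
#' @return A `vci_result` with `vci_tumor`, `vci_cortex` (arbitrary units)
#'   and the dimensionless `rvci`; non-positive ROI means raise a domain
#'   error.
#' @export
compute_rvci <- function(bv, adc, rois,
                         exponents = list(adc = 0.5, dr2_star = 1.5, dr2 = -1.5),
                         voxelwise = FALSE) {
  e <- exponents
  vci_fun <- function(adc_m, dr2s_m, dr2_m)
    adc_m^e$adc * dr2s_m^e$dr2_star * dr2_m^e$dr2

  roi_vci <- function(mask) {
    if (voxelwise) {
      ok <- mask & bv$delta_r2$valid_mask & bv$delta_r2_star$valid_mask &
        adc$valid_mask & bv$delta_r2$delta > 0 & bv$delta_r2_star$delta > 0
      if (!any(ok)) stop_domain("compute_rvci: domain error - no usable voxels")
      return(mean(vci_fun(adc$adc[ok], bv$delta_r2_star$delta[ok],
                          bv$delta_r2$delta[ok])))
    }
    m_adc <- mean(adc$adc[mask & adc$valid_mask])
    m_dr2s <- roi_mean(bv$delta_r2_star, mask)
    m_dr2 <- roi_mean(bv$delta_r2, mask)
    if (!is.finite(m_adc) || !is.finite(m_dr2s) || !is.finite(m_dr2) ||
        m_adc <= 0 || m_dr2s <= 0 || m_dr2 <= 0)
      stop_domain("compute_rvci: domain error - non-positive ROI mean")
    vci_fun(m_adc, m_dr2s, m_dr2)
  }

  vt <- roi_vci(rois$tumor_mask)
  vc <- roi_vci(rois$cortex_mask)
  structure(list(vci_tumor = vt, vci_cortex = vc, rvci = vt / vc,
                 exponents = e),
            class = "vci_result")
}
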