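# Shared fixtures: a reduced phantom geometry for fast cohort tests, and
# hand-built uniform series for closed-form checks.

small_spec <- function(n_per_arm = 2, seed = 11, noise_sigma = 0.02) {
  cohort_spec(n_per_arm = n_per_arm, seed = seed, noise_sigma = noise_sigma,
              grid_dim = c(40, 40, 9), tumor_center_vox = c(13, 20, 5),
              tumor_radius_mm = 0.8, cortex_radius_mm = 0.8,
              max_tumor_radius_mm = 1.3)
}

cv0_profile <- function(arm) default_profile(arm, cv_scale = 0)

# Uniform-tissue multi-echo series with known T2 (ms); no background air,
# so relaxometry tests on it use noise_k = 0.
uniform_multiecho <- function(t2_ms, echo_times = seq(10, 100, by = 10),
                              dims = c(6, 6, 2), s0 = 100, sigma = 0,
                              seed = 1, sequence = "spin_echo",
                              contrast_state = "pre_spion") {
  vols <- withr::with_seed(seed, lapply(echo_times, function(te) {
    s <- array(s0 * exp(-te / t2_ms), dims)
    image_volume(rician_noise(s, sigma))
  }))
  multiecho_series(vols, echo_times, sequence, contrast_state)
}

uniform_dwi <- function(adc, b_values = c(0, 756, 1506), dims = c(6, 6, 2),
                        s0 = 100, sigma = 0, seed = 1) {
  vols <- withr::with_seed(seed, lapply(b_values, function(b) {
    s <- array(s0 * exp(-b * adc), dims)
    image_volume(rician_noise(s, sigma))
  }))
  dwi_series(vols, b_values)
}

# Hand-built relaxation-rate difference maps with uniform tumor/cortex
# deltas, plus matching ROI set: tumor = first half of x, cortex = rest.
toy_maps <- function(d2_t, d2_c, d2s_t, d2s_c, adc_t = 7e-4, adc_c = 7e-4,
                     dims = c(6, 4, 2)) {
  tumor <- array(FALSE, dims); tumor[1:3, , ] <- TRUE
  cortex <- !tumor
  rois <- roi_set(tumor, cortex)
  dmap <- function(vt, vc) {
    delta <- array(vc, dims); delta[tumor] <- vt
    structure(list(delta = delta, valid_mask = array(TRUE, dims),
                   negative = array(FALSE, dims), sequence = "spin_echo"),
              class = "delta_r_map")
  }
  adc <- array(adc_c, dims); adc[tumor] <- adc_t
  adc_map <- structure(list(adc = adc, s0 = array(100, dims),
                            valid_mask = array(TRUE, dims)),
                       class = "adc_map")
  bv <- relative_blood_volumes(dmap(d2_t, d2_c), dmap(d2s_t, d2s_c), rois)
  list(bv = bv, adc = adc_map, rois = rois)
}

# Encoded percent change implied by a profile for one biomarker.
encoded_change <- function(profile, field) 100 * (profile$factors[[field]] - 1)

encoded_rvci_change <- function(profile,
                                e = list(adc = 0.5, dr2_star = 1.5, dr2 = -1.5)) {
  f <- profile$factors
  100 * (f$adc^e$adc * f$dr2_star^e$dr2_star * f$dr2^e$dr2 - 1)
}
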