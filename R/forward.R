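# Forward MRI signal models over ground-truth phantoms.
#
# All magnitude images carry Rician noise (Gaussian noise on the two complex
# channels); sigma is expressed as a fraction of the mean baseline tissue
# signal of the series, so noise_sigma = 0.02 corresponds to SNR 50.

#' Apply Rician noise to a magnitude image
#'
#' @param signal Numeric array of noiseless magnitudes.
#' @param sigma Gaussian sigma of each complex channel (absolute units).
#' @return Array of noisy magnitudes; `sigma = 0` returns the input.
#' @export
rician_noise <- function(signal, sigma) {
  if (sigma == 0) return(signal)
  n <- length(signal)
  re <- signal + stats::rnorm(n, 0, sigma)
  im <- stats::rnorm(n, 0, sigma)
  out <- sqrt(re^2 + im^2)
  dim(out) <- dim(signal)
  out
}

# absolute noise sigma for a series, from its first noiseless frame
abs_sigma <- function(first_frame, tissue, noise_sigma) {
  if (noise_sigma == 0) return(0)
  noise_sigma * mean(first_frame[tissue])
}

#' Forward-simulate a multi-echo series
#'
#' Mono-exponential decay `S(TE) = S0 exp(-TE * R)` with `R = 1/T2` (spin
#' echo) or `1/T2*` (gradient echo); in the post-SPION state the rate is
#' increased by the ground-truth delta-R2 or delta-R2*.
#'
#' @param phantom A `ground_truth_phantom`.
#' @param sequence `"spin_echo"` or `"gradient_echo"`.
#' @param contrast_state `"pre_spion"` or `"post_spion"`.
#' @param echo_times Echo times in ms (defaults per sequence).
#' @param noise_sigma Fraction of mean baseline tissue signal.
#' @param seed Integer seed for the noise stream.
#' @return A [multiecho_series].
#' @export
forward_multiecho <- function(phantom, sequence = c("spin_echo", "gradient_echo"),
                              contrast_state = c("pre_spion", "post_spion"),
                              echo_times = NULL, noise_sigma = 0, seed = 1L) {
  sequence <- match.arg(sequence)
  contrast_state <- match.arg(contrast_state)
  if (is.null(echo_times)) echo_times <- default_echo_times(sequence)
  rate <- if (sequence == "spin_echo") 1000 / phantom$t2 else 1000 / phantom$t2_star
  if (contrast_state == "post_spion")
    rate <- rate + if (sequence == "spin_echo") phantom$delta_r2 else phantom$delta_r2_star
  tissue <- phantom$labels != "background"
  sig1 <- phantom$s0 * exp(-echo_times[1] / 1000 * rate)
  sigma <- abs_sigma(sig1, tissue, noise_sigma)
  vols <- with_local_seed(seed, lapply(echo_times, function(te) {
    s <- phantom$s0 * exp(-te / 1000 * rate)
    image_volume(rician_noise(s, sigma), voxel_size = phantom$voxel_size)
  }))
  multiecho_series(vols, echo_times, sequence, contrast_state)
}

#' Forward-simulate a diffusion-weighted series
#'
#' `S(b) = S0 exp(-b * ADC)`; the b = 0 frame equals S0 at zero noise.
#'
#' @inheritParams forward_multiecho
#' @param b_values b-values in s/mm^2.
#' @return A [dwi_series].
#' @export
forward_dwi <- function(phantom, b_values = c(0, 756, 1506), noise_sigma = 0,
                        seed = 1L) {
  tissue <- phantom$labels != "background"
  sigma <- abs_sigma(phantom$s0, tissue, noise_sigma)
  vols <- with_local_seed(seed, lapply(b_values, function(b) {
    s <- phantom$s0 * exp(-b * phantom$adc)
    image_volume(rician_noise(s, sigma), voxel_size = phantom$voxel_size)
  }))
  dwi_series(vols, b_values)
}

#' Forward-simulate a T2-weighted anatomical volume
#'
#' RARE-style T2 weighting at a long effective echo time; the tumor's longer
#' T2 renders it hyperintense against cortex, which is what the
#' tumor-volume segmentation consumes.
#'
#' @inheritParams forward_multiecho
#' @param te_eff Effective echo time in ms.
#' @return An [image_volume].
#' @export
forward_t2w <- function(phantom, te_eff = 60, noise_sigma = 0, seed = 1L) {
  s <- phantom$s0 * exp(-te_eff / 1000 * (1000 / phantom$t2))
  tissue <- phantom$labels != "background"
  sigma <- abs_sigma(s, tissue, noise_sigma)
  out <- with_local_seed(seed, rician_noise(s, sigma))
  image_volume(out, voxel_size = phantom$voxel_size)
}

#' Forward-simulate a DCE series
#'
#' Spoiled-gradient-echo signal dynamics through the Tofts two-compartment
#' model: pre-injection frames sit at the baseline SPGR signal for
#' `R1 = R1(0)`; post-injection frames follow the closed-form tissue
#' concentration driven by the bi-exponential AIF, converted to `R1(t)` via
#' the contrast-agent relaxivity and to signal via the SPGR equation. The
#' same model primitives ([tissue_concentration()], [r1_dynamics()],
#' [spgr_signal()]) serve the fitting path.
#'
#' @param phantom A `ground_truth_phantom`.
#' @param aif An [aif_parameters()].
#' @param constants An [acquisition_constants()].
#' @param n_frames Number of repetitions.
#' @param dt_s Temporal resolution in seconds.
#' @param tr,flip_angle,te SPGR sequence parameters (ms, degrees, ms).
#' @param injection_index 1-based index of the last pre-contrast frame.
#' @param slice Slice index through the tumor (defaults to the tumor center).
#' @param noise_sigma,seed Noise controls as in [forward_multiecho()].
#' @return A [dce_series] (single slice).
#' @export
forward_dce <- function(phantom, aif = aif_parameters(),
                        constants = acquisition_constants(),
                        n_frames = 100, dt_s = 4.8, tr = 50, flip_angle = 35,
                        te = 2.5, injection_index = 7L, slice = NULL,
                        noise_sigma = 0, seed = 1L) {
  if (is.null(slice)) slice <- phantom$truth$slice %||% ceiling(dim(phantom$s0)[3] / 2)
  kt <- phantom$ktrans[, , slice]
  ve <- phantom$ve[, , slice]
  if (any(kt > 0 & ve <= 0))
    stop_domain("forward_dce: degenerate parameters - ktrans > 0 with ve = 0")
  s0 <- phantom$s0[, , slice]
  times <- (seq_len(n_frames) - 1) * dt_s
  t0 <- times[injection_index]
  base <- s0 * spgr_signal(phantom$r1_0, tr, flip_angle)

  nz <- which(kt > 0 & s0 > 0)
  frames <- lapply(seq_len(n_frames), function(i) {
    if (times[i] <= t0) return(base)
    f <- base
    if (length(nz)) {
      tmin <- (times[i] - t0) / 60
      ct <- tissue_concentration(tmin, ktrans = kt[nz], ve = ve[nz], aif = aif)
      r1 <- r1_dynamics(ct, phantom$r1_0, constants$r1_gd)
      f[nz] <- s0[nz] * spgr_signal(r1, tr, flip_angle)
    }
    f
  })
  tissue <- phantom$labels[, , slice] != "background"
  sigma <- abs_sigma(base, tissue, noise_sigma)
  frames <- with_local_seed(seed, lapply(frames, rician_noise, sigma = sigma))
  s <- dce_series(frames, frame_times = times, tr = tr, flip_angle = flip_angle,
                  te = te, injection_index = injection_index)
  attr(s, "voxel_size") <- phantom$voxel_size
  attr(s, "slice") <- slice
  s
}
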