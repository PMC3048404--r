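# Shared domain types for the imaging pipeline. All containers are plain S3
# lists with constructors that validate their invariants; every downstream
# stage consumes only these typed objects, never raw files.

#' Image volume
#'
#' A 3D scalar grid (arbitrary signal units) with voxel geometry. Voxel
#' indices are 1-based in R; world coordinates are carried by the affine.
#'
#' @param data 3D numeric array.
#' @param voxel_size Numeric length-3, voxel edge lengths in mm (dx, dy, dz).
#' @param affine 4x4 voxel-to-world transform; defaults to a scaling by
#'   `voxel_size`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, voxel_size = c(0.15, 0.15, 0.5), affine = NULL) {
  data <- as.array(data)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L) stop_domain("image_volume: data must be a 3D array")
  if (any(dim(data) < 1L)) stop_domain("image_volume: all dimensions must be >= 1")
  if (!all(is.finite(data))) stop_domain("image_volume: data values must be finite")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop_domain("image_volume: voxel sizes must be three positive numbers")
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop_domain("image_volume: affine must be a 4x4 matrix")
  structure(list(data = data, voxel_size = voxel_size, affine = affine),
            class = "image_volume")
}

#' Voxel volume in mm^3
#' @param vol An `image_volume` (or anything with a `voxel_size` field).
#' @export
voxel_volume <- function(vol) prod(vol$voxel_size)

default_echo_times <- function(sequence) {
  switch(sequence,
    spin_echo     = seq(10, 100, by = 10),   # ms, 10 echoes
    gradient_echo = seq(2.5, 20, by = 2.5),  # ms, 8 echoes
    stop_domain("unknown sequence: ", sequence))
}

#' Multi-echo image series
#'
#' Ordered echo volumes from a multi-echo spin-echo or gradient-echo
#' acquisition, before or after intravascular iron-oxide (SPION) injection.
#'
#' @param volumes List of [image_volume] objects, one per echo.
#' @param echo_times Echo times in ms, strictly increasing, one per volume.
#' @param sequence `"spin_echo"` or `"gradient_echo"`.
#' @param contrast_state `"pre_spion"` or `"post_spion"`.
#' @return An object of class `multiecho_series`.
#' @export
multiecho_series <- function(volumes, echo_times = NULL,
                             sequence = c("spin_echo", "gradient_echo"),
                             contrast_state = c("pre_spion", "post_spion")) {
  sequence <- match.arg(sequence)
  contrast_state <- match.arg(contrast_state)
  if (is.null(echo_times)) echo_times <- default_echo_times(sequence)
  echo_times <- as.numeric(echo_times)
  if (!all(vapply(volumes, inherits, logical(1), "image_volume")))
    stop_domain("multiecho_series: volumes must be image_volume objects")
  if (length(volumes) != length(echo_times))
    stop_domain("multiecho_series: echo count mismatch: ", length(volumes),
                " volumes vs ", length(echo_times), " echo times")
  if (length(echo_times) && any(diff(echo_times) <= 0))
    stop_domain("multiecho_series: echo_times must be strictly increasing")
  dims <- vapply(volumes, function(v) dim(v$data), integer(3))
  if (length(volumes) > 1L && any(dims != dims[, 1]))
    stop_domain("multiecho_series: all echo volumes must share a grid")
  structure(list(volumes = volumes, echo_times = echo_times,
                 sequence = sequence, contrast_state = contrast_state),
            class = "multiecho_series")
}

#' Diffusion-weighted image series
#'
#' @param volumes List of [image_volume] objects, one per b-value.
#' @param b_values b-values in s/mm^2, non-negative; the first must be 0.
#' @return An object of class `dwi_series`.
#' @export
dwi_series <- function(volumes, b_values = c(0, 756, 1506)) {
  b_values <- as.numeric(b_values)
  if (!all(vapply(volumes, inherits, logical(1), "image_volume")))
    stop_domain("dwi_series: volumes must be image_volume objects")
  if (length(volumes) != length(b_values))
    stop_domain("dwi_series: volume count mismatch: ", length(volumes),
                " volumes vs ", length(b_values), " b-values")
  if (any(b_values < 0)) stop_domain("dwi_series: b-values must be non-negative")
  if (b_values[1] != 0) stop_domain("dwi_series: first b-value must be 0")
  if (length(unique(b_values)) < 2L)
    stop_domain("dwi_series: need at least 2 distinct b-values")
  structure(list(volumes = volumes, b_values = b_values), class = "dwi_series")
}

#' Dynamic contrast-enhanced series
#'
#' Time-ordered single-slice frames from a T1-weighted spoiled gradient-echo
#' acquisition during contrast-agent passage.
#'
#' @param frames List of 2D numeric matrices (one image slice per frame).
#' @param frame_times Frame acquisition times in s, uniformly spaced.
#' @param tr Repetition time in ms.
#' @param flip_angle Flip angle in degrees, in (0, 90].
#' @param te Echo time in ms.
#' @param injection_index 1-based index of the last pre-contrast frame;
#'   contrast arrives at `frame_times[injection_index]`.
#' @return An object of class `dce_series`.
#' @export
dce_series <- function(frames, frame_times, tr = 50, flip_angle = 35,
                       te = 2.5, injection_index = 7L) {
  frame_times <- as.numeric(frame_times)
  if (length(frames) != length(frame_times))
    stop_domain("dce_series: frame count mismatch")
  if (length(frame_times) >= 3L) {
    dt <- diff(frame_times)
    if (any(abs(dt - dt[1]) > 1e-9 + 1e-6 * abs(dt[1])))
      stop_domain("dce_series: frame_times must be uniformly spaced")
  }
  if (flip_angle <= 0 || flip_angle > 90)
    stop_domain("dce_series: flip angle must be in (0, 90]")
  injection_index <- as.integer(injection_index)
  if (injection_index <= 0L || injection_index >= length(frames))
    stop_domain("dce_series: injection_index must satisfy 0 < index < n_frames")
  structure(list(frames = frames, frame_times = frame_times, tr = tr,
                 flip_angle = flip_angle, te = te,
                 injection_index = injection_index),
            class = "dce_series")
}

#' Region-of-interest set
#'
#' Tumor and contralateral-cortex masks in the voxel space of their series.
#' All "relative" biomarkers (rCBV, rMBV, rVCI) are tumor-over-cortex ratios,
#' so the two masks must be disjoint.
#'
#' @param tumor_mask,cortex_mask Logical arrays on a common grid.
#' @export
roi_set <- function(tumor_mask, cortex_mask) {
  tumor_mask <- as.array(tumor_mask); cortex_mask <- as.array(cortex_mask)
  if (!identical(dim(tumor_mask), dim(cortex_mask)))
    stop_domain("roi_set: masks must share a grid")
  if (any(tumor_mask & cortex_mask))
    stop_domain("roi_set: tumor and cortex masks must be disjoint")
  structure(list(tumor_mask = tumor_mask == TRUE, cortex_mask = cortex_mask == TRUE),
            class = "roi_set")
}

#' Acquisition constants
#'
#' Field- and agent-level constants: Gd-DTPA longitudinal relaxivity `r1_gd`
#' (mM^-1 s^-1), SPION transverse relaxivity `r2_spion` (40 mM^-1 s^-1),
#' field strength `b0` (9.4 T) and Gd dose (mmol/kg).
#'
#' @param r1_gd,r2_spion,b0,gd_dose Positive numerics.
#' @export
acquisition_constants <- function(r1_gd = 3.3, r2_spion = 40, b0 = 9.4,
                                  gd_dose = 0.3) {
  vals <- c(r1_gd = r1_gd, r2_spion = r2_spion, b0 = b0, gd_dose = gd_dose)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_domain("acquisition_constants: all constants must be positive (",
                paste(names(vals)[vals <= 0 | !is.finite(vals)], collapse = ", "), ")")
  structure(as.list(vals), class = "acquisition_constants")
}

#' Bi-exponential arterial-input-function parameters
#'
#' Plasma concentration model `Cp(t) = D (a1 e^{-m1 t} + a2 e^{-m2 t})` with
#' `t` in minutes since injection: the fast term describes plasma/extracellular
#' equilibration, the slow term renal clearance, and `D` is the injected dose
#' in mmol/kg so that `D * a_i` is in mM.
#'
#' @param a1,a2 Amplitudes in kg/L (positive).
#' @param m1,m2 Decay rates in min^-1 with `m1 > m2 > 0`.
#' @param dose Dose in mmol/kg.
#' @export
aif_parameters <- function(a1 = 3.99, m1 = 0.144, a2 = 4.78, m2 = 0.0111,
                           dose = 0.3) {
  if (a1 <= 0 || a2 <= 0) stop_domain("aif_parameters: amplitudes must be positive")
  if (!(m1 > m2 && m2 > 0)) stop_domain("aif_parameters: need m1 > m2 > 0")
  if (dose <= 0) stop_domain("aif_parameters: dose must be positive")
  structure(list(a1 = a1, m1 = m1, a2 = a2, m2 = m2, dose = dose),
            class = "aif_parameters")
}

#' 4D signal array (x, y, z, echo/b-value) from a series object
#' @param series A [multiecho_series] or [dwi_series].
#' @return 4D numeric array.
#' @export
signal_array <- function(series) {
  vols <- if (inherits(series, "dwi_series") || inherits(series, "multiecho_series"))
    series$volumes else stop_domain("signal_array: unsupported series type")
  arr <- vapply(vols, function(v) v$data, vols[[1]]$data)
  arr
}
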