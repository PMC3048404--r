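# ADC mapping from multi-b-value diffusion-weighted imaging.

#' Voxelwise apparent-diffusion-coefficient fit
#'
#' Ordinary (unweighted) linear least squares of the natural log of the
#' signal against b-value; the negated slope is the ADC. With exactly two
#' b-values this reduces to `ADC = log(S0/S1) / (b1 - b0)`. Voxels with a
#' non-positive signal at any b-value are invalid, as are fitted ADCs
#' outside `(0, 1e-2)` mm^2/s (free-water diffusivity sanity bound).
#' The estimate is invariant to global signal scaling and to b-value
#' ordering.
#'
#' @param series A [dwi_series] with >= 2 distinct b-values.
#' @return An `adc_map` with per-voxel `adc` (mm^2/s), amplitude `s0`, and
#'   `valid_mask`.
#' @export
fit_adc <- function(series) {
  arr <- signal_array(series)
  d <- dim(arr)[1:3]
  b <- series$b_values
  v <- matrix(arr, ncol = length(b))
  valid <- rowSums(v <= 0) == 0

  y <- log(pmax(v, .Machine$double.xmin))
  n <- length(b)
  bbar <- mean(b)
  ybar <- rowMeans(y)
  slope <- (y %*% (b - bbar)) / sum((b - bbar)^2)
  adc <- -as.numeric(slope)
  s0 <- exp(ybar + adc * bbar)

  valid <- valid & is.finite(adc) & adc > 0 & adc < 1e-2
  adc[!valid] <- NA_real_
  structure(list(adc = array(adc, d), s0 = array(s0, d),
                 valid_mask = array(valid, d), b_values = b),
            class = "adc_map")
}
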