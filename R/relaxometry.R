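# Voxelwise T2/T2* relaxometry and SPION blood-volume mapping.
#
# Model: S(TE) = S0 exp(-TE * R) per voxel. The log-linear path is a
# weighted least-squares fit of log signal (weights S^2, the first-order
# variance correction for log-transformed Gaussian noise); the nonlinear
# path refines it by Levenberg-Marquardt. Blood-volume weighting follows
# the steady-state susceptibility-contrast convention: delta-R2* (all
# vessel calibers) for rCBV, delta-R2 (microvessels) for rMBV, each as the
# tumor-over-contralateral-cortex ratio of ROI-mean rate changes.

#' Estimate background noise sigma from corner patches
#'
#' Air voxels of a magnitude image contain pure Rician noise with mean
#' `sigma * sqrt(pi/2)`; the in-plane corner patches of the first echo are
#' averaged and inverted through that relation.
#'
#' @param vol 3D array (first-echo signal).
#' @param patch Corner patch edge length in voxels.
#' @return Estimated Gaussian sigma of the complex channels.
#' @export
estimate_noise_sigma <- function(vol, patch = 3) {
  d <- dim(vol)
  ix <- c(seq_len(patch), d[1] - seq_len(patch) + 1L)
  iy <- c(seq_len(patch), d[2] - seq_len(patch) + 1L)
  mean(vol[ix, iy, ]) / sqrt(pi / 2)
}

#' Voxelwise mono-exponential relaxation fit
#'
#' @param series A [multiecho_series] with >= 3 echoes.
#' @param method `"loglinear"` (weighted LS on log signal, the default) or
#'   `"nlls"` (Levenberg-Marquardt seeded by the log-linear fit).
#' @param noise_k Voxels whose first-echo signal falls below
#'   `noise_k * sigma` (sigma from [estimate_noise_sigma()]) are invalid.
#' @return A `relaxation_map`: per-voxel `rate` (R2 or R2*, s^-1), amplitude
#'   `s0`, `fit_quality` (R-squared of the log fit) and `valid_mask`.
#'   Degenerate voxels (non-positive signal, non-positive rate) are invalid;
#'   an all-invalid volume yields an empty-map warning, not an error.
#' @export
fit_relaxation <- function(series, method = c("loglinear", "nlls"),
                           noise_k = 3) {
  method <- match.arg(method)
  if (length(series$echo_times) < 3L)
    stop_domain("fit_relaxation: need >= 3 echoes")
  arr <- signal_array(series)
  d <- dim(arr)[1:3]
  te_s <- series$echo_times / 1000
  v <- matrix(arr, ncol = length(te_s))

  sigma <- estimate_noise_sigma(array(v[, 1], d))
  valid <- v[, 1] > noise_k * sigma & matrixStats_all_positive(v)

  y <- log(pmax(v, .Machine$double.xmin))
  w <- v^2
  sw <- rowSums(w); swx <- w %*% te_s; swx2 <- w %*% te_s^2
  swy <- rowSums(w * y); swxy <- (w * y) %*% te_s
  det <- sw * swx2 - swx^2
  slope <- (sw * swxy - swx * swy) / det
  inter <- (swx2 * swy - swx * swxy) / det
  rate <- -as.numeric(slope)
  s0 <- exp(as.numeric(inter))

  yhat <- outer(as.numeric(inter), rep(1, length(te_s))) +
    outer(as.numeric(slope), te_s)
  ybar <- swy / sw
  r2 <- 1 - rowSums(w * (y - yhat)^2) / pmax(rowSums(w * (y - ybar)^2), 1e-300)
  r2 <- pmin(pmax(as.numeric(r2), 0), 1)

  valid <- valid & is.finite(rate) & rate > 0

  if (method == "nlls") {
    idx <- which(valid)
    for (i in idx) {
      fit <- tryCatch(
        minpack.lm::nls.lm(par = c(s0[i], rate[i]),
                           fn = function(p) v[i, ] - p[1] * exp(-te_s * p[2]),
                           lower = c(0, 0),
                           control = minpack.lm::nls.lm.control(maxiter = 100)),
        error = function(e) NULL)
      if (!is.null(fit) && fit$info %in% 1:4) {
        s0[i] <- fit$par[1]; rate[i] <- fit$par[2]
        tss <- sum((v[i, ] - mean(v[i, ]))^2)
        r2[i] <- 1 - fit$deviance / max(tss, 1e-300)
      }
    }
    valid <- valid & rate > 0
  }

  if (!any(valid)) warning("fit_relaxation: empty map (no valid voxels)")
  rate[!valid] <- NA_real_
  structure(list(rate = array(rate, d), s0 = array(s0, d),
                 fit_quality = array(r2, d), valid_mask = array(valid, d),
                 sequence = series$sequence,
                 contrast_state = series$contrast_state,
                 sigma = sigma),
            class = "relaxation_map")
}

# all echoes strictly positive, rowwise
matrixStats_all_positive <- function(v) rowSums(v <= 0) == 0

#' Voxelwise relaxation-rate difference map
#'
#' `delta-R = R_post - R_pre` from a pre/post-SPION pair of maps of the same
#' sequence on the same grid. Negative voxels (noise) are retained unbiased
#' in downstream ROI means but flagged; `clamp = TRUE` zeroes them for map
#' display only.
#'
#' @param pre,post `relaxation_map`s (pre- and post-SPION).
#' @param clamp Zero negative voxels (display mode).
#' @return A `delta_r_map` with `delta` (s^-1), `valid_mask` and a
#'   `negative` flag array.
#' @export
delta_r_maps <- function(pre, post, clamp = FALSE) {
  if (!identical(dim(pre$rate), dim(post$rate)))
    stop_domain("delta_r_maps: dimension error - maps on different grids")
  if (!identical(pre$sequence, post$sequence))
    stop_domain("delta_r_maps: pre and post must come from the same sequence")
  delta <- post$rate - pre$rate
  valid <- pre$valid_mask & post$valid_mask
  negative <- valid & !is.na(delta) & delta < 0
  if (clamp) delta[negative] <- 0
  structure(list(delta = delta, valid_mask = valid, negative = negative,
                 sequence = pre$sequence),
            class = "delta_r_map")
}

roi_mean <- function(map, mask, what = "delta") {
  m <- mask & map$valid_mask
  if (!any(m)) return(NA_real_)
  mean(map[[what]][m])
}

#' Relative blood volumes from delta-R maps
#'
#' `rCBV = mean delta-R2*(tumor) / mean delta-R2*(cortex)` (weighted for all
#' vessel calibers) and `rMBV` analogously from delta-R2 (microvessels).
#'
#' @param delta_r2_map delta-R2 map (spin echo) from [delta_r_maps()].
#' @param delta_r2_star_map delta-R2* map (gradient echo).
#' @param rois A [roi_set]; each ROI needs >= 10 valid voxels, and an empty
#'   cortex ROI is a normalization error.
#' @return A `blood_volume_maps` object carrying both maps and the scalar
#'   `rcbv` and `rmbv` ratios.
#' @export
relative_blood_volumes <- function(delta_r2_map, delta_r2_star_map, rois) {
  for (m in list(delta_r2_map, delta_r2_star_map)) {
    if (sum(rois$cortex_mask & m$valid_mask) == 0)
      stop_domain("relative_blood_volumes: normalization error - empty cortex ROI")
    if (sum(rois$tumor_mask & m$valid_mask) < 10 ||
        sum(rois$cortex_mask & m$valid_mask) < 10)
      stop_domain("relative_blood_volumes: need >= 10 valid voxels per ROI")
  }
  t2s_t <- roi_mean(delta_r2_star_map, rois$tumor_mask)
  t2s_c <- roi_mean(delta_r2_star_map, rois$cortex_mask)
  t2_t <- roi_mean(delta_r2_map, rois$tumor_mask)
  t2_c <- roi_mean(delta_r2_map, rois$cortex_mask)
  structure(list(delta_r2 = delta_r2_map, delta_r2_star = delta_r2_star_map,
                 tumor_delta_r2 = t2_t, cortex_delta_r2 = t2_c,
                 tumor_delta_r2_star = t2s_t, cortex_delta_r2_star = t2s_c,
                 rcbv = t2s_t / t2s_c, rmbv = t2_t / t2_c),
            class = "blood_volume_maps")
}
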