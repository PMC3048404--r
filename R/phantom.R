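# Digital mouse-brain phantom cohorts.
#
# A phantom is a voxelwise ground-truth map set (T2, T2*, ADC, SPION-induced
# delta-R2 and delta-R2*, Ktrans, ve, R1(0)) over a 64x64x11 grid at
# 150 um x 150 um x 0.5 mm, holding a spherical tumor in one hemisphere and
# a mirrored contralateral-cortex reference ROI. Two-arm longitudinal
# cohorts (control vs cediranib) are generated by drawing per-animal
# baselines and day-2/day-0 multiplicative effect factors from shipped
# group-effect profiles.

#' Baseline tissue ground-truth values
#'
#' Documented generator anchors (editable by passing `tissue` to
#' [cohort_spec()]): cortex T2 = 40 ms; day-0 tumor T2 = 52 ms, chosen so the
#' control arm reaches ~52.8 ms on day 2 under its +1.6% effect factor;
#' T2* below T2 in both tissues; ADC 7e-4 mm^2/s; SPION-induced delta-R2*
#' and delta-R2 giving day-0 tumor/cortex blood-volume ratios of 1.2;
#' tumor Ktrans 0.1 min^-1 and ve 0.3 (cortex Ktrans 0: intact blood-brain
#' barrier); IVM albumin permeability 3.5e-3 um/s; s0 is the arbitrary
#' proton-density signal scale.
#'
#' @return Named list with `tumor` and `cortex` sub-lists.
#' @export
tissue_defaults <- function() {
  list(
    tumor = list(t2 = 52, t2_star = 35, adc = 7e-4, dr2 = 6, dr2_star = 30,
                 ktrans = 0.1, ve = 0.3, permeability = 3.5e-3),
    cortex = list(t2 = 40, t2_star = 28, adc = 7e-4, dr2 = 5, dr2_star = 25,
                  ktrans = 0, ve = 0.2, permeability = 5e-4),
    r1_0 = 1 / 1.9,
    s0 = 100,
    water_content_day0 = 80
  )
}

#' Cohort specification
#'
#' @param n_per_arm Animals per treatment arm (>= 2).
#' @param seed Base integer seed; all randomness derives from it.
#' @param noise_sigma Rician noise level as a fraction of the mean baseline
#'   tissue signal (0.02 corresponds to SNR 50).
#' @param grid_dim Grid shape (x, y, z).
#' @param voxel_size Voxel edges in mm.
#' @param tumor_radius_mm Day-0 tumor sphere radius (mm).
#' @param tumor_center_vox Tumor center, 1-based voxel indices; the cortex
#'   reference sphere is mirrored across the mid-sagittal plane.
#' @param cortex_radius_mm Radius of the fixed contralateral reference ROI.
#' @param border_vox In-plane background border (used for noise estimation).
#' @param max_tumor_radius_mm Hard cap on the grown radius so the tumor stays
#'   inside the field of view (skull-constrained growth).
#' @param tissue Optional override of [tissue_defaults()].
#' @export
cohort_spec <- function(n_per_arm = 8, seed = 42, noise_sigma = 0.02,
                        grid_dim = c(64, 64, 11),
                        voxel_size = c(0.15, 0.15, 0.5),
                        tumor_radius_mm = 1.1,
                        tumor_center_vox = c(19, 32, 6),
                        cortex_radius_mm = 1.0,
                        border_vox = 3,
                        max_tumor_radius_mm = 2.2,
                        tissue = tissue_defaults()) {
  if (n_per_arm < 2) stop_domain("cohort_spec: n_per_arm must be >= 2")
  if (noise_sigma < 0) stop_domain("cohort_spec: noise_sigma must be >= 0")
  structure(list(n_per_arm = as.integer(n_per_arm), seed = as.integer(seed),
                 noise_sigma = noise_sigma, grid_dim = as.integer(grid_dim),
                 voxel_size = as.numeric(voxel_size),
                 tumor_radius_mm = tumor_radius_mm,
                 tumor_center_vox = as.integer(tumor_center_vox),
                 cortex_radius_mm = cortex_radius_mm,
                 border_vox = as.integer(border_vox),
                 max_tumor_radius_mm = max_tumor_radius_mm,
                 tissue = tissue),
            class = "cohort_spec")
}

#' Group-effect profile
#'
#' Day-2/day-0 multiplicative factors for each ground-truth field, plus
#' per-biomarker between-animal coefficients of variation (CV) of those
#' factors and a baseline CV for day-0 values. The shipped profiles
#' ([default_profile()]) are calibrated to published group effects of
#' VEGFR-inhibitor therapy in orthotopic mouse glioma.
#'
#' @param arm `"control"` or `"cediranib"`.
#' @param factors Named positive multipliers (volume, dr2_star, dr2, t2,
#'   t2_star, adc, ktrans, ve, permeability).
#' @param cv Named non-negative CVs for the factor draws; a scalar recycles.
#' @param baseline_cv CV of per-animal day-0 tumor values.
#' @param water_content_day2 Arm-level day-2 tumor water content (percent).
#' @export
group_effect_profile <- function(arm, factors, cv = 0.05, baseline_cv = 0.10,
                                 water_content_day2 = 80) {
  factors <- as.list(factors)
  if (any(unlist(factors) <= 0)) stop_domain("group_effect_profile: factors must be > 0")
  if (length(cv) == 1L && is.null(names(cv)))
    cv <- stats::setNames(as.list(rep(as.numeric(cv), length(factors))), names(factors))
  else cv <- as.list(cv)
  missing_cv <- setdiff(names(factors), names(cv))
  for (nm in missing_cv) cv[[nm]] <- 0.05
  if (any(unlist(cv) < 0)) stop_domain("group_effect_profile: CV must be >= 0")
  structure(list(arm = arm, factors = factors, cv = cv,
                 baseline_cv = baseline_cv,
                 water_content_day2 = water_content_day2),
            class = "group_effect_profile")
}

#' Shipped group-effect profiles
#'
#' Effect factors encode published arm-level percent changes after 2-3
#' days of treatment in the orthotopic U87 glioma model: e.g. control tumor
#' volume 230% of baseline (factor 2.30), cediranib delta-R2* factor 0.835
#' (-16.5% rCBV). Factor CVs are back-derived from the per-arm SEMs of the
#' same effect sizes assuming 8 animals per arm
#' (CV = SEM * sqrt(8) / 100 / factor); see the methods vignette.
#'
#' @param arm `"control"` or `"cediranib"`.
#' @param cv_scale Optional multiplier on all CVs (0 gives a deterministic
#'   cohort; used by identity tests).
#' @export
default_profile <- function(arm = c("control", "cediranib"), cv_scale = 1) {
  arm <- match.arg(arm)
  if (arm == "control") {
    factors <- list(volume = 2.30, dr2_star = 1.141, dr2 = 0.794,
                    t2 = 1.016, t2_star = 1.0, adc = 0.976,
                    ktrans = 1.063, ve = 0.972, permeability = 1.088)
    cv <- list(volume = 0.406, dr2_star = 0.057, dr2 = 0.075,
               t2 = 0.036, t2_star = 0.02, adc = 0.090,
               ktrans = 0.42, ve = 0.396, permeability = 0.091)
    wc2 <- 80
  } else {
    factors <- list(volume = 1.94, dr2_star = 0.835, dr2 = 0.608,
                    t2 = 0.914, t2_star = 1.0, adc = 0.938,
                    ktrans = 0.657, ve = 0.684, permeability = 0.377)
    cv <- list(volume = 0.51, dr2_star = 0.075, dr2 = 0.27,
               t2 = 0.043, t2_star = 0.02, adc = 0.075,
               ktrans = 0.435, ve = 0.178, permeability = 0.30)
    wc2 <- 80 * (1 - 0.063)
  }
  cv <- lapply(cv, function(x) x * cv_scale)
  group_effect_profile(arm, factors, cv = cv, baseline_cv = 0.10 * cv_scale,
                       water_content_day2 = wc2)
}

# mm coordinates of voxel centers along one axis
axis_mm <- function(n, d) (seq_len(n) - 0.5) * d

sphere_mask <- function(grid_dim, voxel_size, center_mm, radius_mm) {
  x <- axis_mm(grid_dim[1], voxel_size[1]) - center_mm[1]
  y <- axis_mm(grid_dim[2], voxel_size[2]) - center_mm[2]
  z <- axis_mm(grid_dim[3], voxel_size[3]) - center_mm[3]
  r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  r2 <= radius_mm^2
}

# Per-animal random draws, identical for day 0 and day 2 of the same animal.
animal_draws <- function(spec, profile, animal_seed) {
  fields <- c("t2", "t2_star", "adc", "dr2", "dr2_star", "ktrans", "ve",
              "permeability")
  with_local_seed(derive_seed(animal_seed, "animal-draws"), {
    base_mult <- stats::setNames(
      vapply(fields, function(f) rlnorm_cv(1, 1, profile$baseline_cv), 0), fields)
    vol_base <- rlnorm_cv(1, 1, profile$baseline_cv)
    cortex_mult <- stats::setNames(
      vapply(fields, function(f) rlnorm_cv(1, 1, profile$baseline_cv / 2), 0), fields)
    fac <- stats::setNames(vapply(names(profile$factors), function(f)
      rlnorm_cv(1, profile$factors[[f]], profile$cv[[f]]), 0),
      names(profile$factors))
    wc <- rlnorm_cv(1, 1, profile$baseline_cv / 5)
    list(base_mult = base_mult, vol_base = vol_base,
         cortex_mult = cortex_mult, factors = fac, wc_mult = wc)
  })
}

#' Generate a ground-truth phantom for one animal and visit
#'
#' Deterministic given `(spec, profile, animal_seed)`: the same animal seed
#' yields consistent day-0 and day-2 phantoms (shared baseline draws, with
#' day-2 values scaled by the animal's drawn effect factors). The tumor is a
#' sphere whose day-2 volume is scaled by the drawn volume factor; the
#' contralateral cortex reference sphere is fixed.
#'
#' @param spec A [cohort_spec()].
#' @param day Visit day, 0 or 2.
#' @param profile A [group_effect_profile()].
#' @param animal_seed Integer seed identifying the animal.
#' @return An object of class `ground_truth_phantom` with per-voxel maps
#'   (`t2`, `t2_star`, `adc`, `delta_r2`, `delta_r2_star`, `ktrans`, `ve`,
#'   `s0`, `labels`) and a `truth` list of scalar ground-truth values.
#' @export
make_phantom <- function(spec, day, profile, animal_seed) {
  stopifnot(day %in% c(0, 2))
  d <- animal_draws(spec, profile, animal_seed)
  ts <- spec$tissue
  gd <- spec$grid_dim; vs <- spec$voxel_size

  # per-tissue scalar ground truth for this visit
  tv <- mapply(function(v, m) v * m, ts$tumor, d$base_mult[names(ts$tumor)],
               SIMPLIFY = FALSE)
  cvx <- mapply(function(v, m) v * m, ts$cortex, d$cortex_mult[names(ts$cortex)],
                SIMPLIFY = FALSE)
  if (day == 2) {
    for (f in intersect(names(tv), names(d$factors)))
      tv[[f]] <- tv[[f]] * d$factors[[f]]
  }
  # physical guards: T2* cannot exceed T2; ve bounded away from 1
  tv$t2_star <- min(tv$t2_star, 0.85 * tv$t2)
  cvx$t2_star <- min(cvx$t2_star, 0.85 * cvx$t2)
  tv$ve <- min(tv$ve, 0.95)
  if (tv$ktrans < 0 || tv$dr2 < 0 || tv$dr2_star < 0)
    stop_domain("make_phantom: negative ground-truth rate drawn")

  # tumor geometry
  r0 <- spec$tumor_radius_mm * d$vol_base^(1 / 3)
  radius <- if (day == 0) r0 else min(r0 * d$factors[["volume"]]^(1 / 3),
                                      spec$max_tumor_radius_mm)
  ctr_vox <- spec$tumor_center_vox
  ctr_mm <- (ctr_vox - 0.5) * vs
  cortex_ctr_mm <- c(gd[1] * vs[1] - ctr_mm[1], ctr_mm[2], ctr_mm[3])

  bx <- spec$border_vox
  brain_lo <- c((bx + 0.5) * vs[1], (bx + 0.5) * vs[2], 0)
  brain_hi <- c((gd[1] - bx - 0.5) * vs[1], (gd[2] - bx - 0.5) * vs[2], gd[3] * vs[3])
  if (any(ctr_mm - radius < brain_lo) || any(ctr_mm + radius > brain_hi))
    stop_domain("make_phantom: geometry error - tumor radius ", round(radius, 2),
                " mm exceeds the brain region")

  tumor <- sphere_mask(gd, vs, ctr_mm, radius)
  cortex <- sphere_mask(gd, vs, cortex_ctr_mm, spec$cortex_radius_mm)
  brain <- array(FALSE, gd)
  brain[(bx + 1):(gd[1] - bx), (bx + 1):(gd[2] - bx), ] <- TRUE
  tumor <- tumor & brain
  cortex <- cortex & brain & !tumor

  labels <- array("background", gd)
  labels[brain] <- "cortex"
  labels[tumor] <- "tumor"

  fill <- function(field) {
    a <- array(cvx[[field]], gd)   # background holds cortex value; s0 = 0 there
    a[tumor] <- tv[[field]]
    a
  }
  s0 <- array(0, gd); s0[brain] <- ts$s0

  wc0 <- ts$water_content_day0
  wc <- if (day == 0) wc0 * d$wc_mult else
    (wc0 + (profile$water_content_day2 - 80)) * d$wc_mult
  # per-visit wet/dry weighing variability (vanishes with the baseline CV)
  wc <- wc * with_local_seed(derive_seed(animal_seed, "wc-visit", day),
                             rlnorm_cv(1, 1, 0.4 * profile$baseline_cv))

  structure(list(
    t2 = fill("t2"), t2_star = fill("t2_star"), adc = fill("adc"),
    delta_r2 = fill("dr2"), delta_r2_star = fill("dr2_star"),
    ktrans = fill("ktrans"), ve = fill("ve"),
    r1_0 = ts$r1_0, s0 = s0, labels = labels,
    voxel_size = vs, day = day, arm = profile$arm,
    truth = list(tumor = tv, cortex = cvx, radius_mm = radius,
                 volume_mm3 = sum(tumor) * prod(vs),
                 sphere_volume_mm3 = 4 / 3 * pi * radius^3,
                 factors = as.list(d$factors),
                 water_content = wc)),
    class = "ground_truth_phantom")
}

#' Extract the ROI set of a phantom
#' @param phantom A `ground_truth_phantom`.
#' @return A [roi_set] with the tumor and contralateral-cortex masks.
#' @export
phantom_rois <- function(phantom) {
  roi_set(phantom$labels == "tumor", phantom$labels == "cortex")
}
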