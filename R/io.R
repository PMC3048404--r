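# NIfTI-1 + JSON-sidecar readers/writers and pipeline configuration.
#
# Storage convention (BIDS-like): each series is one NIfTI file `<path>.nii`
# holding a 4D array (x, y, z, echo/b-value/frame) plus a JSON sidecar
# `<path>.json` with the acquisition metadata (EchoTime, bval, FrameTimes,
# RepetitionTime, FlipAngle, InjectionIndex, VoxelSize). The sidecar is
# authoritative for timing and voxel geometry.

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", "", path) |> paste0(".json")
}

nifti_path <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) path else paste0(path, ".nii")
}

require_field <- function(meta, field, path) {
  if (is.null(meta[[field]]))
    stop_domain("sidecar schema error: missing field '", field, "' in ", path)
  meta[[field]]
}

volumes_from_4d <- function(arr, voxel_size) {
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  lapply(seq_len(dim(arr)[4]), function(i)
    image_volume(arr[, , , i, drop = FALSE] |> array(dim(arr)[1:3]),
                 voxel_size = voxel_size))
}

#' Write an image series as NIfTI + JSON sidecar
#'
#' @param series A [multiecho_series], [dwi_series] or [dce_series].
#' @param path Output path, with or without the `.nii` extension; the sidecar
#'   is written alongside with extension `.json`.
#' @return Invisibly, the NIfTI path.
#' @export
write_series <- function(series, path) {
  nii <- nifti_path(path)
  if (inherits(series, "multiecho_series")) {
    arr <- signal_array(series)
    vs <- series$volumes[[1]]$voxel_size
    meta <- list(Type = "multiecho", EchoTime = series$echo_times,
                 Sequence = series$sequence, ContrastState = series$contrast_state,
                 VoxelSize = vs)
  } else if (inherits(series, "dwi_series")) {
    arr <- signal_array(series)
    vs <- series$volumes[[1]]$voxel_size
    meta <- list(Type = "dwi", bval = series$b_values, VoxelSize = vs)
  } else if (inherits(series, "dce_series")) {
    nx <- nrow(series$frames[[1]]); ny <- ncol(series$frames[[1]])
    arr <- array(unlist(series$frames), c(nx, ny, 1L, length(series$frames)))
    vs <- c(attr(series, "voxel_size") %||% c(0.2, 0.2, 0.5))
    meta <- list(Type = "dce", FrameTimes = series$frame_times,
                 RepetitionTime = series$tr, FlipAngle = series$flip_angle,
                 EchoTime = series$te, InjectionIndex = series$injection_index,
                 VoxelSize = vs)
  } else stop_domain("write_series: unsupported series type")
  x <- arr
  attr(x, "pixdim") <- vs
  RNifti::writeNifti(RNifti::asNifti(x), nii, datatype = "double")
  jsonlite::write_json(meta, sidecar_path(nii), auto_unbox = TRUE, digits = NA)
  invisible(nii)
}

#' Read an image series from NIfTI + JSON sidecar
#'
#' The sidecar decides the series type: `EchoTime` + `Sequence` gives a
#' [multiecho_series], `bval` a [dwi_series], `FrameTimes` a [dce_series].
#' All type invariants are re-checked on read; an echo-count mismatch between
#' sidecar and data raises a dimension error.
#'
#' @param path NIfTI path (with or without extension).
#' @param sidecar Optional explicit sidecar path or pre-parsed metadata list.
#' @return A validated typed series object.
#' @export
read_series <- function(path, sidecar = NULL) {
  nii <- nifti_path(path)
  meta <- if (is.list(sidecar)) sidecar else {
    sc <- if (is.null(sidecar)) sidecar_path(nii) else sidecar
    if (!file.exists(sc)) stop_domain("sidecar schema error: no sidecar at ", sc)
    jsonlite::fromJSON(sc, simplifyVector = TRUE)
  }
  arr <- as.array(RNifti::readNifti(nii))
  vs <- as.numeric(meta$VoxelSize %||% RNifti::pixdim(RNifti::readNifti(nii))[1:3])
  type <- meta$Type %||% if (!is.null(meta$EchoTime) && !is.null(meta$Sequence))
    "multiecho" else if (!is.null(meta$bval)) "dwi" else if (!is.null(meta$FrameTimes))
    "dce" else stop_domain("sidecar schema error: cannot infer series type")
  switch(type,
    multiecho = multiecho_series(
      volumes_from_4d(arr, vs),
      echo_times = require_field(meta, "EchoTime", path),
      sequence = require_field(meta, "Sequence", path),
      contrast_state = meta$ContrastState %||% "pre_spion"),
    dwi = dwi_series(volumes_from_4d(arr, vs),
                     b_values = require_field(meta, "bval", path)),
    dce = {
      if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr)[1:2], 1L, dim(arr)[3])
      frames <- lapply(seq_len(dim(arr)[4]), function(i) arr[, , 1L, i])
      s <- dce_series(frames,
                      frame_times = require_field(meta, "FrameTimes", path),
                      tr = require_field(meta, "RepetitionTime", path),
                      flip_angle = require_field(meta, "FlipAngle", path),
                      te = meta$EchoTime %||% 2.5,
                      injection_index = require_field(meta, "InjectionIndex", path))
      attr(s, "voxel_size") <- vs
      s
    },
    stop_domain("sidecar schema error: unknown series type '", type, "'"))
}

#' Default pipeline configuration
#'
#' Single home for every tunable constant: acquisition constants (Gd and
#' SPION relaxivities, field strength, dose), the bi-exponential AIF, the
#' pre-contrast longitudinal rate `r1_0` (s^-1), vessel-caliber-index
#' exponents, relaxometry/segmentation settings and the T2-weighted
#' effective echo time.
#'
#' @return A named list of settings.
#' @export
default_config <- function() {
  list(
    constants = unclass(acquisition_constants()),
    aif = unclass(aif_parameters()),
    r1_0 = 1 / 1.9,
    vci_exponents = list(adc = 0.5, dr2_star = 1.5, dr2 = -1.5),
    relaxometry = list(method = "loglinear", noise_k = 3),
    segmentation = list(k = 2, keep_largest = TRUE),
    t2w = list(te_eff = 60),
    strict = FALSE
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

validate_config <- function(cfg) {
  cfg$constants <- unclass(do.call(acquisition_constants, cfg$constants))
  cfg$aif <- unclass(do.call(aif_parameters, cfg$aif))
  if (!is.finite(cfg$r1_0) || cfg$r1_0 <= 0)
    stop_domain("config validation error: r1_0 must be positive")
  ex <- cfg$vci_exponents
  if (!all(c("adc", "dr2_star", "dr2") %in% names(ex)))
    stop_domain("config validation error: vci_exponents needs adc, dr2_star, dr2")
  if (cfg$relaxometry$noise_k < 0)
    stop_domain("config validation error: relaxometry noise_k must be >= 0")
  cfg
}

#' Load a pipeline configuration from JSON
#'
#' Absent keys fall back to [default_config()]; the merged configuration is
#' validated (negative relaxivities, doses or rates raise a validation
#' error). In strict mode an explicit `aif` block is required, so that the
#' documented placeholder AIF constants can never be used silently.
#'
#' @param path JSON file path, or `NULL` for pure defaults.
#' @param strict Require an explicit `aif` block in the file.
#' @export
load_config <- function(path = NULL, strict = FALSE) {
  user <- if (is.null(path)) list()
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  strict <- isTRUE(strict) || isTRUE(user$strict)
  if (strict && is.null(user$aif))
    stop_domain("config validation error: strict mode requires an explicit ",
                "'aif' block (the shipped AIF constants are placeholders)")
  validate_config(merge_config(default_config(), user))
}

#' Write a configuration to JSON
#' @param config Configuration list as returned by [load_config()].
#' @param path Output JSON path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
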