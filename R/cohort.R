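# Cohort-level operations: tumor volume from T2 hyperintensity, longitudinal
# percent change, ex-vivo water content, and between-group ANOVA.

#' Biomarker registry
#'
#' Names of the scalar biomarkers an animal record may carry, with the
#' reporting convention used for longitudinal change: tumor volume is
#' conventionally reported as percent *of baseline* (a growing tumor reads
#' 230%), all other biomarkers as signed percent change.
#'
#' @return Named character vector mapping biomarker name to change mode.
#' @export
biomarker_registry <- function() {
  c(volume_mm3 = "of_baseline", t2_ms = "signed", t2_star_ms = "signed",
    adc = "signed", rcbv = "signed", rmbv = "signed", rvci = "signed",
    ktrans = "signed", ve = "signed", kep = "signed",
    permeability = "signed", water_content = "signed")
}

# 6-connected components over a logical 3D mask; returns the mask of the
# largest component. Union-find with path halving over the in-mask voxels.
largest_component <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) <= 1L) return(mask)
  rank_arr <- array(0L, d)
  rank_arr[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  co <- arrayInd(idx, d)
  strides <- c(1L, d[1], d[1] * d[2])
  for (ax in 1:3) {
    ok <- co[, ax] > 1L
    nb <- idx[ok] - strides[ax]
    nb_rank <- rank_arr[nb]
    here <- which(ok)[nb_rank > 0L]
    nbr <- nb_rank[nb_rank > 0L]
    for (q in seq_along(here)) {
      a <- find(here[q]); b <- find(nbr[q])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_along(idx), find, 0L)
  biggest <- as.integer(names(which.max(table(roots))))
  out <- array(FALSE, d)
  out[idx[roots == biggest]] <- TRUE
  out
}

#' Tumor volume from T2 hyperintensity
#'
#' Segments the hyperintense tumor region of a T2-weighted volume by
#' thresholding at `cortex mean + k * cortex SD` (cortex statistics from the
#' contralateral reference ROI, or an explicit threshold), optionally keeps
#' only the largest 6-connected component (suppresses salt noise above the
#' threshold), and returns `count * voxel volume`.
#'
#' @param t2w An [image_volume].
#' @param rois A [roi_set] supplying the cortex reference (ignored when
#'   `threshold` is given).
#' @param threshold Explicit intensity threshold.
#' @param k Threshold multiplier on the cortex SD.
#' @param keep_largest Keep only the largest connected component.
#' @return Volume in mm^3 (0 with a warning for an empty segmentation); the
#'   segmentation mask is attached as attribute `"mask"`.
#' @export
tumor_volume <- function(t2w, rois = NULL, threshold = NULL, k = 2,
                         keep_largest = TRUE) {
  if (is.null(threshold)) {
    if (is.null(rois)) stop_domain("tumor_volume: supply rois or a threshold")
    cx <- t2w$data[rois$cortex_mask]
    threshold <- mean(cx) + k * stats::sd(cx)
  }
  hyper <- t2w$data > threshold
  if (!any(hyper)) {
    warning("tumor_volume: empty segmentation, returning 0")
    return(structure(0, mask = hyper))
  }
  if (keep_largest) hyper <- largest_component(hyper)
  structure(sum(hyper) * voxel_volume(t2w), mask = hyper)
}

#' Longitudinal percent change
#'
#' Signed mode: `100 * (day2 - day0) / day0`. Growth ("of baseline") mode:
#' `100 * day2 / day0`, the convention under which a doubling tumor reads
#' 200%. Swapping the visits maps a change factor `f` to `1/f`
#' (antisymmetry in log).
#'
#' @param day0,day2 Scalar (or vector) biomarker values; `day0` must be
#'   nonzero.
#' @param mode `"signed"` or `"of_baseline"`.
#' @return Percent value(s); `day0 = 0` yields `NA` with a warning.
#' @export
percent_change <- function(day0, day2, mode = c("signed", "of_baseline")) {
  mode <- match.arg(mode)
  bad <- day0 == 0
  if (any(bad)) warning("percent_change: day0 = 0, change undefined")
  out <- if (mode == "signed") 100 * (day2 - day0) / day0 else 100 * day2 / day0
  out[bad] <- NA_real_
  out
}

#' Ex-vivo tissue water content
#'
#' `(wet - dry) / wet * 100`, in percent.
#'
#' @param wet_mg,dry_mg Wet and dry tissue weights; `wet >= dry > 0`.
#' @export
water_content <- function(wet_mg, dry_mg) {
  if (any(dry_mg <= 0)) stop_domain("water_content: dry weight must be > 0")
  if (any(dry_mg > wet_mg))
    stop_domain("water_content: measurement error - dry weight exceeds wet weight")
  (wet_mg - dry_mg) / wet_mg * 100
}

#' Two-group one-way ANOVA
#'
#' Closed-form one-way ANOVA for two groups (equivalent to the squared
#' pooled-variance t statistic: `F = t^2` with `df = (1, n1 + n2 - 2)`).
#'
#' @param x,y Numeric vectors of per-animal values in each group.
#' @return List with `f`, `p`, `df1`, `df2`.
#' @export
anova_two_group <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop_domain("anova_two_group: need >= 2 per group")
  g <- (sum(x) + sum(y)) / (n1 + n2)
  ssb <- n1 * (mean(x) - g)^2 + n2 * (mean(y) - g)^2
  ssw <- sum((x - mean(x))^2) + sum((y - mean(y))^2)
  df2 <- n1 + n2 - 2L
  f <- if (ssw == 0) ifelse(ssb == 0, 0, Inf) else (ssb / 1) / (ssw / df2)
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  list(f = f, p = p, df1 = 1L, df2 = df2)
}

#' Between-arm comparison of longitudinal biomarker changes
#'
#' Computes each animal's day-2 vs day-0 percent change for one biomarker,
#' then compares arms by one-way ANOVA on those changes. Animals missing a
#' visit are excluded with a message. SEM is `sd / sqrt(n)`; significance is
#' declared at p < 0.05.
#'
#' @param records Long-format data.frame with columns `animal_id`, `arm`,
#'   `day`, `biomarker`, `value` (one row per measurement).
#' @param biomarker Biomarker name from [biomarker_registry()].
#' @param mode Change convention; default follows the registry.
#' @return A `group_comparison`: per-arm mean change and SEM, F statistic,
#'   p value.
#' @export
compare_groups <- function(records, biomarker, mode = NULL) {
  reg <- biomarker_registry()
  if (is.null(mode)) mode <- unname(reg[biomarker] %||% "signed")
  if (is.na(mode)) mode <- "signed"
  pa <- per_animal_changes(records, biomarker, mode)
  arms <- sort(unique(pa$arm))
  if (length(arms) != 2L)
    stop_domain("compare_groups: need exactly 2 arms, got ", length(arms))
  x <- pa$change[pa$arm == arms[1]]
  y <- pa$change[pa$arm == arms[2]]
  if (length(x) < 2L || length(y) < 2L)
    stop_domain("compare_groups: need >= 2 animals per arm with both visits")
  av <- anova_two_group(x, y)
  summ <- data.frame(
    arm = arms,
    n = c(length(x), length(y)),
    mean_change = c(mean(x), mean(y)),
    sem = c(stats::sd(x) / sqrt(length(x)), stats::sd(y) / sqrt(length(y))))
  structure(list(biomarker = biomarker, mode = mode, arms = summ,
                 f_statistic = av$f, p_value = av$p,
                 significant = av$p < 0.05, per_animal = pa),
            class = "group_comparison")
}

#' Per-animal longitudinal changes for one biomarker
#'
#' @inheritParams compare_groups
#' @return data.frame with `animal_id`, `arm`, `day0`, `day2`, `change`.
#' @export
per_animal_changes <- function(records, biomarker,
                               mode = c("signed", "of_baseline")) {
  mode <- match.arg(mode)
  r <- records[records$biomarker == biomarker, , drop = FALSE]
  if (!nrow(r)) stop_domain("per_animal_changes: no records for ", biomarker)
  out <- do.call(rbind, lapply(split(r, r$animal_id), function(g) {
    d0 <- g$value[g$day == 0]; d2 <- g$value[g$day == 2]
    if (length(d0) != 1L || length(d2) != 1L || !is.finite(d0) || !is.finite(d2)) {
      message("per_animal_changes: excluding animal ", g$animal_id[1],
              " (missing visit for ", biomarker, ")")
      return(NULL)
    }
    data.frame(animal_id = g$animal_id[1], arm = g$arm[1],
               day0 = d0, day2 = d2,
               change = percent_change(d0, d2, mode))
  }))
  rownames(out) <- NULL
  out
}

#' Arm-level summary of all biomarker changes
#'
#' @param records Long-format cohort records (see [compare_groups()]).
#' @param biomarkers Biomarkers to summarize; defaults to those present.
#' @return data.frame with one row per biomarker x arm: `n`, `mean_change`,
#'   `sem`, and the change `mode` used.
#' @export
summarize_changes <- function(records, biomarkers = NULL) {
  reg <- biomarker_registry()
  if (is.null(biomarkers)) biomarkers <- intersect(names(reg), unique(records$biomarker))
  out <- do.call(rbind, lapply(biomarkers, function(bm) {
    mode <- unname(reg[bm] %||% "signed"); if (is.na(mode)) mode <- "signed"
    pa <- per_animal_changes(records, bm, mode)
    do.call(rbind, lapply(split(pa, pa$arm), function(g)
      data.frame(biomarker = bm, arm = g$arm[1], mode = mode, n = nrow(g),
                 mean_change = mean(g$change),
                 sem = stats::sd(g$change) / sqrt(nrow(g)))))
  }))
  rownames(out) <- NULL
  out
}
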