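test_that("discretized tumor sphere volume tracks the analytic sphere", {
  spec <- cohort_spec(n_per_arm = 2, seed = 1, tumor_radius_mm = 1.0)
  ph <- make_phantom(spec, 0, cv0_profile("control"), 1)
  analytic <- 4 / 3 * pi * 1.0^3
  shell <- 4 * pi * 1.0^2 * max(spec$voxel_size) / 2
  expect_lt(abs(ph$truth$volume_mm3 - analytic), shell)
})

test_that("hyperintensity segmentation recovers the noiseless tumor exactly", {
  spec <- small_spec(noise_sigma = 0)
  ph <- make_phantom(spec, 2, cv0_profile("control"), 4)
  t2w <- forward_t2w(ph, noise_sigma = 0, seed = 1)
  v <- tumor_volume(t2w, phantom_rois(ph))
  expect_equal(as.numeric(v), ph$truth$volume_mm3)
  expect_equal(sum(attr(v, "mask") != (ph$labels == "tumor")), 0)
})

test_that("segmentation edge cases: empty result, threshold override, salt noise", {
  spec <- small_spec(noise_sigma = 0.02)
  ph <- make_phantom(spec, 0, cv0_profile("control"), 4)
  t2w <- forward_t2w(ph, noise_sigma = 0.02, seed = 1)
  expect_warning(v0 <- tumor_volume(t2w, threshold = max(t2w$data) + 1), "empty")
  expect_equal(as.numeric(v0), 0)
  # at SNR 50 the k = 2 threshold admits scattered false positives; the
  # largest-component filter suppresses them
  v_raw <- tumor_volume(t2w, phantom_rois(ph), keep_largest = FALSE)
  v_cc <- tumor_volume(t2w, phantom_rois(ph), keep_largest = TRUE)
  expect_gt(as.numeric(v_raw), as.numeric(v_cc))
  expect_lt(abs(as.numeric(v_cc) - ph$truth$volume_mm3) / ph$truth$volume_mm3,
            0.15)
})

test_that("percent change conventions and antisymmetry in log", {
  expect_equal(percent_change(50, 50), 0)
  expect_equal(percent_change(52.8, 48.3), -8.52, tolerance = 1e-3)
  expect_equal(percent_change(100, 230), 130)
  expect_equal(percent_change(100, 230, mode = "of_baseline"), 230)
  expect_warning(pc <- percent_change(0, 5), "undefined")
  expect_true(is.na(pc))
  # swapping visits maps factor f to 1/f
  f <- withr::with_seed(2, runif(50, 0.2, 5))
  fwd <- 1 + percent_change(1, f) / 100
  bwd <- 1 + percent_change(f, rep(1, 50)) / 100
  expect_equal(bwd, 1 / fwd, tolerance = 1e-12)
})

test_that("water content arithmetic and measurement errors", {
  expect_equal(water_content(100, 100), 0)
  expect_equal(water_content(100, 20), 80)
  expect_error(water_content(50, 60), "measurement error")
  expect_error(water_content(50, 0), "dry weight")
  # constructed 6.3 percent relative group difference is recovered exactly
  wc_control <- water_content(100, 20)
  wc_treated <- water_content(100, 100 - 0.8 * (1 - 0.063) * 100)
  expect_equal(percent_change(wc_control, wc_treated), -6.3, tolerance = 1e-9)
})

test_that("two-group ANOVA equals aov and the squared pooled t statistic", {
  x <- withr::with_seed(7, rnorm(8, 0, 2))
  y <- withr::with_seed(8, rnorm(6, 1.5, 2))
  av <- anova_two_group(x, y)
  # independent oracle: stats::aov
  df <- data.frame(v = c(x, y), g = rep(c("a", "b"), c(8, 6)))
  tab <- summary(stats::aov(v ~ g, df))[[1]]
  expect_equal(av$f, tab[["F value"]][1], tolerance = 1e-10)
  expect_equal(av$p, tab[["Pr(>F)"]][1], tolerance = 1e-10)
  # F = t^2 for the pooled-variance t test
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(av$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(av$p, tt$p.value, tolerance = 1e-10)
  # identical group means: F = 0, p = 1
  z <- c(1, 2, 3)
  expect_equal(anova_two_group(z, z)$f, 0)
  expect_equal(anova_two_group(z, z)$p, 1)
})

test_that("compare_groups: per-animal changes, exclusions, significance", {
  rec <- expand.grid(animal_id = sprintf("a%02d", 1:8),
                     day = c(0, 2), biomarker = "t2_ms",
                     stringsAsFactors = FALSE)
  rec$arm <- ifelse(as.integer(sub("a", "", rec$animal_id)) <= 4,
                    "control", "cediranib")
  base <- 50
  fac <- ifelse(rec$arm == "control", 1.02, 0.91)
  jit <- withr::with_seed(3, rnorm(nrow(rec), 0, 0.2))
  rec$value <- ifelse(rec$day == 0, base, base * fac) + jit
  cmp <- compare_groups(rec, "t2_ms")
  expect_s3_class(cmp, "group_comparison")
  expect_true(cmp$significant)
  expect_equal(sort(cmp$arms$arm), c("cediranib", "control"))
  expect_equal(cmp$arms$n, c(4, 4))
  # missing visit drops the animal with a message
  rec2 <- rec[!(rec$animal_id == "a01" & rec$day == 2), ]
  expect_message(cmp2 <- compare_groups(rec2, "t2_ms"), "excluding")
  expect_equal(cmp2$arms$n[cmp2$arms$arm == "control"], 3)
})

test_that("ANOVA type-I error is nominal under the null", {
  reps <- 2000
  hits <- withr::with_seed(123, mean(vapply(seq_len(reps), function(i)
    anova_two_group(rnorm(8), rnorm(8))$p < 0.05, NA)))
  expect_lt(abs(hits - 0.05), 0.015)
})
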