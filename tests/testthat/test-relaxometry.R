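test_that("noiseless mono-exponential fits are exact for both methods", {
  for (t2 in c(30, 50, 80)) {
    se <- uniform_multiecho(t2)
    m_ll <- fit_relaxation(se, "loglinear", noise_k = 0)
    expect_equal(m_ll$rate[1, 1, 1], 1000 / t2, tolerance = 1e-9)
    expect_equal(m_ll$s0[1, 1, 1], 100, tolerance = 1e-9)
    expect_true(all(m_ll$valid_mask))
    expect_true(all(m_ll$fit_quality > 0.999999))
    m_nl <- fit_relaxation(se, "nlls", noise_k = 0)
    expect_equal(m_nl$rate, m_ll$rate, tolerance = 1e-3) # < 0.1 % agreement
  }
  expect_error(fit_relaxation(uniform_multiecho(50, echo_times = c(10, 20))),
               "3 echoes")
})

test_that("degenerate voxels are invalid, with an empty-map warning", {
  # constant signal across echoes -> rate 0 -> invalid
  vols <- lapply(1:5, function(i) image_volume(array(50, c(3, 3, 1))))
  se <- multiecho_series(vols, (1:5) * 10)
  expect_warning(m <- fit_relaxation(se, noise_k = 0), "empty map")
  expect_false(any(m$valid_mask))
})

test_that("background sigma estimate and noise threshold mark dark voxels invalid", {
  spec <- small_spec(noise_sigma = 0.02)
  ph <- make_phantom(spec, 0, cv0_profile("control"), 1)
  se <- forward_multiecho(ph, "spin_echo", noise_sigma = 0.02, seed = 2)
  m <- fit_relaxation(se)
  expect_equal(m$sigma, 0.02 * mean((100 * exp(-10 / ph$t2))[ph$labels != "background"]),
               tolerance = 0.15)
  # air voxels excluded (up to the Rician tail above threshold), tissue kept
  expect_lt(mean(m$valid_mask[ph$labels == "background"]), 0.02)
  expect_true(mean(m$valid_mask[ph$labels == "tumor"]) > 0.99)
})

test_that("median T2 bias at SNR 50 stays under 2 percent", {
  t2 <- 50; s0 <- 100; sigma <- 2 # SNR 50 at the amplitude
  se <- uniform_multiecho(t2, dims = c(100, 100, 1), s0 = s0, sigma = sigma,
                          seed = 99)
  m <- fit_relaxation(se, noise_k = 0)
  t2_hat <- 1000 / m$rate[m$valid_mask]
  expect_gt(length(t2_hat), 9000)
  expect_lt(abs(median(t2_hat) - t2) / t2, 0.02)
})

test_that("delta-R maps: zero difference, antisymmetry, grid checks", {
  pre <- fit_relaxation(uniform_multiecho(50, seed = 1), noise_k = 0)
  post <- fit_relaxation(uniform_multiecho(40, seed = 2), noise_k = 0)
  d0 <- delta_r_maps(pre, pre)
  expect_true(all(d0$delta == 0))
  d <- delta_r_maps(pre, post)
  dswap <- delta_r_maps(post, pre)
  expect_equal(d$delta, -dswap$delta)
  expect_equal(d$delta[1, 1, 1], 1000 / 40 - 1000 / 50, tolerance = 1e-9)
  small <- fit_relaxation(uniform_multiecho(50, dims = c(4, 4, 1)), noise_k = 0)
  expect_error(delta_r_maps(pre, small), "dimension")
  gre <- fit_relaxation(uniform_multiecho(30, sequence = "gradient_echo",
                                          echo_times = seq(2.5, 20, 2.5)),
                        noise_k = 0)
  expect_error(delta_r_maps(pre, gre), "sequence")
  # negative voxels flagged but retained
  expect_true(all(dswap$negative == (dswap$delta < 0)))
})

test_that("relative blood volumes: identity, normalization errors", {
  tm <- toy_maps(d2_t = 5, d2_c = 5, d2s_t = 25, d2s_c = 25)
  expect_equal(tm$bv$rcbv, 1)
  expect_equal(tm$bv$rmbv, 1)
  tm2 <- toy_maps(d2_t = 6, d2_c = 5, d2s_t = 30, d2s_c = 25)
  expect_equal(tm2$bv$rcbv, 1.2, tolerance = 1e-12)
  expect_equal(tm2$bv$rmbv, 1.2, tolerance = 1e-12)

  # empty cortex ROI is a normalization error
  dims <- c(6, 4, 2)
  dmap <- structure(list(delta = array(1, dims),
                         valid_mask = array(c(TRUE, FALSE)[
                           1 + (slice.index(array(0, dims), 1) > 3)], dims),
                         negative = array(FALSE, dims), sequence = "spin_echo"),
                    class = "delta_r_map")
  tumor <- array(FALSE, dims); tumor[1:3, , ] <- TRUE
  rois <- roi_set(tumor, !tumor)
  expect_error(relative_blood_volumes(dmap, dmap, rois), "cortex")
})

test_that("end-to-end: tumor/cortex delta-R2* ratio recovers the encoded blood volume", {
  spec <- small_spec(noise_sigma = 0)
  prof <- cv0_profile("cediranib")
  for (day in c(0, 2)) {
    ph <- make_phantom(spec, day, prof, 7)
    rois <- phantom_rois(ph)
    pre <- fit_relaxation(forward_multiecho(ph, "gradient_echo", "pre_spion",
                                            noise_sigma = 0, seed = 1))
    post <- fit_relaxation(forward_multiecho(ph, "gradient_echo", "post_spion",
                                             noise_sigma = 0, seed = 2))
    drs <- delta_r_maps(pre, post)
    pre2 <- fit_relaxation(forward_multiecho(ph, "spin_echo", "pre_spion",
                                             noise_sigma = 0, seed = 3))
    post2 <- fit_relaxation(forward_multiecho(ph, "spin_echo", "post_spion",
                                              noise_sigma = 0, seed = 4))
    dr2 <- delta_r_maps(pre2, post2)
    bv <- relative_blood_volumes(dr2, drs, rois)
    expect_equal(bv$rcbv, ph$truth$tumor$dr2_star / ph$truth$cortex$dr2_star,
                 tolerance = 1e-6)
    expect_equal(bv$rmbv, ph$truth$tumor$dr2 / ph$truth$cortex$dr2,
                 tolerance = 1e-6)
  }
})
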