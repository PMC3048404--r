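test_that("phantom generation is deterministic and day-consistent", {
  spec <- small_spec()
  prof <- default_profile("cediranib")
  p1 <- make_phantom(spec, 2, prof, 77)
  p2 <- make_phantom(spec, 2, prof, 77)
  expect_identical(p1, p2)
  s1 <- forward_multiecho(p1, "spin_echo", noise_sigma = 0.02, seed = 5)
  s2 <- forward_multiecho(p2, "spin_echo", noise_sigma = 0.02, seed = 5)
  expect_identical(signal_array(s1), signal_array(s2))
  # same animal, different day: baseline draws shared
  d0 <- make_phantom(spec, 0, prof, 77)
  expect_equal(d0$truth$factors, p1$truth$factors)
})

test_that("zero-CV cediranib phantoms apply effect factors exactly", {
  spec <- small_spec()
  prof <- cv0_profile("cediranib")
  d0 <- make_phantom(spec, 0, prof, 3)
  d2 <- make_phantom(spec, 2, prof, 3)
  expect_equal(d2$truth$tumor$ktrans, d0$truth$tumor$ktrans * (1 - 0.343),
               tolerance = 1e-12)
  expect_equal(d2$truth$tumor$t2 / d0$truth$tumor$t2, 0.914, tolerance = 1e-12)
  expect_equal(d2$truth$tumor$dr2 / d0$truth$tumor$dr2, 0.608, tolerance = 1e-12)
  # cortex is longitudinally stable
  expect_equal(d2$truth$cortex, d0$truth$cortex)
  # phantom invariants
  for (p in list(d0, d2)) {
    tissue <- p$labels != "background"
    expect_true(all(p$t2_star[tissue] <= p$t2[tissue]))
    expect_true(all(p$ve[tissue] > 0 & p$ve[tissue] < 1))
    expect_true(all(p$ktrans[tissue] >= 0))
  }
})

test_that("control tumor growth encodes ~230% of baseline across animals", {
  spec <- cohort_spec(n_per_arm = 2, seed = 9)
  prof <- default_profile("control")
  ratios <- vapply(1:60, function(i) {
    d0 <- make_phantom(spec, 0, prof, i)
    d2 <- make_phantom(spec, 2, prof, i)
    d2$truth$sphere_volume_mm3 / d0$truth$sphere_volume_mm3
  }, 0)
  sem <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 2.30), 3 * sem + 0.05)
})

test_that("geometry errors are raised for tumors exceeding the grid", {
  spec <- small_spec()
  spec$tumor_radius_mm <- 3.5
  spec$max_tumor_radius_mm <- 5
  expect_error(make_phantom(spec, 0, cv0_profile("control"), 1), "geometry")
})

test_that("multi-echo forward signal follows S0 exp(-TE/T2) with SPION offset", {
  spec <- small_spec(noise_sigma = 0)
  spec$tissue$tumor$t2 <- 50
  ph <- make_phantom(spec, 0, cv0_profile("control"), 1)
  se <- forward_multiecho(ph, "spin_echo", echo_times = c(10, 30, 50),
                          noise_sigma = 0, seed = 1)
  tum <- ph$labels == "tumor"
  s0 <- ph$s0[tum][1]
  expect_equal(se$volumes[[3]]$data[tum][1] / s0, exp(-1), tolerance = 1e-12)
  # post-SPION fitted-rate difference equals the encoded delta-R2
  pre <- fit_relaxation(forward_multiecho(ph, "spin_echo", "pre_spion",
                                          noise_sigma = 0, seed = 1))
  post <- fit_relaxation(forward_multiecho(ph, "spin_echo", "post_spion",
                                           noise_sigma = 0, seed = 1))
  dr <- delta_r_maps(pre, post)
  expect_equal(mean(dr$delta[tum]), ph$truth$tumor$dr2, tolerance = 1e-9)
})

test_that("Rician noise floor matches sigma * sqrt(pi/2)", {
  sigma <- 3
  vals <- withr::with_seed(1, rician_noise(array(0, c(100000, 1, 1)), sigma))
  expect_equal(mean(vals), sigma * sqrt(pi / 2), tolerance = 0.01)
})

test_that("DWI forward model and noiseless ADC round-trip", {
  spec <- small_spec(noise_sigma = 0)
  spec$tissue$tumor$adc <- 7e-4
  ph <- make_phantom(spec, 0, cv0_profile("control"), 1)
  dwi <- forward_dwi(ph, noise_sigma = 0, seed = 1)
  tum <- ph$labels == "tumor"
  expect_equal(dwi$volumes[[3]]$data[tum][1] / dwi$volumes[[1]]$data[tum][1],
               exp(-1506 * 7e-4), tolerance = 1e-12)
  expect_equal(dwi$volumes[[1]]$data[tum][1], ph$s0[tum][1]) # b = 0 frame is S0
  amap <- fit_adc(dwi)
  expect_equal(amap$adc[tum], rep(7e-4, sum(tum)), tolerance = 1e-12)
})

test_that("DCE forward: flat without transfer, baseline before injection, oracle match", {
  spec <- small_spec(noise_sigma = 0)
  prof <- cv0_profile("control")
  ph <- make_phantom(spec, 0, prof, 1)
  aif <- aif_parameters(); cst <- acquisition_constants()

  ph0 <- ph; ph0$ktrans[] <- 0
  flat <- forward_dce(ph0, aif, cst, n_frames = 30, noise_sigma = 0, seed = 1)
  sig <- vapply(flat$frames, function(f) f[20, 20], 0)
  expect_equal(sig, rep(sig[1], 30))

  dce <- forward_dce(ph, aif, cst, n_frames = 60, noise_sigma = 0, seed = 1)
  slice <- attr(dce, "slice")
  tum2d <- ph$labels[, , slice] == "tumor"
  y <- vapply(dce$frames, function(f) mean(f[tum2d]), 0)
  inj <- dce$injection_index
  expect_equal(y[seq_len(inj)], rep(y[1], inj)) # pre-injection at baseline

  # noiseless curve equals the trapezoidal-convolution oracle of the AIF
  kt <- ph$truth$tumor$ktrans; ve <- ph$truth$tumor$ve
  times <- dce$frame_times; t0 <- times[inj]
  dt <- 0.01 / 60 # 0.01 s in minutes
  tg <- seq(0, (max(times) - t0) / 60, by = dt)
  cp <- aif_concentration(tg, aif)
  kep <- kt / ve
  conv <- function(tq) { # Ktrans * int Cp(tau) exp(-kep (t - tau)) dtau
    tt <- c(tg[tg < tq], tq) # include the exact endpoint
    g <- aif_concentration(tt, aif) * exp(kep * tt)
    kt * exp(-kep * tq) * gliomark:::trapz(tt, g)
  }
  post <- which(times > t0)
  ct_oracle <- vapply((times[post] - t0) / 60, conv, 0)
  s_oracle <- ph$s0[ph$labels == "tumor"][1] *
    spgr_signal(ph$r1_0 + cst$r1_gd * ct_oracle, dce$tr, dce$flip_angle)
  expect_equal(y[post], s_oracle, tolerance = 1e-6)

  # degenerate parameters refused
  phd <- ph; phd$ve[] <- 0
  expect_error(forward_dce(phd, aif, cst, noise_sigma = 0), "degenerate")
})
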