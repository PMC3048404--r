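test_that("AIF: initial value, monotone decay, closed-form integral", {
  aif <- aif_parameters()
  expect_equal(aif_concentration(0, aif), aif$dose * (aif$a1 + aif$a2))
  expect_equal(aif_concentration(1e6, aif), 0, tolerance = 1e-12)
  tg <- seq(0, 30, by = 0.1)
  expect_true(all(diff(aif_concentration(tg, aif)) < 0))
  expect_error(aif_concentration(-1, aif), "t must be")
  # integral over [0, Inf) = D (a1/m1 + a2/m2), quadrature vs closed form
  q <- stats::integrate(aif_concentration, 0, Inf, aif = aif,
                        rel.tol = 1e-10)$value
  expect_equal(q, aif$dose * (aif$a1 / aif$m1 + aif$a2 / aif$m2),
               tolerance = 1e-8)
})

test_that("tissue concentration: zeros, positivity, removable singularity", {
  aif <- aif_parameters()
  tg <- seq(0, 10, by = 0.05)
  expect_equal(tissue_concentration(tg, 0, 0.3, aif), rep(0, length(tg)))
  ct <- tissue_concentration(tg, 0.1, 0.3, aif)
  expect_equal(ct[1], 0)
  expect_true(all(ct >= 0))
  # kep -> m1 limit is continuous (term becomes a1 t exp(-m1 t))
  ve_sing <- 0.1 / aif$m1 # makes kep exactly m1
  ct_sing <- tissue_concentration(tg, 0.1, ve_sing, aif)
  ct_near <- tissue_concentration(tg, 0.1, ve_sing * (1 + 1e-5), aif)
  expect_equal(ct_sing, ct_near, tolerance = 1e-3)
  expect_error(tissue_concentration(tg, 0.1, 0, aif), "degenerate")
})

test_that("closed-form tissue curves match trapezoidal convolution on a 5x5 grid", {
  aif <- aif_parameters()
  tq <- c(0.5, 1, 2, 4, 8) # minutes
  dt <- 0.01 / 60
  tg <- seq(0, max(tq), by = dt)
  cp <- aif_concentration(tg, aif)
  for (kt in c(0.02, 0.05, 0.1, 0.3, 0.8)) {
    for (ve in c(0.1, 0.2, 0.3, 0.45, 0.6)) {
      kep <- kt / ve
      ekt <- exp(kep * tg)
      cum <- c(0, cumsum((cp[-1] * ekt[-1] + cp[-length(cp)] * ekt[-length(cp)]) / 2 * dt))
      oracle <- kt * exp(-kep * tg) * cum
      idx <- vapply(tq, function(q) which.min(abs(tg - q)), 0L)
      closed <- tissue_concentration(tg[idx], kt, ve, aif)
      expect_equal(closed, oracle[idx], tolerance = 1e-6)
    }
  }
})

test_that("SPGR signal: flip-angle limits, saturation, monotonicity in R1", {
  expect_equal(spgr_signal(0.5, 50, 90, 2), 2 * (1 - exp(-0.05 * 0.5)))
  expect_equal(spgr_signal(1e6, 50, 35, 3), 3 * sin(35 * pi / 180),
               tolerance = 1e-9)
  r1g <- seq(0.1, 20, by = 0.1)
  expect_true(all(diff(spgr_signal(r1g, 50, 35)) > 0))
  expect_error(spgr_signal(0, 50, 35), "r1")
})

test_that("R1 dynamics are linear in concentration", {
  expect_equal(r1_dynamics(0, 0.526, 3.3), 0.526)
  expect_equal(r1_dynamics(2, 0.526, 3.3) - 0.526,
               2 * (r1_dynamics(1, 0.526, 3.3) - 0.526))
  expect_error(r1_dynamics(-1, 0.5, 3.3), "finite")
})

test_that("Tofts fit recovers noiseless parameters and is scale invariant", {
  aif <- aif_parameters(); cst <- acquisition_constants()
  times <- (0:99) * 4.8
  for (truth in list(c(kt = 0.05, ve = 0.2), c(kt = 0.3, ve = 0.45))) {
    y <- gliomark:::dce_model_signal(times, times[7], truth["kt"], truth["ve"],
                                     500, 50, 35, 1 / 1.9, cst$r1_gd, aif)
    ser <- dce_series(lapply(y, function(v) matrix(v, 1, 1)), times,
                      injection_index = 7L)
    fit <- fit_tofts(ser, signal = y, aif = aif, constants = cst)
    expect_true(fit$converged)
    expect_equal(fit$ktrans, unname(truth["kt"]), tolerance = 1e-3)
    expect_equal(fit$ve, unname(truth["ve"]), tolerance = 1e-3)
    expect_equal(fit$kep, fit$ktrans / fit$ve, tolerance = 1e-12)
    expect_gt(fit$goodness, 0.999999)
    # global signal scaling is absorbed by s_scale
    fit2 <- fit_tofts(ser, signal = y * 1234, aif = aif, constants = cst)
    expect_equal(fit2$ktrans, fit$ktrans, tolerance = 1e-6)
    expect_equal(fit2$ve, fit$ve, tolerance = 1e-6)
  }
})

test_that("Tofts fit preconditions and failure path", {
  aif <- aif_parameters(); cst <- acquisition_constants()
  times <- (0:14) * 4.8
  y <- rep(1, 15)
  ser <- dce_series(lapply(y, function(v) matrix(v, 1, 1)), times,
                    injection_index = 10L)
  expect_error(fit_tofts(ser, signal = y, aif = aif, constants = cst),
               "post-injection")
  times2 <- (0:49) * 4.8
  ser2 <- dce_series(lapply(1:50, function(v) matrix(v, 1, 1)), times2,
                     injection_index = 2L)
  expect_error(fit_tofts(ser2, signal = rep(1, 50), aif = aif, constants = cst),
               "baseline")
  bad <- dce_series(lapply(1:50, function(v) matrix(v, 1, 1)), times2,
                    injection_index = 7L)
  res <- fit_tofts(bad, signal = c(rep(1, 10), NaN, rep(1, 39)), aif = aif,
                   constants = cst)
  expect_false(res$converged)
  expect_true(is.na(res$ktrans))
})

test_that("injection detection finds the arrival frame", {
  aif <- aif_parameters(); cst <- acquisition_constants()
  times <- (0:99) * 4.8
  y <- gliomark:::dce_model_signal(times, times[12], 0.2, 0.3, 100, 50, 35,
                                   1 / 1.9, cst$r1_gd, aif)
  yn <- withr::with_seed(3, y + rnorm(100, 0, 0.1))
  expect_true(abs(detect_injection(yn) - 12) <= 1)
})

test_that("parameter recovery degrades as baseline frames vanish", {
  aif <- aif_parameters(); cst <- acquisition_constants()
  times <- (0:99) * 4.8
  err <- sapply(c(3, 20), function(inj) {
    y0 <- gliomark:::dce_model_signal(times, times[inj], 0.1, 0.3, 100, 50, 35,
                                      1 / 1.9, cst$r1_gd, aif)
    reps <- vapply(1:12, function(r) {
      yn <- withr::with_seed(1000 + r, as.numeric(
        rician_noise(array(y0, c(100, 1, 1)), 0.05 * y0[1])))
      ser <- dce_series(lapply(yn, function(v) matrix(v, 1, 1)), times,
                        injection_index = inj)
      fit <- fit_tofts(ser, signal = yn, aif = aif, constants = cst)
      abs(fit$ktrans - 0.1) / 0.1
    }, 0)
    sqrt(mean(reps^2))
  })
  expect_lte(err[2], err[1]) # more baseline anchoring never hurts
})
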