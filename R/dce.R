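# Tofts two-compartment DCE-MRI model: bi-exponential AIF, closed-form
# tissue concentration, longitudinal relaxation dynamics, SPGR signal, and
# bounded multi-start nonlinear estimation of (Ktrans, ve).

#' Plasma concentration of the bi-exponential AIF
#'
#' `Cp(t) = D (a1 e^{-m1 t} + a2 e^{-m2 t})`, positive and monotone
#' decreasing for `t > 0`; `t` is in minutes since injection.
#'
#' @param t Time(s) in minutes since injection, `>= 0`.
#' @param aif An [aif_parameters()].
#' @return Plasma concentration in mM-equivalents.
#' @export
aif_concentration <- function(t, aif = aif_parameters()) {
  if (any(t < 0)) stop_domain("aif_concentration: t must be >= 0")
  aif$dose * (aif$a1 * exp(-aif$m1 * t) + aif$a2 * exp(-aif$m2 * t))
}

#' Closed-form Tofts tissue concentration
#'
#' `Ct(t) = D Ktrans sum_i a_i (e^{-kep t} - e^{-m_i t}) / (m_i - kep)` with
#' `kep = Ktrans/ve`; equals the convolution
#' `Ktrans * integral Cp(tau) e^{-kep (t - tau)} dtau`. The removable
#' singularity at `kep = m_i` uses the limit form `a_i t e^{-m_i t}`.
#' Vectorized over `t` or over `(ktrans, ve)` (one of the two scalar).
#'
#' @param t Minutes since injection, `>= 0`.
#' @param ktrans Volume transfer constant, min^-1, `>= 0`.
#' @param ve Extravascular-extracellular volume fraction in (0, 1).
#' @param aif An [aif_parameters()].
#' @return Tissue concentration (same units as the AIF).
#' @export
tissue_concentration <- function(t, ktrans, ve, aif = aif_parameters()) {
  if (any(t < 0)) stop_domain("tissue_concentration: t must be >= 0")
  if (any(ktrans < 0)) stop_domain("tissue_concentration: ktrans must be >= 0")
  if (any(ve <= 0 & ktrans > 0))
    stop_domain("tissue_concentration: degenerate parameters - ve = 0 with ktrans > 0")
  kep <- ifelse(ktrans > 0, ktrans / ve, 0)
  term <- function(a, m) {
    reg <- abs(m - kep) >= 1e-8
    d <- ifelse(reg, m - kep, 1)
    regular <- a * (exp(-kep * t) - exp(-m * t)) / d
    limit <- a * t * exp(-m * t)
    if (length(reg) == 1L) {
      if (reg) regular else limit
    } else {
      ifelse(reg, regular, limit)
    }
  }
  aif$dose * ktrans * (term(aif$a1, aif$m1) + term(aif$a2, aif$m2))
}

#' Longitudinal relaxation rate under contrast
#'
#' `R1(t) = R1(0) + r1 * Ct(t)` - linear fast-exchange relaxivity model.
#'
#' @param c_t Tissue concentration (mM).
#' @param r1_0 Pre-contrast longitudinal rate, s^-1.
#' @param r1_gd Contrast-agent relaxivity, mM^-1 s^-1.
#' @export
r1_dynamics <- function(c_t, r1_0, r1_gd) {
  if (any(!is.finite(c_t)) || any(c_t < 0))
    stop_domain("r1_dynamics: concentrations must be finite and >= 0")
  r1_0 + r1_gd * c_t
}

#' Spoiled-gradient-echo steady-state signal
#'
#' `S = s_scale sin(a) (1 - E) / (1 - cos(a) E)` with `E = exp(-TR * R1)`;
#' strictly increasing in `R1` for flip angles in (0, 90].
#'
#' @param r1 Longitudinal rate(s), s^-1, `> 0`.
#' @param tr Repetition time, ms.
#' @param flip Flip angle, degrees.
#' @param s_scale Arbitrary signal scale.
#' @export
spgr_signal <- function(r1, tr, flip, s_scale = 1) {
  if (any(r1 <= 0)) stop_domain("spgr_signal: r1 must be > 0")
  a <- flip * pi / 180
  e1 <- exp(-tr / 1000 * r1)
  s_scale * sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

# Full signal model S(t) for an ROI: pre-injection frames at baseline.
dce_model_signal <- function(times_s, t0_s, ktrans, ve, s_scale, tr, flip,
                             r1_0, r1_gd, aif) {
  s <- rep(s_scale * spgr_signal(r1_0, tr, flip), length(times_s))
  post <- times_s > t0_s
  if (any(post) && ktrans > 0) {
    tmin <- (times_s[post] - t0_s) / 60
    ct <- tissue_concentration(tmin, ktrans, ve, aif)
    s[post] <- s_scale * spgr_signal(r1_dynamics(ct, r1_0, r1_gd), tr, flip)
  }
  s
}

#' Detect the contrast-arrival frame
#'
#' Argmax of the baseline-z-scored signal derivative; used when a series
#' does not carry an `injection_index`. The prior is an injection roughly
#' 30 s after the start of the acquisition.
#'
#' @param y Signal time course.
#' @param n_baseline Frames used to estimate the baseline derivative noise.
#' @return 1-based index of the last pre-contrast frame.
#' @export
detect_injection <- function(y, n_baseline = 5) {
  dy <- diff(y)
  s <- stats::sd(dy[seq_len(min(n_baseline, length(dy)))])
  if (!is.finite(s) || s == 0) s <- 1
  which.max(dy / s)
}

#' Fitted Tofts parameters
#'
#' @param ktrans,ve Fitted values (min^-1, fraction); `kep` is derived as
#'   `ktrans / ve`.
#' @param r1_0 Baseline longitudinal rate used, s^-1.
#' @param goodness R-squared of the signal fit.
#' @param converged Logical convergence flag.
#' @param s_scale Fitted signal scale.
#' @export
tofts_parameters <- function(ktrans, ve, r1_0, goodness = NA_real_,
                             converged = NA, s_scale = NA_real_) {
  kep <- if (isTRUE(is.finite(ktrans)) && isTRUE(is.finite(ve))) ktrans / ve
         else NA_real_
  structure(list(ktrans = ktrans, ve = ve, kep = kep, r1_0 = r1_0,
                 goodness = goodness, converged = converged,
                 s_scale = s_scale),
            class = "tofts_parameters")
}

#' Fit the Tofts model to a DCE signal time course
#'
#' Bounded Levenberg-Marquardt least squares over `(Ktrans, ve, s_scale)`
#' minimizing signal residuals of the composed SPGR/relaxivity/Tofts model,
#' multi-started over a 3x3 log grid of `(Ktrans, ve)`; ties are broken by
#' lowest residual then lowest Ktrans. The signal scale is anchored by the
#' pre-injection baseline frames, making the fit invariant to global signal
#' scaling. A fit that converges from no start returns an `NA` record with
#' `converged = FALSE` rather than raising.
#'
#' @param series A [dce_series].
#' @param signal Optional explicit time course; default is the ROI-mean
#'   signal over `roi`.
#' @param roi Optional logical matrix matching the frame grid.
#' @param aif An [aif_parameters()].
#' @param constants An [acquisition_constants()] (supplies `r1_gd`).
#' @param r1_0 Pre-contrast longitudinal rate, s^-1 (fixed from config; the
#'   protocol has no pre-contrast T1 mapping).
#' @param starts Optional data.frame of `ktrans`, `ve` start values.
#' @return A [tofts_parameters()] object.
#' @export
fit_tofts <- function(series, signal = NULL, roi = NULL,
                      aif = aif_parameters(),
                      constants = acquisition_constants(),
                      r1_0 = 1 / 1.9, starts = NULL) {
  y <- if (!is.null(signal)) as.numeric(signal)
  else if (!is.null(roi))
    vapply(series$frames, function(f) mean(f[roi]), 0)
  else stop_domain("fit_tofts: supply a signal vector or an roi mask")

  times <- series$frame_times
  inj <- series$injection_index
  if (is.null(inj) || is.na(inj)) inj <- detect_injection(y)
  if (length(y) - inj < 10)
    stop_domain("fit_tofts: need >= 10 post-injection frames")
  if (inj < 3) stop_domain("fit_tofts: need >= 3 baseline frames")
  t0 <- times[inj]
  baseline <- mean(y[seq_len(inj)])
  sc0 <- baseline / spgr_signal(r1_0, series$tr, series$flip_angle)

  if (is.null(starts))
    starts <- expand.grid(ktrans = c(0.02, 0.1, 0.5), ve = c(0.1, 0.2, 0.45))

  resid_fn <- function(p)
    y - dce_model_signal(times, t0, p[1], p[2], p[3], series$tr,
                         series$flip_angle, r1_0, constants$r1_gd, aif)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(starts$ktrans[i], starts$ve[i], sc0),
                         fn = resid_fn,
                         lower = c(0, 1e-4, 1e-12),
                         upper = c(10, 0.999, Inf),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    rss <- fit$deviance
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 && fit$par[1] < best$par[1]))
      best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best))
    return(tofts_parameters(NA_real_, NA_real_, r1_0, converged = FALSE))
  tss <- sum((y - mean(y))^2)
  tofts_parameters(best$par[1], best$par[2], r1_0,
                   goodness = 1 - best$rss / tss, converged = TRUE,
                   s_scale = best$par[3])
}
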