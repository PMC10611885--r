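#' Convert a DCE-MRI signal series to contrast-agent concentration
#'
#' Inverts the spoiled-gradient-echo signal equation
#' `S = M0 sin(a) (1 - E1) / (1 - cos(a) E1)` with `E1 = exp(-TR * R1)`.
#' `M0` is estimated from the pre-contrast baseline frames given the native
#' `T10`; concentration follows from relaxivity: `C = (R1 - 1/T10) / r1`.
#' The `"linear"` mode uses the low-concentration approximation
#' `C = (S/S0 - 1) / (r1 * T10)`, which only depends on the signal ratio.
#'
#' @param signal Signal time series (vector).
#' @param T10_s Native longitudinal relaxation time, s.
#' @param r1_per_mM_s Contrast relaxivity, /mM/s (default 4.5 at 3 T).
#' @param TR_s Repetition time, s.
#' @param flip_deg Flip angle, degrees.
#' @param baseline_frames Number of leading pre-bolus frames.
#' @param mode `"spgr"` (full inversion) or `"linear"`.
#' @return Concentration series, mM.
#' @export
dce_signal_to_concentration <- function(signal, T10_s, r1_per_mM_s = 4.5,
                                        TR_s = 0.004, flip_deg = 12,
                                        baseline_frames = 5,
                                        mode = c("spgr", "linear")) {
  mode <- match.arg(mode)
  if (any(signal <= 0)) stop("signal must be positive", call. = FALSE)
  stopifnot(T10_s > 0, baseline_frames >= 1, baseline_frames < length(signal))
  s0 <- mean(signal[seq_len(baseline_frames)])
  if (mode == "linear") {
    return((signal / s0 - 1) / (r1_per_mM_s * T10_s))
  }
  a <- flip_deg * pi / 180
  R10 <- 1 / T10_s
  E10 <- exp(-TR_s * R10)
  M0 <- s0 * (1 - cos(a) * E10) / (sin(a) * (1 - E10))
  E1 <- (M0 * sin(a) - signal) / (M0 * sin(a) - signal * cos(a))
  if (any(E1 <= 0 | E1 >= 1)) {
    E1 <- pmin(pmax(E1, 1e-12), 1 - 1e-12)
  }
  R1 <- -log(E1) / TR_s
  (R1 - R10) / r1_per_mM_s
}

#' Forward spoiled-gradient-echo signal from a concentration series
#'
#' Companion to [dce_signal_to_concentration()]; used by the phantom generator
#' and for roundtrip validation.
#'
#' @param conc Concentration series, mM.
#' @param M0 Equilibrium signal scale.
#' @inheritParams dce_signal_to_concentration
#' @return Signal series.
#' @export
spgr_signal <- function(conc, M0 = 1000, T10_s = 1.4, r1_per_mM_s = 4.5,
                        TR_s = 0.004, flip_deg = 12) {
  a <- flip_deg * pi / 180
  R1 <- 1 / T10_s + r1_per_mM_s * conc
  E1 <- exp(-TR_s * R1)
  M0 * sin(a) * (1 - E1) / (1 - cos(a) * E1)
}

#' Extended Tofts model fit for DCE-MRI
#'
#' `Ct(t) = vp * Cp(t) + Ktrans * int_0^t Cp(tau) exp(-kep (t - tau)) dtau`,
#' fitted by bounded Levenberg-Marquardt on the acquisition grid;
#' `ve = Ktrans / kep` is derived (and exactly consistent by construction).
#'
#' @param conc Tibble `time_min`, `conc_mM`: tissue concentration.
#' @param plasma_conc Tibble `time_min`, `conc_mM`: plasma concentration.
#' @param multistart Number of random restarts (default 5).
#' @param seed Seed for restart draws.
#' @return Object of class `tofts_fit`: list with `Ktrans` (/min), `kep`
#'   (/min), `ve`, `vp`, `rss`, `converged`.
#' @export
fit_extended_tofts <- function(conc, plasma_conc, multistart = 5, seed = 1) {
  t <- conc$time_min
  ct <- conc$conc_mM
  cp <- stats::approx(plasma_conc$time_min, plasma_conc$conc_mM, xout = t, rule = 2)$y
  if (max(cp) <= 0) stop("plasma curve has no bolus", call. = FALSE)
  dt <- stats::median(diff(t))
  model <- function(Ktrans, kep, vp) {
    vp * cp + Ktrans * conv_grid(cp, exp(-kep * t), dt)
  }
  resid_fn <- function(par) model(par[1], par[2], par[3]) - ct
  lo <- c(0, 1e-4, 0); hi <- c(5, 10, 0.5)
  starts <- list(c(0.05, 0.5, 0.02))
  old <- get_rng_state(); set.seed(seed)
  for (i in seq_len(max(multistart - 1, 0))) {
    starts[[i + 1]] <- c(stats::runif(1, 0, 0.5), stats::runif(1, 0.05, 3),
                         stats::runif(1, 0, 0.1))
  }
  restore_rng_state(old)
  best <- NULL; n_conv <- 0
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn, lower = lo, upper = hi,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (fit$info %in% 1:4) n_conv <- n_conv + 1
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best)) stop("extended Tofts fit failed from every start", call. = FALSE)
  p <- best$par
  structure(
    list(Ktrans = p[1], kep = p[2], ve = p[1] / p[2], vp = p[3],
         rss = best$rss, converged = n_conv > 0),
    class = "tofts_fit"
  )
}

#' @export
print.tofts_fit <- function(x, ...) {
  cat("<tofts_fit> Ktrans =", signif(x$Ktrans, 4), "/min, kep =",
      signif(x$kep, 4), "/min, ve =", signif(x$ve, 4), ", vp =",
      signif(x$vp, 4), "\n")
  invisible(x)
}

#' DSC-MRI perfusion quantification
#'
#' From gradient-echo dynamic susceptibility signals:
#' `dR2*(t) = -log(S/S0) / TE` for tissue and AIF. CBV is the ratio of the
#' curve integrals. Leakage is corrected Boxerman-style by regressing the
#' tissue curve on a non-leaky reference curve and its running integral
#' (`tissue ~ K1 * ref - K2 * int(ref)`); the leakage term `K2` is added back
#' to form the corrected curve and `CBVlc`. CBF comes from block-circulant
#' SVD deconvolution of the tissue curve with the AIF (singular values below
#' `svd_threshold` of the maximum zeroed); `CBF = max` of the deconvolved
#' residue, `MTT = CBV / CBF`, `TTP` = time of the tissue curve maximum.
#'
#' @param tissue_signal,aif_signal Signal series (vectors, same grid).
#' @param time_s Acquisition times, s.
#' @param TE_s Echo time, s.
#' @param baseline_frames Number of pre-bolus frames (>= 5).
#' @param reference_curve Optional non-leaky reference dR2* curve (e.g. the
#'   mean over non-lesion brain); when `NULL`, leakage correction is skipped
#'   and `CBVlc = CBV`.
#' @param svd_threshold Relative singular-value cutoff (default 0.2).
#' @return A one-row tibble of class `dsc_result`: `cbv`, `cbvlc`, `cbf_per_s`,
#'   `mtt_s`, `ttp_s`, `k_leak_per_s`.
#' @export
dsc_quantify <- function(tissue_signal, aif_signal, time_s, TE_s,
                         baseline_frames = 5, reference_curve = NULL,
                         svd_threshold = 0.2) {
  stopifnot(TE_s > 0, baseline_frames >= 5)
  if (any(tissue_signal <= 0) || any(aif_signal <= 0))
    stop("DSC signals must be positive", call. = FALSE)
  base <- seq_len(baseline_frames)
  dr2_t <- -log(tissue_signal / mean(tissue_signal[base])) / TE_s
  dr2_a <- -log(aif_signal / mean(aif_signal[base])) / TE_s
  int_a <- pracma::trapz(time_s, dr2_a)
  if (abs(int_a) < 1e-12) stop("AIF integral is (near) zero", call. = FALSE)
  cbv <- pracma::trapz(time_s, dr2_t) / int_a

  k_leak <- 0
  cbvlc <- cbv
  if (!is.null(reference_curve)) {
    cum_ref <- pracma::cumtrapz(time_s, reference_curve)[, 1]
    X <- cbind(reference_curve, -cum_ref)
    cf <- stats::lsfit(X, dr2_t, intercept = FALSE)$coefficients
    k_leak <- unname(cf[2])
    corrected <- dr2_t + k_leak * cum_ref
    cbvlc <- pracma::trapz(time_s, corrected) / int_a
  }

  dt <- stats::median(diff(time_s))
  n <- length(dr2_t)
  L <- 2 * n
  a_pad <- c(dr2_a, rep(0, L - n))
  c_pad <- c(dr2_t, rep(0, L - n))
  A <- matrix(0, L, L)
  for (j in seq_len(L)) A[, j] <- a_pad[((seq_len(L) - j) %% L) + 1]
  A <- A * dt
  sv <- svd(A)
  dinv <- ifelse(sv$d >= svd_threshold * max(sv$d), 1 / sv$d, 0)
  r <- sv$v %*% (dinv * (t(sv$u) %*% c_pad))
  cbf <- max(r[seq_len(n)])
  mtt <- if (cbf > 0) cbv / cbf else NA_real_
  ttp <- time_s[which.max(dr2_t)]

  out <- tibble::tibble(cbv = cbv, cbvlc = cbvlc, cbf_per_s = cbf,
                        mtt_s = mtt, ttp_s = ttp, k_leak_per_s = k_leak)
  class(out) <- c("dsc_result", class(out))
  out
}

#' Pulsed-ASL (QUIPSS II) cerebral blood flow
#'
#' `CBF = 6000 * lambda * dM / (2 * alpha * M0 * TI1 * exp(-TI2 / T1b))`
#' in mL/100g/min.
#'
#' @param delta_M Label-control difference signal (scalar or array).
#' @param M0 Equilibrium magnetisation (same shape or scalar, > 0).
#' @param constants Named list: `lambda_blood_partition` (mL/g, default 0.9),
#'   `inversion_efficiency` (default 0.98), `T1_blood_s` (default 1.65),
#'   `TI1_s` (default 0.7), `TI2_s` (default 1.8).
#' @return CBF in mL/100g/min, same shape as `delta_M`.
#' @export
asl_cbf <- function(delta_M, M0, constants = list()) {
  k <- utils::modifyList(
    list(lambda_blood_partition = 0.9, inversion_efficiency = 0.98,
         T1_blood_s = 1.65, TI1_s = 0.7, TI2_s = 1.8),
    constants
  )
  if (any(M0 <= 0)) stop("M0 must be positive", call. = FALSE)
  6000 * k$lambda_blood_partition * delta_M /
    (2 * k$inversion_efficiency * M0 * k$TI1_s * exp(-k$TI2_s / k$T1_blood_s))
}

#' @rdname asl_cbf
#' @param cbf_ml_100g_min CBF to forward-generate a difference signal from.
#' @export
asl_delta_m <- function(cbf_ml_100g_min, M0, constants = list()) {
  k <- utils::modifyList(
    list(lambda_blood_partition = 0.9, inversion_efficiency = 0.98,
         T1_blood_s = 1.65, TI1_s = 0.7, TI2_s = 1.8),
    constants
  )
  cbf_ml_100g_min * (2 * k$inversion_efficiency * M0 * k$TI1_s *
                       exp(-k$TI2_s / k$T1_blood_s)) /
    (6000 * k$lambda_blood_partition)
}

#' Apparent diffusion coefficient by log-linear fit
#'
#' `ln S(b) = ln S0 - b * ADC` fitted by ordinary least squares over the
#' acquired b-values; exact for noiseless mono-exponential decay.
#'
#' @param signals Diffusion-weighted signals, > 0.
#' @param b_values_s_mm2 b-values, s/mm^2 (>= 2 distinct).
#' @return A one-row tibble: `adc_mm2_s`, `s0`, `n_bvalues`.
#' @export
fit_adc <- function(signals, b_values_s_mm2) {
  if (any(signals <= 0)) stop("signals must be positive", call. = FALSE)
  if (length(unique(b_values_s_mm2)) < 2)
    stop("need at least 2 distinct b-values", call. = FALSE)
  fit <- stats::lm(log(signals) ~ b_values_s_mm2)
  tibble::tibble(
    adc_mm2_s = -unname(stats::coef(fit)[2]),
    s0 = exp(unname(stats::coef(fit)[1])),
    n_bvalues = length(unique(b_values_s_mm2))
  )
}

#' Normalise a parameter map or value set to contralateral white matter
#'
#' @param values Numeric array/vector of parameter values.
#' @param cwm_values Values over the contralateral-white-matter region, or a
#'   [voi_mask()] together with `map` semantics: if a mask is given, `values`
#'   must be an array over the same grid and the CWM mean is taken from it.
#' @return `values / mean(CWM values)`.
#' @export
normalize_to_cwm <- function(values, cwm_values) {
  if (inherits(cwm_values, "voi_mask")) {
    if (sum(cwm_values$voxels) == 0) stop("CWM mask is empty", call. = FALSE)
    cwm_values <- values[cwm_values$voxels]
  }
  if (length(cwm_values) == 0) stop("CWM region is empty", call. = FALSE)
  m <- mean(cwm_values)
  if (m <= 0) stop("CWM mean must be positive", call. = FALSE)
  values / m
}
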