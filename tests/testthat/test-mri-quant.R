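test_that("SPGR signal inversion is a faithful roundtrip", {
  t <- seq(0, 5, by = 0.1)
  conc <- 2 * gamma_bolus(t, 0.6, 3, 0.25)
  sig <- spgr_signal(conc, M0 = 1200, T10_s = 1.4)
  back <- dce_signal_to_concentration(sig, T10_s = 1.4, baseline_frames = 5)
  expect_lt(max(abs(back - conc)), 1e-6)

  # constant baseline signal maps to zero concentration
  flat <- rep(spgr_signal(0, M0 = 1000), 20)
  expect_lt(max(abs(dce_signal_to_concentration(flat, T10_s = 1.4, baseline_frames = 5))), 1e-9)

  # linear mode depends only on the signal ratio
  s1 <- spgr_signal(conc, M0 = 1000)
  c1 <- dce_signal_to_concentration(s1, T10_s = 1.4, baseline_frames = 5, mode = "linear")
  c2 <- dce_signal_to_concentration(2 * s1, T10_s = 1.4, baseline_frames = 5, mode = "linear")
  expect_equal(c1, c2, tolerance = 1e-12)

  expect_error(dce_signal_to_concentration(c(-1, 1, 1, 1, 1, 1), T10_s = 1.4), "positive")
})

test_that("extended Tofts fit: vascular-only identity and inverse-crime recovery", {
  t <- seq(0, 5, by = 0.1)
  cp <- gd_bolus_test(t)
  plasma <- tibble::tibble(time_min = t, conc_mM = cp)

  # Ktrans = 0: tissue is a scaled plasma curve
  ct0 <- tibble::tibble(time_min = t, conc_mM = 0.05 * cp)
  f0 <- fit_extended_tofts(ct0, plasma)
  expect_lt(abs(f0$vp - 0.05), 1e-6)
  expect_lt(f0$Ktrans, 1e-6)

  # full recovery of (Ktrans, ve, vp)
  p <- list(Ktrans = 0.1, ve = 0.2, vp = 0.02)
  kep <- p$Ktrans / p$ve
  ct <- p$vp * cp + p$Ktrans * fpiaquant:::conv_grid(cp, exp(-kep * t), 0.1)
  fit <- fit_extended_tofts(tibble::tibble(time_min = t, conc_mM = ct), plasma)
  expect_lt(abs(fit$Ktrans / p$Ktrans - 1), 0.01)
  expect_lt(abs(fit$ve / p$ve - 1), 0.01)
  expect_lt(abs(fit$vp / p$vp - 1), 0.01)
  # ve = Ktrans/kep holds exactly in the returned object
  expect_equal(fit$ve, fit$Ktrans / fit$kep, tolerance = 1e-12)
})

test_that("grade presets produce higher fitted ve in grade IV than grade II", {
  ves <- sapply(c(2, 4), function(g) {
    st <- generate_study(small_phantom(grade = g, seed = 41))
    quantify_study(st)$ve
  })
  expect_gt(ves[2], ves[1])
})

test_that("DSC quantification: null leakage, box-residue deconvolution, gamma TTP", {
  t <- seq(0, 90, by = 1.5)
  TE <- 0.03
  aif_dr2 <- 40 * gamma_bolus(t, 15, 3, 2.5)   # bolus starting at 15 s
  aif_sig <- 1000 * exp(-TE * aif_dr2)

  # tissue = AIF (x) box residue, height F, width W: computed analytically on a
  # fine grid as F * (int_{t-W}^{t} aif), then sampled at the acquisition times
  F_true <- 0.01; W_true <- 8
  tf <- seq(0, 90, by = 0.05)
  aif_f <- 40 * gamma_bolus(tf, 15, 3, 2.5)
  cum_f <- c(0, cumsum(diff(tf) * (head(aif_f, -1) + tail(aif_f, -1)) / 2))
  cum_at <- function(tt) approx(tf, cum_f, xout = pmax(tt, 0), rule = 2)$y
  tis_dr2 <- F_true * (cum_at(t) - cum_at(t - W_true))
  tis_sig <- 1000 * exp(-TE * tis_dr2)
  res <- dsc_quantify(tis_sig, aif_sig, t, TE, baseline_frames = 8)
  expect_lt(abs(res$cbf_per_s / F_true - 1), 0.10)
  expect_lt(abs(res$mtt_s / W_true - 1), 0.10)
  expect_equal(res$cbv, F_true * W_true, tolerance = 0.02 * F_true * W_true)

  # no-leakage tissue: k_leak ~ 0 and CBVlc = CBV within 1%
  ref <- 0.5 * tis_dr2
  res_lc <- dsc_quantify(tis_sig, aif_sig, t, TE, baseline_frames = 8,
                         reference_curve = ref)
  expect_lt(abs(res_lc$k_leak_per_s), 1e-6)
  expect_lt(abs(res_lc$cbvlc / res_lc$cbv - 1), 0.01)

  # TTP of a gamma-variate bolus matches its analytic mode within one frame
  alpha <- 3; beta <- 2.5; t0 <- 15
  g <- 30 * fpiaquant:::gv_curve(t, t0 = t0, alpha = alpha, beta = beta)
  g_sig <- 1000 * exp(-TE * g)
  res_g <- dsc_quantify(g_sig, aif_sig, t, TE, baseline_frames = 8)
  expect_lt(abs(res_g$ttp_s - (t0 + alpha * beta)), 1.5 + 1e-9)

  # CBV invariant to joint global scaling of both signals' baselines
  res_sc <- dsc_quantify(tis_sig * 3, aif_sig * 3, t, TE, baseline_frames = 8)
  expect_equal(res_sc$cbv, res$cbv, tolerance = 1e-9)
})

test_that("ASL quantification: zero difference, linearity, exact roundtrip", {
  expect_equal(asl_cbf(0, 1000), 0)
  cbf1 <- asl_cbf(5, 1000)
  expect_equal(asl_cbf(5, 2000), cbf1 / 2, tolerance = 1e-12)
  dm <- asl_delta_m(60, 1000)
  expect_lt(abs(asl_cbf(dm, 1000) - 60), 1e-9)
  expect_error(asl_cbf(5, 0), "positive")
})

test_that("ADC fit: exact two-point solution, scale invariance, small noise bias", {
  s <- c(100, 100 * exp(-1))
  b <- c(0, 1000)
  fit <- fit_adc(s, b)
  expect_equal(fit$adc_mm2_s, 1e-3, tolerance = 1e-12)
  expect_equal(fit$s0, 100, tolerance = 1e-9)

  fit2 <- fit_adc(s * 7.5, b)
  expect_equal(fit2$adc_mm2_s, fit$adc_mm2_s, tolerance = 1e-12)

  # mono-exponential input at any >= 2 b-values is recovered exactly
  b3 <- c(0, 500, 1000)
  expect_equal(fit_adc(80 * exp(-b3 * 8e-4), b3)$adc_mm2_s, 8e-4, tolerance = 1e-12)

  set.seed(12)
  adcs <- replicate(100, {
    noisy <- 100 * exp(-b3 * 1e-3) * (1 + rnorm(3, 0, 0.02))
    fit_adc(noisy, b3)$adc_mm2_s
  })
  expect_lt(abs(mean(adcs) / 1e-3 - 1), 0.03)

  expect_error(fit_adc(c(100, -1), b), "positive")
  expect_error(fit_adc(c(100, 90), c(500, 500)), "distinct")
})

test_that("CWM normalisation: unity at the reference, scale invariance", {
  vals <- array(runif(64, 1, 3), c(4, 4, 4))
  cwm <- box_mask(c(4, 4, 4), 1:2, 1:2, 1:2)
  norm <- normalize_to_cwm(vals, cwm)
  expect_equal(mean(norm[cwm$voxels]), 1.0, tolerance = 1e-12)
  norm2 <- normalize_to_cwm(vals * 5.5, cwm)
  expect_equal(norm2, norm, tolerance = 1e-12)
  uni <- array(2, c(4, 4, 4))
  expect_true(all(normalize_to_cwm(uni, cwm) == 1))
  empty <- cwm; empty$voxels[] <- FALSE
  expect_error(normalize_to_cwm(vals, empty), "empty")
})
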