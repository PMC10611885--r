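sched <- default_frame_schedule()

test_that("forward 2TC model limits and late-slope behaviour", {
  aif <- test_aif()
  # K1 = 0 -> pure blood signal
  cb <- tibble::tibble(time_min = aif$time_min, value_kBq_mL = aif$value_kBq_mL * 0.8)
  tac0 <- tissue_response(list(K1 = 0, k2 = 0.1, k3 = 0.05, vb = 0.1), aif,
                          schedule = sched, blood_fn = cb)
  oracle_blood <- vapply(seq_len(nrow(sched)), function(i) {
    sel <- aif$time_min >= sched$start_s[i] / 60 & aif$time_min <= sched$end_s[i] / 60
    mean(0.1 * 0.8 * aif$value_kBq_mL[sel])
  }, numeric(1))
  expect_equal(tac0$value_kBq_mL, oracle_blood, tolerance = 1e-9)

  # constant input, k3 = 0: one-tissue equilibrium (1 - vb) K1/k2
  const_cp <- input_function(seq(0, 400, by = 0.05), rep(1, 8001))
  t_late <- seq(350, 400, by = 1)
  tac1 <- tissue_response(list(K1 = 0.1, k2 = 0.2, k3 = 0, vb = 0), const_cp,
                          times_min = t_late)
  expect_equal(tail(tac1$value_kBq_mL, 1), 0.1 / 0.2, tolerance = 1e-3)

  # constant input, irreversible: late slope (1 - vb) K1 k3/(k2 + k3)
  tac2 <- tissue_response(list(K1 = 0.1, k2 = 0.2, k3 = 0.05, vb = 0), const_cp,
                          times_min = t_late)
  slope <- coef(lm(tac2$value_kBq_mL ~ t_late))[2]
  expect_equal(unname(slope), 0.02, tolerance = 1e-3)
})

test_that("forward model agrees with an independent brute-force convolution", {
  aif <- test_aif()
  p <- list(K1 = 0.08, k2 = 0.25, k3 = 0.04, vb = 0.05)
  tac <- tissue_response(p, aif, schedule = sched)
  oracle <- brute_force_2tc(p, aif, sched)
  expect_lt(max(abs(tac$value_kBq_mL - oracle)) / max(oracle), 0.01)
})

test_that("Patlak fit: exact on a linear identity, accurate on 2TC simulations", {
  # constant Cp = 1 and CT = 0.02 t + 0.5 -> Ki and V0 exact
  cp <- input_function(seq(0, 66.5, by = 0.01), rep(1, 6651))
  mid <- frame_mid_times(sched)
  tac_lin <- tissue_tac(mid, 0.02 * mid + 0.5)
  pf <- patlak_fit(tac_lin, cp)
  expect_equal(pf$Ki, 0.02, tolerance = 1e-10)
  expect_equal(pf$V0, 0.5, tolerance = 1e-9)
  expect_equal(pf$n_points, sum(mid >= 15))

  aif <- test_aif()
  tac <- tissue_response(list(K1 = 0.1, k2 = 0.2, k3 = 0.05, vb = 0), aif, schedule = sched)
  expect_lt(abs(patlak_fit(tac, aif)$Ki / 0.02 - 1), 0.05)

  # reversible tracer: Ki indistinguishable from zero
  tac_rev <- tissue_response(list(K1 = 0.1, k2 = 0.2, k3 = 0, vb = 0), aif, schedule = sched)
  expect_lt(abs(suppressWarnings(patlak_fit(tac_rev, aif))$Ki), 1e-3)

  expect_error(patlak_fit(tac, aif, t_star_min = 62), "3 frames")
})

test_that("Patlak slope converges to K1 k3/(k2+k3) as t_star grows", {
  aif <- test_aif()
  tac <- tissue_response(list(K1 = 0.1, k2 = 0.2, k3 = 0.05, vb = 0), aif, schedule = sched)
  errs <- sapply(c(10, 15, 20), function(ts) abs(patlak_fit(tac, aif, t_star_min = ts)$Ki - 0.02))
  expect_true(all(diff(errs) <= 1e-6))   # nonincreasing error
  expect_lt(errs[3] / 0.02, 0.05)
})

test_that("2TC fit recovers generating parameters (inverse crime, zero noise)", {
  aif <- test_aif()
  p <- list(K1 = 0.1, k2 = 0.2, k3 = 0.05, vb = 0.04)
  tac <- tissue_response(p, aif, schedule = sched, dt_s = 1)
  fit <- fit_2tc(tac, aif, schedule = sched, dt_s = 1, multistart = 6)
  expect_lt(abs(fit$K1 / p$K1 - 1), 0.001)
  expect_lt(abs(fit$k2 / p$k2 - 1), 0.001)
  expect_lt(abs(fit$k3 / p$k3 - 1), 0.001)
  expect_lt(abs(fit$vb / p$vb - 1), 0.001)
  ki_true <- p$K1 * p$k3 / (p$k2 + p$k3)
  expect_lt(abs(fit$Ki / ki_true - 1), 0.001)
  expect_true(fit$converged)
})

test_that("all-zero TAC yields a null kinetic estimate", {
  aif <- test_aif()
  tac <- tissue_tac(frame_mid_times(sched), rep(0, 28))
  fit <- fit_2tc(tac, aif, schedule = sched, multistart = 3, dt_s = 2)
  expect_lt(fit$K1, 1e-6)
  expect_equal(fit$Ki, 0, tolerance = 1e-8)
  sp <- spectral_analysis(tac, aif, schedule = sched)
  expect_true(all(sp$alpha == 0))
})

test_that("2TC Ki estimation is robust to frame noise (seeded replicates)", {
  aif <- test_aif()
  p <- list(K1 = 0.1, k2 = 0.2, k3 = 0.05, vb = 0.04)
  tac <- tissue_response(p, aif, schedule = sched, dt_s = 2)
  ki_true <- p$K1 * p$k3 / (p$k2 + p$k3)
  set.seed(99)
  errs <- replicate(100, {
    noisy <- tissue_tac(tac$mid_time_min,
                        tac$value_kBq_mL * (1 + rnorm(28, 0, 0.05)))
    f <- fit_2tc(noisy, aif, schedule = sched, multistart = 3, dt_s = 2)
    abs(f$Ki - ki_true) / ki_true
  })
  expect_lt(median(errs), 0.10)
})

test_that("optimiser never lands above the residual at the generating truth", {
  aif <- test_aif()
  p <- list(K1 = 0.07, k2 = 0.3, k3 = 0.03, vb = 0.05)
  tac <- tissue_response(p, aif, schedule = sched, dt_s = 2)
  set.seed(5)
  noisy <- tissue_tac(tac$mid_time_min, tac$value_kBq_mL * (1 + rnorm(28, 0, 0.05)))
  fit <- fit_2tc(noisy, aif, schedule = sched, multistart = 5, dt_s = 2)
  w <- sched$duration_s / mean(sched$duration_s)
  rss_truth <- sum(w * (tac$value_kBq_mL - noisy$value_kBq_mL)^2)
  expect_lte(fit$rss, rss_truth + 1e-9)
})

test_that("spectral analysis recovers a single-exponential basis component", {
  aif <- test_aif()
  # unit weight on the exact basis member whose grid rate is nearest 0.1/min
  grid_betas <- exp(seq(log(0.001), log(10), length.out = 100))
  beta_true <- grid_betas[which.min(abs(grid_betas - 0.1))]
  dt <- 1 / 60
  t_fine <- seq(0, 66.5, by = dt)
  cp <- approx(aif$time_min, aif$value_kBq_mL, xout = t_fine, rule = 2)$y
  conv <- fpiaquant:::conv_grid(cp, exp(-beta_true * t_fine), dt)
  vals <- vapply(seq_len(nrow(sched)), function(i) {
    sel <- t_fine >= sched$start_s[i] / 60 & t_fine <= sched$end_s[i] / 60
    mean(conv[sel])
  }, numeric(1))
  tac <- tissue_tac(frame_mid_times(sched), vals)
  sp <- spectral_analysis(tac, aif, schedule = sched, include_blood = FALSE)
  expect_lt(abs(sum(sp$alpha) - 1), 0.05)
  peak_beta <- sp$beta_per_min[which.max(sp$alpha)]
  expect_lt(abs(log(peak_beta / beta_true)), 0.2)  # mass at the grid point nearest 0.1
})

test_that("spectral trapping weight is consistent with Patlak on irreversible data", {
  aif <- test_aif()
  for (p in list(list(K1 = 0.1, k2 = 0.2, k3 = 0.05, vb = 0),
                 list(K1 = 0.06, k2 = 0.25, k3 = 0.03, vb = 0))) {
    tac <- tissue_response(p, aif, schedule = sched)
    ki_pat <- patlak_fit(tac, aif)$Ki
    ki_trap <- attr(spectral_analysis(tac, aif, schedule = sched), "Ki_trap")
    expect_lt(abs(ki_trap - ki_pat) / ki_pat, 0.10)
  }
})

test_that("spectrum weights are nonnegative and reversible data needs no trapping term", {
  aif <- test_aif()
  tac_rev <- tissue_response(list(K1 = 0.1, k2 = 0.2, k3 = 0, vb = 0), aif, schedule = sched)
  sp_with <- spectral_analysis(tac_rev, aif, schedule = sched)
  expect_true(all(sp_with$alpha >= 0))
  # removing the beta = 0 column barely changes the residual on reversible data
  basis_rss <- attr(sp_with, "rss")
  sp_dropped <- spectral_analysis(tac_rev, aif, schedule = sched, include_trapping = FALSE)
  expect_lt(attr(sp_with, "Ki_trap"), 1e-4)
  tss <- sum(tac_rev$value_kBq_mL^2)
  expect_lt(abs(basis_rss - attr(sp_dropped, "rss")) / tss, 0.01)
})

test_that("kinetic estimators are invariant to joint rescaling of TAC and input", {
  aif <- test_aif()
  p <- list(K1 = 0.1, k2 = 0.2, k3 = 0.05, vb = 0)
  tac <- tissue_response(p, aif, schedule = sched, dt_s = 2)
  c <- 3.1
  aif_s <- input_function(aif$time_min, aif$value_kBq_mL * c)
  tac_s <- tissue_tac(tac$mid_time_min, tac$value_kBq_mL * c)
  expect_equal(patlak_fit(tac_s, aif_s)$Ki, patlak_fit(tac, aif)$Ki, tolerance = 1e-9)
  f1 <- fit_2tc(tac, aif, schedule = sched, multistart = 3, dt_s = 2)
  f2 <- fit_2tc(tac_s, aif_s, schedule = sched, multistart = 3, dt_s = 2)
  expect_equal(f2$Ki, f1$Ki, tolerance = 1e-5)
  k1 <- attr(spectral_analysis(tac, aif, schedule = sched), "Ki_trap")
  k2_ <- attr(spectral_analysis(tac_s, aif_s, schedule = sched), "Ki_trap")
  expect_equal(k2_, k1, tolerance = 1e-8)
})
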