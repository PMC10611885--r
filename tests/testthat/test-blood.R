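make_blood <- function(wb_fun, pf = rep(1, 5), plasma_ratio = 1) {
  cont_t <- seq(0, 10, by = 1 / 6)
  disc_t <- c(2.5, 15, 30, 45, 60)
  blood_series(
    continuous = tibble::tibble(time_min = cont_t, wb_kBq_mL = wb_fun(cont_t)),
    discrete = tibble::tibble(time_min = disc_t, wb_kBq_mL = wb_fun(disc_t),
                              plasma_kBq_mL = plasma_ratio * wb_fun(disc_t),
                              parent_fraction = pf)
  )
}

test_that("cross-calibration recovers the least-squares scale factor", {
  f <- function(t) 10 * exp(-0.2 * t) + 2
  b <- make_blood(f)
  expect_equal(attr(cross_calibrate(b$continuous, b$discrete), "scale"), 1.0, tolerance = 1e-9)

  doubled <- b$continuous
  doubled$wb_kBq_mL <- doubled$wb_kBq_mL * 2
  cc <- cross_calibrate(doubled, b$discrete)
  expect_equal(attr(cc, "scale"), 0.5, tolerance = 1e-9)
  expect_equal(cc$wb_kBq_mL, b$continuous$wb_kBq_mL, tolerance = 1e-9)

  late <- b$discrete[b$discrete$time_min > 12, ]
  expect_error(cross_calibrate(b$continuous, late), "window")
})

test_that("cross-calibration is robust to measurement noise on overlap points", {
  f <- function(t) 30 * exp(-0.3 * t) + 5
  set.seed(7)
  errs <- replicate(100, {
    cont_t <- seq(0, 10, by = 1 / 6)
    cont <- tibble::tibble(time_min = cont_t, wb_kBq_mL = 2 * f(cont_t))
    td <- c(1, 2.5, 4, 5.5, 7, 8.5)
    disc <- tibble::tibble(time_min = td,
                           wb_kBq_mL = f(td) * rnorm(length(td), 1, 0.05))
    attr(cross_calibrate(cont, disc), "scale")
  })
  expect_true(all(abs(errs / 0.5 - 1) < 0.10))
})

test_that("metabolite correction: identity at pf = 1, halving at pf = 0.5, sigmoid recovery", {
  f <- function(t) 10 * exp(-0.1 * t) + 1
  b1 <- make_blood(f, pf = rep(1, 5))
  c1 <- metabolite_correct(b1)
  expect_equal(c1$parent_plasma_kBq_mL, b1$discrete$plasma_kBq_mL)

  b5 <- make_blood(f, pf = rep(0.5, 5))
  c5 <- metabolite_correct(b5)
  expect_equal(c5$parent_plasma_kBq_mL, 0.5 * b5$discrete$plasma_kBq_mL)
  # the fitted pf never exceeds 1 so correction never increases activity
  pf_fun <- attr(c5, "pf_fun")
  expect_true(all(pf_fun(seq(0, 66, by = 0.5)) <= 1 + 1e-12))

  # sigmoid-declining truth sampled at the protocol times
  pf_true <- function(t) 1 - 0.5 * t^2 / (20^2 + t^2)
  bs <- make_blood(f, pf = pf_true(c(2.5, 15, 30, 45, 60)))
  cs <- metabolite_correct(bs, pf_model = "sigmoid")
  fitted <- attr(cs, "pf_fun")(c(2.5, 15, 30, 45, 60))
  expect_true(all(abs(fitted - pf_true(c(2.5, 15, 30, 45, 60))) < 0.02))
})

test_that("merged input function keeps the early segment and hits the tail points", {
  f <- function(t) 20 * exp(-0.15 * t) + 3
  cont <- tibble::tibble(time_min = seq(0, 10, by = 0.1), value_kBq_mL = f(seq(0, 10, by = 0.1)))
  disc <- tibble::tibble(time_min = c(15, 30, 45, 60), parent_plasma_kBq_mL = f(c(15, 30, 45, 60)))
  merged <- merge_input_function(cont, disc)
  expect_s3_class(merged, "input_function")
  # continuous part preserved
  early <- merged[merged$time_min < 10, ]
  expect_equal(early$value_kBq_mL, f(early$time_min), tolerance = 1e-9)
  # passes through every discrete point
  at <- approx(merged$time_min, merged$value_kBq_mL, xout = disc$time_min)$y
  expect_equal(at, disc$parent_plasma_kBq_mL, tolerance = 1e-6)
})

test_that("full input-function assembly approximates the generating bolus integral", {
  sp <- small_phantom(grade = 4, seed = 9, pet_cv_at_300s = 0)
  st <- generate_study(sp)
  ifn <- build_input_function(st$blood)
  truth <- simulate_aif(seq(0, 60, by = 1 / 120), sp$aif_params)
  int_est <- pracma::trapz(ifn$time_min[ifn$time_min <= 60],
                           ifn$value_kBq_mL[ifn$time_min <= 60])
  int_true <- pracma::trapz(truth$time_min, truth$value_kBq_mL)
  expect_lt(abs(int_est - int_true) / int_true, 0.05)
})

test_that("population input function: identity for one patient, linear in dose/weight", {
  f <- function(t) 15 * exp(-0.1 * t) + 2
  ifn <- input_function(seq(0, 66, by = 0.1), f(seq(0, 66, by = 0.1)))
  meta <- patient_meta("p1", 350, 70, 4)
  tmpl <- population_input_function(list(ifn), list(meta))
  back <- apply_population_if(tmpl, meta)
  expect_equal(approx(back$time_min, back$value_kBq_mL, xout = c(1, 10, 50))$y,
               f(c(1, 10, 50)), tolerance = 1e-6)

  # two identical patients -> template equals either normalised curve
  tmpl2 <- population_input_function(list(ifn, ifn), list(meta, meta))
  expect_equal(tmpl2$suv_value, tmpl$suv_value)

  # applying to a patient with double dose doubles the curve
  meta2 <- patient_meta("p2", 700, 70, 4)
  up <- apply_population_if(tmpl, meta2)
  expect_equal(up$value_kBq_mL, 2 * back$value_kBq_mL, tolerance = 1e-9)

  expect_error(population_input_function(list(), list()), "at least one")
})

test_that("leave-one-out population input function preserves Patlak Ki within 15%", {
  sched <- paper_schedule()
  set.seed(11)
  n <- 5
  metas <- lapply(seq_len(n), function(i)
    patient_meta(paste0("p", i), runif(1, 280, 420), runif(1, 60, 90), 4))
  t_dense <- seq(0, 66.5, by = 1 / 60)
  ifs <- lapply(metas, function(m) {
    pars <- aif_defaults()
    sc <- (m$injected_activity_MBq / m$body_weight_kg) / (347 / 75)
    pars$A1 <- pars$A1 * sc; pars$A2 <- pars$A2 * sc; pars$A3 <- pars$A3 * sc
    simulate_aif(t_dense, pars)
  })
  p <- list(K1 = 0.1, k2 = 0.2, k3 = 0.05, vb = 0)
  for (i in seq_len(n)) {
    tac <- tissue_response(p, ifs[[i]], schedule = sched)
    ki_own <- patlak_fit(tac, ifs[[i]])$Ki
    tmpl <- population_input_function(ifs[-i], metas[-i])
    ki_pop <- patlak_fit(tac, apply_population_if(tmpl, metas[[i]]))$Ki
    expect_lt(abs(ki_pop - ki_own) / ki_own, 0.15)
  }
})
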