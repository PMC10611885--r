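#' Tri-exponential bolus arterial input function
#'
#' Feng-type analytic input:
#' `Cp(t) = (A1 (t-t0) - A2 - A3) exp(-l1 (t-t0)) + A2 exp(-l2 (t-t0)) + A3 exp(-l3 (t-t0))`
#' for `t > t0`, zero before onset. With the default parameters the late
#' plasma activity plateaus, as required for a tracer whose tissue curves
#' keep rising over the whole acquisition.
#'
#' @param times_min Evaluation times, minutes.
#' @param params Named list: amplitudes `A1` (kBq/mL/min), `A2`, `A3`
#'   (kBq/mL), rates `l1 > l2 > l3 > 0` (/min), onset `t0_min >= 0`.
#' @return An [input_function()].
#' @export
simulate_aif <- function(times_min, params = aif_defaults()) {
  p <- utils::modifyList(aif_defaults(), as.list(params))
  with(p, {
    if (!all(is.finite(c(A1, A2, A3, l1, l2, l3, t0_min))))
      stop("AIF parameters must be finite", call. = FALSE)
    if (!(l1 > l2 && l2 > l3 && l3 > 0)) stop("need l1 > l2 > l3 > 0", call. = FALSE)
    if (t0_min < 0) stop("onset must be nonnegative", call. = FALSE)
    tau <- pmax(times_min - t0_min, 0)
    v <- (A1 * tau - A2 - A3) * exp(-l1 * tau) + A2 * exp(-l2 * tau) + A3 * exp(-l3 * tau)
    v[times_min <= t0_min] <- 0
    input_function(times_min, pmax(v, 0))
  })
}

#' @rdname simulate_aif
#' @export
aif_defaults <- function() {
  list(A1 = 250, A2 = 8, A3 = 7, l1 = 4.1, l2 = 0.12, l3 = 0.01, t0_min = 0.5)
}

#' Grade-dependent kinetic and MRI generating presets
#'
#' Per-region generating parameters for the digital phantom: irreversible-2TC
#' rates for PET and perfusion/permeability/diffusion values for the MRI arms.
#' Values increase (K1, k3, Ktrans, CBV, CBF) or decrease (ADC) with grade so
#' that the simulated cohort reproduces the qualitative grade orderings of
#' tracer uptake; `ve` is elevated only in the grade-4 preset. They are
#' configuration, not measured values.
#'
#' @param region One of `"background"`, `"grade2"`, `"grade3"`, `"grade4"`.
#' @return Named list of generating parameters.
#' @export
grade_presets <- function(region = c("background", "grade2", "grade3", "grade4")) {
  region <- match.arg(region)
  presets <- list(
    background = list(K1 = 0.030, k2 = 0.25, k3 = 0.012, vb = 0.04,
                      Ktrans = 0.002, ve = 0.03, vp = 0.010,
                      CBV_rel = 1.0, CBF_rel = 1.0, ADC = 0.75e-3),
    grade2 = list(K1 = 0.045, k2 = 0.22, k3 = 0.030, vb = 0.04,
                  Ktrans = 0.010, ve = 0.05, vp = 0.015,
                  CBV_rel = 1.2, CBF_rel = 1.1, ADC = 1.30e-3),
    grade3 = list(K1 = 0.060, k2 = 0.22, k3 = 0.040, vb = 0.05,
                  Ktrans = 0.030, ve = 0.09, vp = 0.020,
                  CBV_rel = 1.8, CBF_rel = 1.6, ADC = 1.10e-3),
    grade4 = list(K1 = 0.085, k2 = 0.21, k3 = 0.045, vb = 0.06,
                  Ktrans = 0.080, ve = 0.18, vp = 0.040,
                  CBV_rel = 3.0, CBF_rel = 2.5, ADC = 0.85e-3)
  )
  presets[[region]]
}

#' Phantom specification
#'
#' Geometry, presets and noise levels for one synthetic patient study.
#'
#' @param grade WHO grade of the simulated lesion (2, 3 or 4).
#' @param grid_shape Voxel grid (default `c(64, 64, 48)`).
#' @param voxel_size_mm Voxel size (default 2 mm isotropic).
#' @param lesion_radius_mm FLAIR-lesion radius (default 14); the
#'   contrast-enhancing (T1CE) lesion is concentric at 70% radius.
#' @param psf_fwhm_mm Gaussian point-spread FWHM emulating reconstruction
#'   smoothing (default 5).
#' @param pet_cv_at_300s Voxel noise coefficient of variation for a 300-s
#'   frame (default 0.05); variance scales as 1/frame duration.
#' @param mri_sigma MRI noise SD as a fraction of baseline signal (default 0.02).
#' @param pf_mode Parent-fraction simulation: `"unity"` (non-metabolised
#'   tracer) or `"sigmoid"` (declining, to exercise metabolite correction).
#' @param aif_params Bolus parameters for [simulate_aif()].
#' @param seed Integer seed.
#' @param patient_id Identifier.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grade = 4, grid_shape = c(64, 64, 48),
                         voxel_size_mm = c(2, 2, 2), lesion_radius_mm = 14,
                         psf_fwhm_mm = 5, pet_cv_at_300s = 0.05,
                         mri_sigma = 0.02, pf_mode = c("unity", "sigmoid"),
                         aif_params = aif_defaults(), seed = 1,
                         patient_id = sprintf("PT%02d", seed %% 100)) {
  pf_mode <- match.arg(pf_mode)
  stopifnot(grade %in% c(2, 3, 4), lesion_radius_mm > 0, all(voxel_size_mm > 0))
  preset <- grade_presets(paste0("grade", grade))
  stopifnot(preset$K1 >= 0, preset$K1 <= 1, preset$ve > 0, preset$ve < 1,
            preset$ADC >= 0.1e-3, preset$ADC <= 3e-3)
  structure(
    list(grade = grade, grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
         lesion_radius_mm = lesion_radius_mm, psf_fwhm_mm = psf_fwhm_mm,
         pet_cv_at_300s = pet_cv_at_300s, mri_sigma = mri_sigma,
         pf_mode = pf_mode, aif_params = aif_params, seed = seed,
         patient_id = patient_id, preset = preset,
         background = grade_presets("background")),
    class = "phantom_spec"
  )
}

sphere_mask <- function(grid_shape, voxel_size_mm, centre_mm, radius_mm) {
  cx <- (seq_len(grid_shape[1]) - 1) * voxel_size_mm[1]
  cy <- (seq_len(grid_shape[2]) - 1) * voxel_size_mm[2]
  cz <- (seq_len(grid_shape[3]) - 1) * voxel_size_mm[3]
  dx2 <- (cx - centre_mm[1])^2
  dy2 <- (cy - centre_mm[2])^2
  dz2 <- (cz - centre_mm[3])^2
  arr <- outer(outer(dx2, dy2, "+"), dz2, "+")
  arr <= radius_mm^2
}

tube_mask_y <- function(grid_shape, voxel_size_mm, x_mm, z_mm, radius_mm, y_range_mm) {
  cx <- (seq_len(grid_shape[1]) - 1) * voxel_size_mm[1]
  cy <- (seq_len(grid_shape[2]) - 1) * voxel_size_mm[2]
  cz <- (seq_len(grid_shape[3]) - 1) * voxel_size_mm[3]
  r2 <- outer((cx - x_mm)^2, rep(0, grid_shape[2]), "+")
  arr <- array(FALSE, grid_shape)
  in_y <- cy >= y_range_mm[1] & cy <= y_range_mm[2]
  disc <- outer((cx - x_mm)^2, (cz - z_mm)^2, "+") <= radius_mm^2  # x-z disc
  for (j in which(in_y)) arr[, j, ] <- disc
  arr
}

gaussian_blur_fft <- function(vol, sigma_vox) {
  if (all(sigma_vox <= 0)) return(vol)
  d <- dim(vol)
  gk <- lapply(1:3, function(ax) {
    n <- d[ax]
    f <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1)) / n
    exp(-2 * pi^2 * sigma_vox[ax]^2 * f^2)
  })
  G <- outer(outer(gk[[1]], gk[[2]]), gk[[3]])
  Re(stats::fft(stats::fft(vol) * G, inverse = TRUE)) / prod(d)
}

#' Generate a complete synthetic PET/MRI study
#'
#' Builds VOI geometry (spherical FLAIR and T1CE lesions, mirrored
#' contralateral region, contralateral-white-matter sphere, sagittal-sinus
#' tube), drives an irreversible-2TC forward model with a bolus input
#' function to produce frame-integrated PET volumes (Gaussian PSF, Gaussian
#' noise with variance inversely proportional to frame duration, blood-pool
#' signal in the sinus), simulates DCE/DSC/ASL/DWI series from the grade
#' presets via the corresponding forward models, samples the blood tables at
#' the protocol times (2.5, 15, 30, 45, 60 min), and records the full ground
#' truth.
#'
#' @param spec A [phantom_spec()].
#' @return A study list (`pet`, `masks`, `blood`, `meta`, `mri`, `truth`)
#'   compatible with [write_study()] / [load_study()] and [quantify_study()].
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)

  gs <- spec$grid_shape; vs <- spec$voxel_size_mm
  fov <- (gs - 1) * vs
  schedule <- default_frame_schedule()

  lesion_centre <- c(0.70 * fov[1], 0.50 * fov[2], 0.50 * fov[3])
  mirror_centre <- c(fov[1] - lesion_centre[1], lesion_centre[2], lesion_centre[3])
  cwm_centre <- c(0.28 * fov[1], 0.30 * fov[2], 0.55 * fov[3])
  masks <- list(
    lesion_flair = voi_mask(sphere_mask(gs, vs, lesion_centre, spec$lesion_radius_mm),
                            "lesion_flair", vs),
    lesion_t1ce = voi_mask(sphere_mask(gs, vs, lesion_centre, 0.7 * spec$lesion_radius_mm),
                           "lesion_t1ce", vs),
    contralateral = voi_mask(sphere_mask(gs, vs, mirror_centre, spec$lesion_radius_mm),
                             "contralateral", vs),
    cwm = voi_mask(sphere_mask(gs, vs, cwm_centre, 8), "cwm", vs),
    sinus = voi_mask(tube_mask_y(gs, vs, 0.5 * fov[1], 0.78 * fov[3], 4,
                                 c(0.15 * fov[2], 0.85 * fov[2])), "sinus", vs)
  )
  if (any(masks$lesion_flair$voxels & masks$sinus$voxels))
    stop("lesion and sinus regions overlap", call. = FALSE)

  # --- PET ---
  t_total <- total_duration_min(schedule)
  t_dense <- seq(0, t_total, by = 1 / 60)
  aif <- simulate_aif(t_dense, spec$aif_params)
  pf_fun <- if (spec$pf_mode == "unity") function(t) rep(1, length(t))
            else function(t) 1 - 0.4 * t^2 / (30^2 + t^2)
  # whole blood: parent plasma / (plasma-to-wb ratio 1) / pf
  wb_dense <- aif$value_kBq_mL / pf_fun(t_dense)
  blood_curve <- tibble::tibble(time_min = t_dense, value_kBq_mL = wb_dense)

  lesion_tac <- tissue_response(spec$preset, aif, schedule = schedule, blood_fn = blood_curve)
  backgr_tac <- tissue_response(spec$background, aif, schedule = schedule, blood_fn = blood_curve)
  sinus_tac_vals <- frame_average(t_dense, wb_dense, schedule)

  nf <- nrow(schedule)
  pet <- array(0, c(gs, nf))
  sigma_vox <- rep(spec$psf_fwhm_mm / 2.3548, 3) / vs
  for (i in seq_len(nf)) {
    vol <- array(backgr_tac$value_kBq_mL[i], gs)
    vol[masks$lesion_flair$voxels] <- lesion_tac$value_kBq_mL[i]
    vol[masks$sinus$voxels] <- sinus_tac_vals[i]
    if (spec$psf_fwhm_mm > 0) vol <- gaussian_blur_fft(vol, sigma_vox)
    if (spec$pet_cv_at_300s > 0) {
      sd_vol <- spec$pet_cv_at_300s * sqrt(300 / schedule$duration_s[i]) * abs(vol)
      vol <- vol + array(stats::rnorm(prod(gs), 0, 1), gs) * sd_vol
    }
    pet[, , , i] <- vol
  }
  pet_img <- dynamic_image(pet, schedule, voxel_size_mm = vs)

  # --- blood tables ---
  cont_t <- seq(0, 10, by = 1 / 60)
  disc_t <- c(2.5, 15, 30, 45, 60)
  wb_at <- function(t) stats::approx(t_dense, wb_dense, xout = t, rule = 2)$y
  blood <- blood_series(
    continuous = tibble::tibble(time_min = cont_t, wb_kBq_mL = wb_at(cont_t)),
    discrete = tibble::tibble(
      time_min = disc_t, wb_kBq_mL = wb_at(disc_t),
      plasma_kBq_mL = wb_at(disc_t),
      parent_fraction = pf_fun(disc_t)
    )
  )

  meta <- patient_meta(spec$patient_id,
                       injected_activity_MBq = stats::runif(1, 342, 368),
                       body_weight_kg = stats::runif(1, 60, 90),
                       who_grade = spec$grade)

  mri <- simulate_mri_series(spec, masks, gs, vs)

  truth <- list(
    grade = spec$grade, preset = spec$preset, background = spec$background,
    aif_params = spec$aif_params,
    noiseless_tacs = list(
      lesion_flair = lesion_tac$value_kBq_mL,
      cwm = backgr_tac$value_kBq_mL,
      sinus = sinus_tac_vals
    ),
    mid_time_min = frame_mid_times(schedule)
  )

  list(pet = pet_img, masks = masks, blood = blood, meta = meta,
       mri = mri, truth = truth)
}

# gamma-variate vascular contrast bolus with a slow washout tail (mM)
gd_plasma_curve <- function(t_min, t0 = 0.5, alpha = 3, beta = 0.1,
                            peak_mM = 5, tail_mM = 0.8, tail_decay = 1 / 15) {
  tau <- pmax(t_min - t0, 0)
  g <- tau^alpha * exp(-tau / beta)
  g <- g / max((alpha * beta)^alpha * exp(-alpha), .Machine$double.eps) * peak_mM
  tail <- tail_mM * (1 - exp(-5 * tau)) * exp(-tail_decay * tau)
  out <- g + tail
  out[t_min <= t0] <- 0
  out
}

simulate_mri_series <- function(spec, masks, gs, vs) {
  regions <- list(lesion = masks$lesion_flair$voxels, sinus = masks$sinus$voxels)
  p_les <- spec$preset; p_bg <- spec$background

  # DCE: 50 frames x 6 s
  dce_t_min <- seq(0, by = 0.1, length.out = 50)
  cp_gd <- gd_plasma_curve(dce_t_min)
  dce_pars <- list(time_min = dce_t_min, TR_s = 0.004, flip_deg = 12,
                   T10_s = 1.4, r1_per_mM_s = 4.5, baseline_frames = 5, M0 = 1000)
  tofts_fwd <- function(p) {
    p$vp * cp_gd + p$Ktrans * conv_grid(cp_gd, exp(-(p$Ktrans / p$ve) * dce_t_min), 0.1)
  }
  dce_sig <- list(
    background = spgr_signal(tofts_fwd(p_bg), M0 = dce_pars$M0),
    lesion = spgr_signal(tofts_fwd(p_les), M0 = dce_pars$M0),
    sinus = spgr_signal(cp_gd, M0 = dce_pars$M0)
  )
  dce <- fill_series(gs, regions, dce_sig, spec$mri_sigma * dce_sig$background[1])
  dce <- c(list(signal = dce), dce_pars)

  # DSC: 60 frames x 1.5 s
  dsc_t_s <- seq(0, by = 1.5, length.out = 60)
  aif_dr2 <- 60 * gv_curve(dsc_t_s, t0 = 15, alpha = 3, beta = 2.5)
  cbf_cwm <- 0.005; cbv_cwm <- 0.02  # 1/s and unitless reference scales
  dsc_curve <- function(p) {
    cbf <- cbf_cwm * p$CBF_rel; cbv <- cbv_cwm * p$CBV_rel
    mtt <- cbv / cbf
    cbf * conv_grid(aif_dr2, exp(-dsc_t_s / mtt), 1.5)
  }
  TE <- 0.03; S0 <- 1000
  dsc_sig <- list(
    background = S0 * exp(-TE * dsc_curve(p_bg)),
    lesion = S0 * exp(-TE * dsc_curve(p_les)),
    sinus = S0 * exp(-TE * aif_dr2)
  )
  dsc <- fill_series(gs, regions, dsc_sig, spec$mri_sigma * S0)
  dsc <- c(list(signal = dsc), list(time_s = dsc_t_s, TE_s = TE, baseline_frames = 8))

  # ASL
  asl_const <- list(lambda_blood_partition = 0.9, inversion_efficiency = 0.98,
                    T1_blood_s = 1.65, TI1_s = 0.7, TI2_s = 1.8)
  cbf_abs_cwm <- 20
  M0 <- array(1000, gs)
  cbf_map <- array(cbf_abs_cwm * p_bg$CBF_rel, gs)
  cbf_map[regions$lesion] <- cbf_abs_cwm * p_les$CBF_rel
  dm <- asl_delta_m(cbf_map, M0, asl_const)
  dm <- dm + array(stats::rnorm(prod(gs), 0, spec$mri_sigma * mean(dm)), gs)
  asl <- c(list(delta_M = dm, M0 = M0), asl_const)

  # DWI
  b_values <- c(0, 500, 1000)
  adc_map <- array(p_bg$ADC, gs)
  adc_map[regions$lesion] <- p_les$ADC
  dwi_sig <- array(0, c(gs, length(b_values)))
  for (j in seq_along(b_values)) {
    s <- 1000 * exp(-b_values[j] * adc_map)
    dwi_sig[, , , j] <- s + array(stats::rnorm(prod(gs), 0, spec$mri_sigma * 1000), gs)
  }
  dwi <- list(signal = dwi_sig, b_values_s_mm2 = b_values)

  list(dce = dce, dsc = dsc, asl = asl, dwi = dwi)
}

#' Region-level (TAC-space) cohort simulator
#'
#' Lightweight counterpart of [generate_study()] for experiments that need
#' many cohort replicates: it simulates the region-mean lesion TAC of each
#' patient directly from the grade presets, with Gaussian frame noise whose
#' standard deviation follows the voxel noise model scaled down by the
#' effective number of independent voxels averaged in a lesion VOI
#' (`sd = cv_at_300s / sqrt(n_eff_voxels) * sqrt(300 / duration) * value`).
#'
#' @param grades WHO grades of the simulated patients.
#' @param seed Integer seed.
#' @param cv_at_300s Voxel-level CV at a 300-s frame (default 0.05, matching
#'   [phantom_spec()]).
#' @param n_eff_voxels Effective independent voxels in a region average
#'   (default 64: a 1-2 cm lesion at 2-mm voxels after 5-mm PSF smoothing).
#' @param aif_params Bolus parameters for [simulate_aif()].
#' @return Tibble with `patient_id`, `who_grade`, `grade_label` and a `tac`
#'   list-column of [tissue_tac()] objects; the shared input function is in
#'   `attr(, "input_fn")`.
#' @export
simulate_cohort_tacs <- function(grades, seed = 1, cv_at_300s = 0.05,
                                 n_eff_voxels = 64, aif_params = aif_defaults()) {
  schedule <- default_frame_schedule()
  aif <- simulate_aif(seq(0, total_duration_min(schedule), by = 1 / 60), aif_params)
  base <- lapply(unique(grades), function(g)
    tissue_response(grade_presets(paste0("grade", g)), aif, schedule = schedule, dt_s = 2))
  names(base) <- as.character(unique(grades))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  sd_scale <- cv_at_300s / sqrt(n_eff_voxels) * sqrt(300 / schedule$duration_s)
  tacs <- lapply(seq_along(grades), function(i) {
    clean <- base[[as.character(grades[i])]]
    tissue_tac(clean$mid_time_min,
               clean$value_kBq_mL * (1 + stats::rnorm(nrow(clean), 0, 1) * sd_scale),
               region = "lesion")
  })
  out <- tibble::tibble(
    patient_id = sprintf("PT%02d", seq_along(grades)),
    who_grade = as.integer(grades),
    grade_label = ifelse(grades == 2, "LGG", "HGG"),
    tac = tacs
  )
  attr(out, "input_fn") <- aif
  out
}

gv_curve <- function(t, t0, alpha, beta) {
  tau <- pmax(t - t0, 0)
  g <- tau^alpha * exp(-tau / beta)
  g / max((alpha * beta)^alpha * exp(-alpha), .Machine$double.eps)
}

fill_series <- function(gs, regions, region_curves, noise_sd) {
  nfr <- length(region_curves$background)
  out <- array(0, c(gs, nfr))
  for (i in seq_len(nfr)) {
    vol <- array(region_curves$background[i], gs)
    vol[regions$lesion] <- region_curves$lesion[i]
    vol[regions$sinus] <- region_curves$sinus[i]
    if (noise_sd > 0) vol <- vol + array(stats::rnorm(prod(gs), 0, noise_sd), gs)
    out[, , , i] <- vol
  }
  out
}
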