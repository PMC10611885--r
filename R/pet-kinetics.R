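#' Forward irreversible two-tissue-compartment model
#'
#' Tissue activity for a tracer delivered at rate `K1`, effluxed at `k2` and
#' irreversibly trapped at `k3` (k4 = 0):
#' `CT(t) = (1 - vb) * (h (*) Cp)(t) + vb * Cb(t)` with impulse response
#' `h(t) = K1 * (k3/(k2+k3) + k2/(k2+k3) * exp(-(k2+k3) t))`
#' (limit `h = K1` when `k2 + k3 = 0`). The convolution runs on a fine time
#' grid (default 1 s); when a frame schedule is supplied the returned values
#' are interval averages over each frame, matching how a scanner integrates
#' counts.
#'
#' @param params Named list/vector with `K1` (mL/cm^3/min), `k2`, `k3` (/min),
#'   `vb` (blood volume fraction in `[0,1]`).
#' @param input_fn [input_function()]: parent-plasma concentration.
#' @param schedule A [frame_schedule()] for frame-averaged output, or `NULL`.
#' @param times_min Point-sample times (minutes), used when `schedule` is `NULL`.
#' @param blood_fn Whole-blood curve for the `vb` term (an `input_function`
#'   or tibble `time_min`,`value_kBq_mL`); defaults to `input_fn`.
#' @param dt_s Fine-grid step in seconds (default 1).
#' @return A [tissue_tac()] tibble.
#' @export
tissue_response <- function(params, input_fn, schedule = NULL, times_min = NULL,
                            blood_fn = NULL, dt_s = 1) {
  p <- as.list(params)
  K1 <- p$K1; k2 <- p$k2; k3 <- p$k3
  vb <- if (is.null(p$vb)) 0 else p$vb
  stopifnot(K1 >= 0, k2 >= 0, k3 >= 0, vb >= 0, vb <= 1)
  t_end <- if (!is.null(schedule)) max(schedule$end_s) / 60 else max(times_min)
  fg <- fine_grid_curve(params, input_fn, blood_fn, t_end, dt_s)
  if (!is.null(schedule)) {
    vals <- frame_average(fg$t, fg$ct, schedule)
    tissue_tac(frame_mid_times(schedule), vals, statistic = "mean", region = "model")
  } else {
    vals <- stats::approx(fg$t, fg$ct, xout = times_min, rule = 2)$y
    tissue_tac(times_min, vals, statistic = "mean", region = "model")
  }
}

# dense forward model: returns fine grid t (min) and CT
fine_grid_curve <- function(params, input_fn, blood_fn, t_end, dt_s = 1) {
  p <- as.list(params)
  K1 <- p$K1; k2 <- p$k2; k3 <- p$k3
  vb <- if (is.null(p$vb)) 0 else p$vb
  dt <- dt_s / 60
  t <- seq(0, t_end, by = dt)
  cp <- interp_curve(input_fn, t)
  cb <- if (is.null(blood_fn)) cp else interp_curve(blood_fn, t)
  s <- k2 + k3
  h <- if (s <= 0) rep(K1, length(t)) else K1 * (k3 / s + (k2 / s) * exp(-s * t))
  free <- conv_grid(cp, h, dt)
  list(t = t, ct = (1 - vb) * free + vb * cb)
}

interp_curve <- function(curve, t) {
  tt <- curve$time_min
  vv <- if (!is.null(curve$value_kBq_mL)) curve$value_kBq_mL else curve[[2]]
  out <- stats::approx(tt, vv, xout = t, rule = 2)$y
  out[t < min(tt)] <- 0
  out
}

# causal convolution of two sampled curves; FFT product with end-point
# correction so the quadrature is trapezoid-accurate (O(dt^2))
conv_grid <- function(x, y, dt) {
  n <- length(x)
  full <- stats::convolve(x, rev(y), type = "open") * dt
  full[seq_len(n)] - 0.5 * dt * (x[1] * y + x * y[1])
}

frame_average <- function(t_fine, v_fine, schedule) {
  vapply(seq_len(nrow(schedule)), function(i) {
    sel <- t_fine >= schedule$start_s[i] / 60 & t_fine <= schedule$end_s[i] / 60
    mean(v_fine[sel])
  }, numeric(1))
}

#' Patlak graphical analysis
#'
#' For an irreversibly trapped tracer, `CT(t)/Cp(t)` plotted against the
#' normalised time `int_0^t Cp / Cp(t)` becomes linear once the reversible
#' compartments equilibrate; the slope is the net influx rate constant `Ki`
#' and the intercept `V0` the effective distribution volume of the reversible
#' space. Ordinary least squares over frames with mid-time `>= t_star_min`.
#'
#' @param tac A [tissue_tac()].
#' @param input_fn [input_function()].
#' @param t_star_min Start of the linear phase (default 15 min).
#' @param r2_warn Warn if the fit's R-squared falls below this (default 0.95),
#'   indicating the linear phase has not been reached.
#' @return Object of class `patlak_fit`: list with `Ki`, `V0`, `t_star_min`,
#'   `r_squared`, `n_points` and the plot coordinates.
#' @export
patlak_fit <- function(tac, input_fn, t_star_min = 15, r2_warn = 0.95) {
  cp_mid <- interp_curve(input_fn, tac$mid_time_min)
  cum <- cumtrapz_curve(input_fn)
  int_mid <- stats::approx(input_fn$time_min, cum, xout = tac$mid_time_min, rule = 2)$y
  use <- tac$mid_time_min >= t_star_min
  if (sum(use) < 3) stop("need at least 3 frames after t_star", call. = FALSE)
  if (any(cp_mid[use] <= 0)) stop("input function must be positive over the fit window", call. = FALSE)
  x <- int_mid[use] / cp_mid[use]
  y <- tac$value_kBq_mL[use] / cp_mid[use]
  fit <- stats::lm(y ~ x)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (is.finite(r2) && r2 < r2_warn) {
    warning("Patlak plot R-squared ", signif(r2, 3),
            " below ", r2_warn, ": linear phase may not be reached at t_star = ",
            t_star_min, " min")
  }
  structure(
    list(Ki = unname(stats::coef(fit)[2]), V0 = unname(stats::coef(fit)[1]),
         t_star_min = t_star_min, r_squared = r2, n_points = sum(use),
         x = x, y = y, region = tac$region[1]),
    class = "patlak_fit"
  )
}

cumtrapz_curve <- function(input_fn) {
  t <- input_fn$time_min; v <- input_fn$value_kBq_mL
  c(0, cumsum(diff(t) * (utils::head(v, -1) + utils::tail(v, -1)) / 2))
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat("<patlak_fit> Ki =", signif(x$Ki, 4), "mL/cm^3/min, V0 =", signif(x$V0, 4),
      ", r^2 =", signif(x$r_squared, 4), "(", x$n_points, "frames, t* =",
      x$t_star_min, "min )\n")
  invisible(x)
}

#' Nonlinear irreversible two-tissue-compartment fit
#'
#' Weighted nonlinear least squares of the forward model [tissue_response()]
#' against a measured TAC, weights proportional to frame duration. Bounded
#' Levenberg-Marquardt with multistart; `k4` is fixed at zero (irreversible
#' configuration), so the derived macro parameter is `Ki = K1 k3 / (k2 + k3)`.
#'
#' @param tac A [tissue_tac()].
#' @param input_fn [input_function()].
#' @param schedule [frame_schedule()] matching `tac` (used for frame averaging
#'   and duration weights); if `NULL`, point-sample model with equal weights.
#' @param blood_fn Whole-blood curve for the vascular term (default: `input_fn`).
#' @param fit_vb Fit the blood volume fraction (default `TRUE`); otherwise
#'   fixed at `vb_fixed`.
#' @param vb_fixed Fixed vb when `fit_vb = FALSE` (default 0).
#' @param multistart Number of random restarts (default 10).
#' @param seed Seed for the restart draws (default 1).
#' @param lower,upper Bounds on `(K1, k2, k3, vb)`.
#' @param dt_s Fine-grid step for the forward model, seconds.
#' @return Object of class `tc2_fit`: list with `K1`, `k2`, `k3`, `vb`, `Ki`,
#'   `rss`, `converged`, `n_starts_converged`.
#' @export
fit_2tc <- function(tac, input_fn, schedule = NULL, blood_fn = NULL,
                    fit_vb = TRUE, vb_fixed = 0, multistart = 10, seed = 1,
                    lower = c(0, 0, 0, 0), upper = c(2, 5, 5, 0.2), dt_s = 2) {
  obs <- tac$value_kBq_mL
  w <- if (!is.null(schedule)) schedule$duration_s / mean(schedule$duration_s) else rep(1, length(obs))
  sw <- sqrt(w)
  t_end <- if (!is.null(schedule)) max(schedule$end_s) / 60 else max(tac$mid_time_min)

  # precompute interpolated inputs once; model evaluated on shared fine grid
  dt <- dt_s / 60
  t_fine <- seq(0, t_end, by = dt)
  cp <- interp_curve(input_fn, t_fine)
  cb <- if (is.null(blood_fn)) cp else interp_curve(blood_fn, t_fine)

  model_vals <- function(K1, k2, k3, vb) {
    s <- k2 + k3
    h <- if (s <= 0) rep(K1, length(t_fine)) else K1 * (k3 / s + (k2 / s) * exp(-s * t_fine))
    ct <- (1 - vb) * conv_grid(cp, h, dt) + vb * cb
    if (!is.null(schedule)) frame_average(t_fine, ct, schedule)
    else stats::approx(t_fine, ct, xout = tac$mid_time_min, rule = 2)$y
  }
  resid_fn <- function(par) {
    vb <- if (fit_vb) par[4] else vb_fixed
    sw * (model_vals(par[1], par[2], par[3], vb) - obs)
  }

  npar <- if (fit_vb) 4 else 3
  lo <- lower[seq_len(npar)]; hi <- upper[seq_len(npar)]
  starts <- list(c(0.05, 0.2, 0.02, 0.03)[seq_len(npar)])
  if (multistart > 1) {
    old <- get_rng_state()
    set.seed(seed)
    for (i in seq_len(multistart - 1)) {
      starts[[i + 1]] <- lo + stats::runif(npar) * (pmin(hi, c(0.5, 1, 0.5, 0.2)[seq_len(npar)]) - lo)
    }
    restore_rng_state(old)
  }
  best <- NULL; n_conv <- 0
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn, lower = lo, upper = hi,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    conv <- fit$info %in% 1:4
    if (conv) n_conv <- n_conv + 1
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(par = fit$par, rss = rss, conv = conv)
    }
  }
  if (is.null(best)) stop("all multistart fits failed", call. = FALSE)
  par <- best$par
  vb <- if (fit_vb) par[4] else vb_fixed
  K1 <- par[1]; k2 <- par[2]; k3 <- par[3]
  Ki <- if (k2 + k3 > 0) K1 * k3 / (k2 + k3) else 0
  structure(
    list(K1 = K1, k2 = k2, k3 = k3, vb = vb, Ki = Ki, rss = best$rss,
         converged = n_conv > 0, n_starts_converged = n_conv,
         region = tac$region[1]),
    class = "tc2_fit"
  )
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

#' @export
print.tc2_fit <- function(x, ...) {
  cat("<tc2_fit> K1 =", signif(x$K1, 4), " k2 =", signif(x$k2, 4),
      " k3 =", signif(x$k3, 4), " vb =", signif(x$vb, 4),
      " Ki =", signif(x$Ki, 4), if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  invisible(x)
}

#' Spectral analysis of a tissue TAC
#'
#' Decomposes the TAC into a nonnegative sum of input-convolved exponentials
#' over a log-spaced grid of decay rates `beta` augmented with `beta = 0`
#' (trapping) and an optional whole-blood column:
#' `CT ~ sum_i alpha_i (Cp (*) exp(-beta_i t)) + alpha_b Cb`, `alpha >= 0`,
#' solved by non-negative least squares. The weight on the `beta = 0`
#' component is the trapping rate `Ki_trap`; the reversible components yield
#' `VT_rev = sum_{beta>0} alpha/beta`.
#'
#' @param tac A [tissue_tac()].
#' @param input_fn [input_function()].
#' @param schedule Optional [frame_schedule()] for frame-averaged basis
#'   functions (recommended; falls back to point samples at TAC mid-times).
#' @param n_betas Number of nonzero grid rates (default 100).
#' @param beta_min,beta_max Grid range, /min (defaults 0.001 and 10).
#' @param include_blood Include a whole-blood basis column (default `TRUE`).
#' @param include_trapping Include the `beta = 0` (trapping) basis column
#'   (default `TRUE`); disabling it quantifies how much of the fit relies on
#'   irreversible uptake.
#' @param blood_fn Whole-blood curve; defaults to `input_fn`.
#' @return Object of class `spectrum`: tibble (`beta_per_min`, `alpha`) with
#'   attributes `Ki_trap`, `VT_rev`, `blood_weight`, `rss`.
#' @export
spectral_analysis <- function(tac, input_fn, schedule = NULL,
                              n_betas = 100, beta_min = 0.001, beta_max = 10,
                              include_blood = TRUE, include_trapping = TRUE,
                              blood_fn = NULL) {
  betas <- exp(seq(log(beta_min), log(beta_max), length.out = n_betas))
  if (anyDuplicated(signif(betas, 12))) stop("duplicate beta grid points", call. = FALSE)
  t_end <- if (!is.null(schedule)) max(schedule$end_s) / 60 else max(tac$mid_time_min)
  dt <- 1 / 60
  t_fine <- seq(0, t_end, by = dt)
  cp <- interp_curve(input_fn, t_fine)
  cb <- if (is.null(blood_fn)) cp else interp_curve(blood_fn, t_fine)
  to_frames <- function(v) {
    if (!is.null(schedule)) frame_average(t_fine, v, schedule)
    else stats::approx(t_fine, v, xout = tac$mid_time_min, rule = 2)$y
  }
  cols <- lapply(betas, function(b) to_frames(conv_grid(cp, exp(-b * t_fine), dt)))
  if (include_trapping) {
    col0 <- to_frames(c(0, cumsum(diff(t_fine) * (utils::head(cp, -1) + utils::tail(cp, -1)) / 2)))
    basis <- cbind(col0, do.call(cbind, cols))
    beta_grid <- c(0, betas)
  } else {
    basis <- do.call(cbind, cols)
    beta_grid <- betas
  }
  if (include_blood) {
    basis <- cbind(basis, to_frames(cb))
  }
  sol <- pracma::lsqnonneg(basis, tac$value_kBq_mL)
  alphas <- sol$x
  blood_weight <- if (include_blood) alphas[length(alphas)] else 0
  a <- alphas[seq_along(beta_grid)]
  out <- tibble::tibble(beta_per_min = beta_grid, alpha = a)
  attr(out, "Ki_trap") <- if (include_trapping) a[1] else 0
  rev_sel <- beta_grid > 0
  attr(out, "VT_rev") <- sum(a[rev_sel] / beta_grid[rev_sel])
  attr(out, "blood_weight") <- blood_weight
  attr(out, "rss") <- sum((basis %*% alphas - tac$value_kBq_mL)^2)
  attr(out, "region") <- tac$region[1]
  class(out) <- c("spectrum", class(out))
  out
}
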