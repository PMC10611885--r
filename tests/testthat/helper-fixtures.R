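# Shared fixtures: built in code at test time, kept deliberately small.

paper_schedule <- function() default_frame_schedule()

# dense evaluation grid and default bolus input used across kinetic tests
test_aif <- function(t_end = 66.5, dt = 1 / 60) {
  simulate_aif(seq(0, t_end, by = dt))
}

# Brute-force forward irreversible-2TC model, independent of the package's
# FFT convolution path: direct O(n^2) Riemann convolution on a 0.25-s grid,
# then exact frame averaging of that dense curve.
brute_force_2tc <- function(params, input_fn, schedule, dt_s = 0.25) {
  K1 <- params$K1; k2 <- params$k2; k3 <- params$k3
  vb <- if (is.null(params$vb)) 0 else params$vb
  dt <- dt_s / 60
  t <- seq(0, max(schedule$end_s) / 60, by = dt)
  cp <- approx(input_fn$time_min, input_fn$value_kBq_mL, xout = t, rule = 2)$y
  cp[t < min(input_fn$time_min)] <- 0
  s <- k2 + k3
  h <- if (s == 0) rep(K1, length(t)) else K1 * (k3 / s + (k2 / s) * exp(-s * t))
  ct_free <- numeric(length(t))
  for (i in seq_along(t)) {
    ct_free[i] <- sum(cp[1:i] * h[i:1]) * dt
  }
  ct <- (1 - vb) * ct_free + vb * cp
  vapply(seq_len(nrow(schedule)), function(j) {
    sel <- t >= schedule$start_s[j] / 60 & t <= schedule$end_s[j] / 60
    mean(ct[sel])
  }, numeric(1))
}

# small uniform-value dynamic image on a tiny grid
tiny_image <- function(value = 1, gs = c(6, 6, 4), nframes = 6) {
  sched <- frame_schedule(list(c(nframes, 60)))
  dynamic_image(array(value, c(gs, nframes)), sched)
}

box_mask <- function(gs, xr, yr, zr, role = "roi", vs = c(2, 2, 2)) {
  arr <- array(FALSE, gs)
  arr[xr, yr, zr] <- TRUE
  voi_mask(arr, role = role, voxel_size_mm = vs)
}

# fast phantom spec for image-level tests
small_phantom <- function(grade = 4, seed = 1, ...) {
  phantom_spec(grade = grade, seed = seed, grid_shape = c(32, 32, 24),
               lesion_radius_mm = 10, ...)
}

# gamma-variate bolus normalised to unit peak (independent of package internals)
gamma_bolus <- function(t, t0, alpha, beta) {
  tau <- pmax(t - t0, 0)
  g <- tau^alpha * exp(-tau / beta)
  g / ((alpha * beta)^alpha * exp(-alpha))
}

# contrast plasma curve used in DCE tests
gd_bolus_test <- function(t_min) {
  5 * gamma_bolus(t_min, 0.5, 3, 0.1) + 0.8 * (1 - exp(-5 * pmax(t_min - 0.5, 0))) *
    exp(-pmax(t_min - 0.5, 0) / 15)
}

# exact two-sided rank-sum p by direct label enumeration (independent oracle)
enum_ranksum_p <- function(x, y) {
  n <- length(x); N <- n + length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n)])
  sums <- apply(combn(N, n), 2, function(ix) sum(r[ix]))
  min(1, 2 * min(mean(sums <= w + 1e-9), mean(sums >= w - 1e-9)))
}
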