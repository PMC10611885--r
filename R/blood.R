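#' Blood sampling container
#'
#' Pairs the two arms of arterial sampling: a continuous early-phase
#' whole-blood curve (first ~10 min, from an on-line detector) and discrete
#' samples (default times 2.5, 15, 30, 45, 60 min) with whole-blood and plasma
#' activity and the parent (unmetabolised) fraction.
#'
#' @param continuous Tibble with columns `time_min`, `wb_kBq_mL`.
#' @param discrete Tibble with columns `time_min`, `wb_kBq_mL`,
#'   `plasma_kBq_mL`, `parent_fraction`.
#' @return A list of class `blood_series`.
#' @export
blood_series <- function(continuous, discrete) {
  stopifnot(all(c("time_min", "wb_kBq_mL") %in% names(continuous)),
            all(c("time_min", "wb_kBq_mL", "plasma_kBq_mL", "parent_fraction") %in% names(discrete)))
  if (any(diff(continuous$time_min) <= 0) || any(diff(discrete$time_min) <= 0))
    stop("blood sample times must be strictly increasing", call. = FALSE)
  if (any(continuous$wb_kBq_mL < 0) || any(discrete$wb_kBq_mL < 0) ||
      any(discrete$plasma_kBq_mL < 0))
    stop("blood activities must be nonnegative", call. = FALSE)
  if (any(discrete$parent_fraction < 0 | discrete$parent_fraction > 1))
    stop("parent fractions must lie in [0, 1]", call. = FALSE)
  structure(list(continuous = tibble::as_tibble(continuous),
                 discrete = tibble::as_tibble(discrete)),
            class = "blood_series")
}

#' Parent-plasma input function container
#'
#' @param time_min Dense increasing time grid (minutes).
#' @param value_kBq_mL Nonnegative parent-plasma activity concentration.
#' @param provenance `"measured"` or `"population"`.
#' @return A tibble of class `input_function`.
#' @export
input_function <- function(time_min, value_kBq_mL, provenance = "measured") {
  stopifnot(length(time_min) == length(value_kBq_mL))
  if (any(diff(time_min) <= 0)) stop("time grid must be strictly increasing", call. = FALSE)
  if (any(!is.finite(value_kBq_mL)) || any(value_kBq_mL < -1e-9))
    stop("input function must be finite and nonnegative", call. = FALSE)
  out <- tibble::tibble(time_min = as.numeric(time_min),
                        value_kBq_mL = pmax(as.numeric(value_kBq_mL), 0))
  attr(out, "provenance") <- provenance
  class(out) <- c("input_function", class(out))
  out
}

#' Cross-calibrate the continuous detector against discrete samples
#'
#' Scales the continuous whole-blood curve by the least-squares factor matching
#' the discrete whole-blood samples that fall inside the continuous window:
#' `scale = sum(c * d) / sum(c^2)` over overlapping samples, with `c` the
#' continuous curve interpolated at the discrete times.
#'
#' @param continuous Tibble `time_min`, `wb_kBq_mL`.
#' @param discrete Tibble with at least `time_min`, `wb_kBq_mL`.
#' @return The continuous tibble with `wb_kBq_mL` rescaled; the factor is in
#'   `attr(, "scale")`.
#' @export
cross_calibrate <- function(continuous, discrete) {
  rng <- range(continuous$time_min)
  ov <- discrete[discrete$time_min >= rng[1] & discrete$time_min <= rng[2], ]
  if (nrow(ov) == 0) {
    stop("no discrete sample falls inside the continuous sampling window", call. = FALSE)
  }
  c_at <- stats::approx(continuous$time_min, continuous$wb_kBq_mL, xout = ov$time_min)$y
  scale <- sum(c_at * ov$wb_kBq_mL) / sum(c_at^2)
  out <- continuous
  out$wb_kBq_mL <- out$wb_kBq_mL * scale
  attr(out, "scale") <- scale
  out
}

#' Fit / interpolate the parent fraction and correct plasma for metabolites
#'
#' Builds a parent-fraction model through the discrete samples with
#' `pf(0) = 1` enforced and monotone nonincreasing behaviour, and multiplies
#' the plasma activity by it. The default model is monotone piecewise-linear
#' interpolation; `"sigmoid"` fits `pf(t) = 1 - (1 - pf_inf) * t^h / (t50^h + t^h)`
#' by least squares (useful when samples are noisy).
#'
#' @param series A [blood_series()].
#' @param pf_model `"interpolate"` or `"sigmoid"`.
#' @return Tibble of corrected discrete samples (`time_min`,
#'   `parent_plasma_kBq_mL`); the fitted parent-fraction function (of time in
#'   minutes) is in `attr(, "pf_fun")`.
#' @export
metabolite_correct <- function(series, pf_model = c("interpolate", "sigmoid")) {
  pf_model <- match.arg(pf_model)
  d <- series$discrete
  if (any(d$parent_fraction < 0 | d$parent_fraction > 1))
    stop("parent fractions must lie in [0, 1]", call. = FALSE)
  t_k <- c(0, d$time_min)
  pf_k <- c(1, cummin(pmin(d$parent_fraction, 1)))  # enforce pf(0)=1, monotone
  if (pf_model == "interpolate") {
    pf_fun <- stats::approxfun(t_k, pf_k, rule = 2)
  } else {
    resid_fn <- function(p) {
      pf_inf <- stats::plogis(p[1]); t50 <- exp(p[2]); h <- exp(p[3])
      1 - (1 - pf_inf) * d$time_min^h / (t50^h + d$time_min^h) - d$parent_fraction
    }
    fit <- minpack.lm::nls.lm(par = c(0, log(20), log(2)), fn = resid_fn,
                              control = minpack.lm::nls.lm.control(maxiter = 200))
    p <- fit$par
    pf_inf <- stats::plogis(p[1]); t50 <- exp(p[2]); h <- exp(p[3])
    pf_fun <- function(t) 1 - (1 - pf_inf) * pmax(t, 0)^h / (t50^h + pmax(t, 0)^h)
  }
  out <- tibble::tibble(
    time_min = d$time_min,
    parent_plasma_kBq_mL = d$plasma_kBq_mL * pf_fun(d$time_min)
  )
  attr(out, "pf_fun") <- pf_fun
  out
}

#' Merge continuous and discrete arms into one input function
#'
#' Keeps the (already calibrated, metabolite-corrected) continuous segment up
#' to its end, then continues by piecewise-linear interpolation through the
#' later discrete points, anchored at the continuous end value so the merged
#' curve is continuous at the junction. Beyond the last discrete point the
#' value is held constant.
#'
#' @param continuous_parent Tibble `time_min`, `value_kBq_mL` (parent plasma).
#' @param discrete_parent Tibble `time_min`, `parent_plasma_kBq_mL`.
#' @param total_min End of the output grid (default 66.5).
#' @param dt_min Output grid step for the tail segment (default 0.1).
#' @return An [input_function()].
#' @export
merge_input_function <- function(continuous_parent, discrete_parent,
                                 total_min = 66.5, dt_min = 0.1) {
  t_end <- max(continuous_parent$time_min)
  tail_pts <- discrete_parent[discrete_parent$time_min > t_end, ]
  gap_times <- c(t_end, tail_pts$time_min, total_min)
  if (any(diff(gap_times) > 20)) {
    warning("input-function gap exceeding 20 min with no data; interpolating anyway")
  }
  anchor_val <- continuous_parent$value_kBq_mL[which.max(continuous_parent$time_min)]
  knots_t <- c(t_end, tail_pts$time_min)
  knots_v <- c(anchor_val, tail_pts$parent_plasma_kBq_mL)
  t_tail <- seq(t_end, total_min, by = dt_min)
  if (t_tail[length(t_tail)] < total_min) t_tail <- c(t_tail, total_min)
  v_tail <- stats::approx(knots_t, knots_v, xout = t_tail, rule = 2)$y
  keep <- continuous_parent$time_min < t_end
  input_function(
    c(continuous_parent$time_min[keep], t_tail),
    c(continuous_parent$value_kBq_mL[keep], v_tail),
    provenance = "measured"
  )
}

#' Assemble a metabolite-corrected input function from raw blood data
#'
#' Convenience composition: cross-calibration of the continuous detector,
#' plasma/whole-blood conversion (constant ratio fitted from discrete samples),
#' parent-fraction correction, and the continuous/discrete merge.
#'
#' @param series A [blood_series()].
#' @param pf_model Passed to [metabolite_correct()].
#' @param total_min Scan length in minutes.
#' @return An [input_function()].
#' @export
build_input_function <- function(series, pf_model = "interpolate", total_min = 66.5) {
  cont <- cross_calibrate(series$continuous, series$discrete)
  d <- series$discrete
  pw_ratio <- if (all(d$wb_kBq_mL > 0)) mean(d$plasma_kBq_mL / d$wb_kBq_mL) else 1
  corrected <- metabolite_correct(series, pf_model = pf_model)
  pf_fun <- attr(corrected, "pf_fun")
  cont_parent <- tibble::tibble(
    time_min = cont$time_min,
    value_kBq_mL = cont$wb_kBq_mL * pw_ratio * pf_fun(cont$time_min)
  )
  merge_input_function(cont_parent, corrected, total_min = total_min)
}

#' Population-average input function
#'
#' Normalises each measured input function to SUV units (divide by injected
#' dose over body weight), averages on a common grid, and returns a template
#' that can be rescaled to a new patient's dose and weight with
#' [apply_population_if()].
#'
#' @param ifs List of [input_function()] objects.
#' @param metas List of [patient_meta()] rows, parallel to `ifs`.
#' @return A tibble of class `population_if` (`time_min`, `suv_value`).
#' @export
population_input_function <- function(ifs, metas) {
  if (length(ifs) == 0) stop("need at least one measured input function", call. = FALSE)
  stopifnot(length(ifs) == length(metas))
  t_max <- min(vapply(ifs, function(f) max(f$time_min), numeric(1)))
  grid <- seq(0, t_max, by = 0.1)
  curves <- mapply(function(f, m) {
    suv_scale <- m$injected_activity_MBq / m$body_weight_kg
    stats::approx(f$time_min, f$value_kBq_mL, xout = grid, rule = 2)$y / suv_scale
  }, ifs, metas)
  out <- tibble::tibble(time_min = grid, suv_value = rowMeans(as.matrix(curves)))
  class(out) <- c("population_if", class(out))
  out
}

#' @rdname population_input_function
#' @param template A `population_if` template.
#' @param meta A [patient_meta()] row for the patient to scale to.
#' @export
apply_population_if <- function(template, meta) {
  input_function(template$time_min,
                 template$suv_value * meta$injected_activity_MBq / meta$body_weight_kg,
                 provenance = "population")
}
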