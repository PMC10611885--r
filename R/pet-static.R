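#' Standardised uptake value
#'
#' `SUV = C[kBq/mL] / (injected_activity[MBq] / body_weight[kg])`, assuming a
#' tissue density of 1 g/mL (so kBq/mL / (kBq/g injected per g) is unitless).
#'
#' @param values Activity concentration, kBq/mL: a 3-D array or numeric vector.
#' @param meta A [patient_meta()] row.
#' @param window Provenance label for the static window used.
#' @return Object of class `suv_image`: list with `voxels` (same shape as
#'   `values`), `window`, `corrected`.
#' @export
compute_suv <- function(values, meta, window = "static_frame") {
  if (meta$injected_activity_MBq <= 0 || meta$body_weight_kg <= 0)
    stop("dose and weight must be positive", call. = FALSE)
  suv <- values / (meta$injected_activity_MBq / meta$body_weight_kg)
  structure(list(voxels = suv, window = window, corrected = FALSE),
            class = "suv_image")
}

#' @export
print.suv_image <- function(x, ...) {
  cat("<suv_image> window=", x$window, if (x$corrected) " (blood-corrected)",
      ", max=", signif(max(x$voxels), 4), "\n", sep = "")
  invisible(x)
}

#' Static analysis window of a dynamic acquisition
#'
#' Two conventions: `"last5_mean"` is the duration-weighted mean of the final
#' five frames (the last 26 min of the default schedule); `"frame_nearest_60"`
#' selects the single frame whose mid-time is closest to 60 min. Note that no
#' frame of the default schedule has mid-time exactly 60 min — the 55.5-60.5
#' min frame (mid-time 58 min) is the closest and is the one selected.
#'
#' @param image A [dynamic_image()].
#' @param mode `"last5_mean"` or `"frame_nearest_60"`.
#' @return A 3-D array of activity values (kBq/mL) for the window, with
#'   attributes `window_min` (length) and `frames` used.
#' @export
static_window <- function(image, mode = c("last5_mean", "frame_nearest_60")) {
  mode <- match.arg(mode)
  sched <- image$schedule
  if (mode == "last5_mean") {
    if (nrow(sched) < 5) stop("need at least 5 frames for last5_mean", call. = FALSE)
    idx <- seq.int(nrow(sched) - 4, nrow(sched))
    w <- sched$duration_s[idx] / sum(sched$duration_s[idx])
    d <- dim(image$voxels)
    out <- array(0, d[1:3])
    for (j in seq_along(idx)) out <- out + w[j] * image$voxels[, , , idx[j]]
    attr(out, "window_min") <- sum(sched$duration_s[idx]) / 60
    attr(out, "frames") <- idx
  } else {
    idx <- which.min(abs(sched$mid_min - 60))
    out <- image$voxels[, , , idx]
    attr(out, "window_min") <- sched$duration_s[idx] / 60
    attr(out, "frames") <- idx
  }
  out
}

#' Blood-pool correction of an SUV image
#'
#' Subtracts a normalised whole-blood contribution estimated in the superior
#' sagittal sinus: `SUVc = SUV - blood_fraction * mean(SUV over sinus)`.
#' `blood_fraction` scales the sinus (pure blood) signal down to a nominal
#' tissue blood-volume fraction; no clamping at zero is applied.
#'
#' @param suv A `suv_image`.
#' @param sinus A non-empty [voi_mask()] over the sagittal sinus.
#' @param blood_fraction Fraction of the sinus mean to subtract, in `[0,1]`
#'   (default 0.05, a nominal cerebral blood volume fraction).
#' @return A corrected `suv_image` (`corrected = TRUE`); the subtracted value
#'   is in `attr(, "nSUVwb")`.
#' @export
blood_correct <- function(suv, sinus, blood_fraction = 0.05) {
  stopifnot(blood_fraction >= 0, blood_fraction <= 1)
  if (sum(sinus$voxels) == 0) stop("sinus mask is empty", call. = FALSE)
  n_suv_wb <- blood_fraction * mean(suv$voxels[sinus$voxels])
  out <- suv
  out$voxels <- suv$voxels - n_suv_wb
  out$corrected <- TRUE
  attr(out, "nSUVwb") <- n_suv_wb
  out
}

#' Tumour-to-brain ratios
#'
#' `tbr_max = max(SUV in tumour) / mean(SUV in contralateral)`;
#' `tbr_mean = mean / mean`.
#'
#' @param suv A `suv_image`.
#' @param tumour,contralateral Non-empty [voi_mask()]s.
#' @return A one-row tibble with `tbr_max`, `tbr_mean`, `suv_max`, `suv_mean`,
#'   `contralateral_mean`.
#' @export
tbr <- function(suv, tumour, contralateral) {
  if (sum(tumour$voxels) == 0 || sum(contralateral$voxels) == 0)
    stop("tumour and contralateral masks must be non-empty", call. = FALSE)
  ref <- mean(suv$voxels[contralateral$voxels])
  if (ref <= 0) stop("contralateral mean SUV is not positive", call. = FALSE)
  tum <- suv$voxels[tumour$voxels]
  tibble::tibble(
    tbr_max = max(tum) / ref, tbr_mean = mean(tum) / ref,
    suv_max = max(tum), suv_mean = mean(tum), contralateral_mean = ref
  )
}

#' Fractional-threshold segmentation of an SUV image
#'
#' Finds the maximum SUV inside a search region and keeps voxels at or above
#' `fraction * SUVmax`, restricted to the 26-connected component containing
#' the maximum voxel (so low-uptake background at similar intensity elsewhere
#' is not picked up). `fraction = 0.3` and `0.4` give the SUV30 and SUV40
#' masks used for PET/MRI overlap scoring.
#'
#' @param suv A `suv_image`.
#' @param fraction Threshold fraction in (0, 1).
#' @param search A non-empty [voi_mask()] to search within.
#' @return A [voi_mask()] with role `"suv<100*fraction>"`.
#' @export
threshold_mask <- function(suv, fraction, search) {
  stopifnot(fraction > 0, fraction < 1)
  if (sum(search$voxels) == 0) stop("search region is empty", call. = FALSE)
  vals <- suv$voxels[search$voxels]
  vmax <- max(vals)
  if (vmax <= 0) stop("image is nonpositive over the search region", call. = FALSE)
  cand <- array(FALSE, dim(suv$voxels))
  cand[search$voxels] <- suv$voxels[search$voxels] >= fraction * vmax
  seed <- array(FALSE, dim(suv$voxels))
  in_search <- which(search$voxels)
  seed[in_search[which.max(suv$voxels[search$voxels])]] <- TRUE
  comp <- connected_component(cand, seed)
  voi_mask(comp, role = paste0("suv", round(100 * fraction)),
           voxel_size_mm = search$voxel_size_mm, affine = search$affine)
}

# 26-connectivity connected component containing `seed`, within `cand`.
# Iterative dilation by axis shifts until fixpoint; grids here are small.
connected_component <- function(cand, seed) {
  comp <- seed & cand
  repeat {
    grown <- dilate26(comp) & cand
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  comp
}

dilate26 <- function(m) {
  d <- dim(m)
  out <- m
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    out <- out | shift3(m, dx, dy, dz)
  }
  out
}

shift3 <- function(m, dx, dy, dz) {
  d <- dim(m)
  out <- array(FALSE, d)
  xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
  sx <- xs - dx; sy <- ys - dy; sz <- zs - dz
  okx <- sx >= 1 & sx <= d[1]; oky <- sy >= 1 & sy <= d[2]; okz <- sz >= 1 & sz <= d[3]
  out[xs[okx], ys[oky], zs[okz]] <- m[sx[okx], sy[oky], sz[okz]]
  out
}

#' Dice overlap between two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`. Symmetric in its arguments.
#'
#' @param a,b [voi_mask()]s on the same grid.
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop("masks are on different grids", call. = FALSE)
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0) stop("both masks are empty", call. = FALSE)
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

#' Percent volume variation between an MRI and an SUV mask
#'
#' `((volume_mri - volume_suv) / volume_suv) * 100`, volumes in mL. Note the
#' asymmetry: the SUV-threshold mask is the denominator (reference).
#'
#' @param mri MRI-derived [voi_mask()].
#' @param suv SUV-threshold [voi_mask()] (non-empty).
#' @return Percent volume variation.
#' @export
volume_variation <- function(mri, suv) {
  v_suv <- mask_volume_mL(suv)
  if (v_suv <= 0) stop("SUV mask is empty", call. = FALSE)
  (mask_volume_mL(mri) - v_suv) / v_suv * 100
}
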