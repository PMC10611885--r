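#' Timed 4-D PET image container
#'
#' Holds a 4-D array of decay-corrected activity concentration (kBq/mL) on a
#' regular grid, together with its voxel geometry and frame schedule. The frame
#' axis is the 4th array dimension and must match the schedule length.
#'
#' @param voxels 4-D numeric array (x, y, z, frame), kBq/mL.
#' @param schedule A [frame_schedule()].
#' @param voxel_size_mm Numeric length-3, positive.
#' @param affine 4x4 voxel-to-world matrix; default built from `voxel_size_mm`.
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(voxels, schedule,
                          voxel_size_mm = c(2, 2, 2),
                          affine = NULL) {
  stopifnot(length(dim(voxels)) == 4, is_frame_schedule(schedule))
  if (dim(voxels)[4] != nrow(schedule)) {
    stop("frame-count mismatch: image has ", dim(voxels)[4],
         " frames but schedule has ", nrow(schedule), call. = FALSE)
  }
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive", call. = FALSE)
  if (any(!is.finite(voxels))) stop("voxel values must be finite", call. = FALSE)
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  structure(
    list(voxels = voxels, schedule = schedule,
         voxel_size_mm = voxel_size_mm, affine = affine),
    class = "dynamic_image"
  )
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat("<dynamic_image> ", paste(d[1:3], collapse = "x"), " voxels, ",
      d[4], " frames, ", round(total_duration_min(x$schedule), 2), " min\n", sep = "")
  invisible(x)
}

#' Volume-of-interest mask
#'
#' @param voxels 3-D logical array.
#' @param role Label for the mask's role, e.g. `"lesion_flair"`, `"lesion_t1ce"`,
#'   `"contralateral"`, `"cwm"`, `"sinus"`, `"suv30"`, `"suv40"`.
#' @inheritParams dynamic_image
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(voxels, role = "roi", voxel_size_mm = c(2, 2, 2), affine = NULL) {
  stopifnot(length(dim(voxels)) == 3)
  voxels <- array(as.logical(voxels), dim = dim(voxels))
  if (any(is.na(voxels))) stop("mask may not contain NA", call. = FALSE)
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  structure(
    list(voxels = voxels, role = role,
         voxel_size_mm = voxel_size_mm, affine = affine),
    class = "voi_mask"
  )
}

#' @export
print.voi_mask <- function(x, ...) {
  cat("<voi_mask> role=", x$role, ", ", sum(x$voxels), " voxels (",
      round(mask_volume_mL(x), 2), " mL)\n", sep = "")
  invisible(x)
}

#' Mask volume in millilitres
#' @param mask A `voi_mask`.
#' @export
mask_volume_mL <- function(mask) {
  sum(mask$voxels) * prod(mask$voxel_size_mm) / 1000
}

#' Patient metadata record
#'
#' @param patient_id Character scalar.
#' @param injected_activity_MBq Injected dose, MBq. Values outside 50-1000 MBq
#'   trigger a warning (plausibility screen).
#' @param body_weight_kg Body weight, kg.
#' @param who_grade WHO grade, one of 2, 3, 4. The binary `grade_label`
#'   (LGG for grade 2, HGG for 3-4) is derived.
#' @return A one-row tibble of class `patient_meta`.
#' @export
patient_meta <- function(patient_id, injected_activity_MBq, body_weight_kg, who_grade) {
  stopifnot(is.character(patient_id), length(patient_id) == 1)
  if (!is.finite(injected_activity_MBq) || injected_activity_MBq <= 0)
    stop("injected activity must be positive", call. = FALSE)
  if (!is.finite(body_weight_kg) || body_weight_kg <= 0)
    stop("body weight must be positive", call. = FALSE)
  if (injected_activity_MBq < 50 || injected_activity_MBq > 1000)
    warning("injected activity ", injected_activity_MBq,
            " MBq outside plausible 50-1000 MBq range")
  if (!who_grade %in% c(2, 3, 4)) stop("who_grade must be 2, 3 or 4", call. = FALSE)
  out <- tibble::tibble(
    patient_id = patient_id,
    injected_activity_MBq = injected_activity_MBq,
    body_weight_kg = body_weight_kg,
    who_grade = as.integer(who_grade),
    grade_label = ifelse(who_grade == 2, "LGG", "HGG")
  )
  class(out) <- c("patient_meta", class(out))
  out
}

#' Region time-activity curve
#'
#' @param mid_time_min Frame mid-times, minutes, strictly increasing.
#' @param value_kBq_mL Activity concentration per frame.
#' @param statistic `"mean"` or `"max"` over the region.
#' @param region Region name.
#' @return A tibble of class `tissue_tac` with columns `mid_time_min`,
#'   `value_kBq_mL`, `statistic`, `region`.
#' @export
tissue_tac <- function(mid_time_min, value_kBq_mL, statistic = "mean", region = "roi") {
  stopifnot(length(mid_time_min) == length(value_kBq_mL))
  if (any(diff(mid_time_min) <= 0)) stop("mid-times must be strictly increasing", call. = FALSE)
  out <- tibble::tibble(
    mid_time_min = as.numeric(mid_time_min),
    value_kBq_mL = as.numeric(value_kBq_mL),
    statistic = statistic, region = region
  )
  class(out) <- c("tissue_tac", class(out))
  out
}

#' Extract a region time-activity curve from a dynamic image
#'
#' @param image A [dynamic_image()].
#' @param mask A [voi_mask()] on the same grid.
#' @param statistic `"mean"` (region average per frame) or `"max"`.
#' @return A [tissue_tac()] tibble.
#' @export
extract_tac <- function(image, mask, statistic = c("mean", "max")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(image, "dynamic_image"), inherits(mask, "voi_mask"))
  if (!identical(dim(image$voxels)[1:3], dim(mask$voxels))) {
    stop("mask grid does not match image grid", call. = FALSE)
  }
  idx <- which(mask$voxels)
  if (length(idx) == 0) stop("mask is empty", call. = FALSE)
  nf <- dim(image$voxels)[4]
  nvox <- prod(dim(image$voxels)[1:3])
  mat <- matrix(image$voxels, nrow = nvox, ncol = nf)[idx, , drop = FALSE]
  vals <- if (statistic == "mean") colMeans(mat) else apply(mat, 2, max)
  tissue_tac(frame_mid_times(image$schedule), vals,
             statistic = statistic, region = mask$role)
}

#' Nearest-neighbour resampling of a mask onto a reference grid
#'
#' Maps each reference voxel centre through the reference affine into world
#' space, then through the inverse of the mask affine into mask voxel indices,
#' and takes the nearest voxel. Masks defined in MRI space are brought onto the
#' PET quantification grid this way.
#'
#' @param mask A `voi_mask` (any grid).
#' @param reference A `dynamic_image` or `voi_mask` providing the target grid.
#' @return A `voi_mask` on the reference grid.
#' @export
resample_mask <- function(mask, reference) {
  ref_dim <- if (inherits(reference, "dynamic_image")) dim(reference$voxels)[1:3] else dim(reference$voxels)
  if (identical(dim(mask$voxels), ref_dim) &&
      isTRUE(all.equal(mask$affine, reference$affine, tolerance = 1e-8))) {
    return(voi_mask(mask$voxels, role = mask$role,
                    voxel_size_mm = reference$voxel_size_mm, affine = reference$affine))
  }
  # voxel index -> world: affine %*% c(i-1, j-1, k-1, 1) (0-based indexing)
  map <- solve(mask$affine) %*% reference$affine
  grid <- as.matrix(expand.grid(i = seq_len(ref_dim[1]) - 1,
                                j = seq_len(ref_dim[2]) - 1,
                                k = seq_len(ref_dim[3]) - 1))
  src <- cbind(grid, 1) %*% t(map)
  src_idx <- round(src[, 1:3]) + 1
  md <- dim(mask$voxels)
  inside <- src_idx[, 1] >= 1 & src_idx[, 1] <= md[1] &
    src_idx[, 2] >= 1 & src_idx[, 2] <= md[2] &
    src_idx[, 3] >= 1 & src_idx[, 3] <= md[3]
  vals <- logical(nrow(grid))
  lin <- (src_idx[inside, 3] - 1) * md[1] * md[2] + (src_idx[inside, 2] - 1) * md[1] + src_idx[inside, 1]
  vals[inside] <- mask$voxels[lin]
  voi_mask(array(vals, dim = ref_dim), role = mask$role,
           voxel_size_mm = reference$voxel_size_mm, affine = reference$affine)
}
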