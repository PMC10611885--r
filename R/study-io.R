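#' Write a study to a directory of NIfTI / CSV / JSON files
#'
#' Persists a complete (typically simulated) PET/MRI study: the 4-D PET volume,
#' VOI masks, dynamic MRI series, blood sampling tables, patient metadata and,
#' when present, the generating ground truth. All volumes go to NIfTI-1, tables
#' to CSV, metadata to JSON; a manifest of MD5 checksums is written alongside.
#'
#' @param study A study list as produced by [generate_study()] or [load_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)

  write_vol(study$pet$voxels, study$pet$voxel_size_mm, file.path(dir, "pet.nii.gz"))
  readr::write_csv(tibble::as_tibble(study$pet$schedule)[c("frame", "start_s", "duration_s")],
                   file.path(dir, "schedule.csv"))
  for (m in study$masks) {
    write_vol(m$voxels * 1, m$voxel_size_mm, file.path(dir, "masks", paste0(m$role, ".nii.gz")))
  }
  readr::write_csv(study$blood$continuous, file.path(dir, "blood_continuous.csv"))
  readr::write_csv(study$blood$discrete, file.path(dir, "blood_discrete.csv"))
  jsonlite::write_json(as.list(study$meta), file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)

  geom <- list(voxel_size_mm = study$pet$voxel_size_mm, affine = study$pet$affine)
  mri_params <- list()
  if (!is.null(study$mri)) {
    if (!is.null(study$mri$dce)) {
      write_vol(study$mri$dce$signal, study$pet$voxel_size_mm, file.path(dir, "dce.nii.gz"))
      mri_params$dce <- study$mri$dce[setdiff(names(study$mri$dce), "signal")]
    }
    if (!is.null(study$mri$dsc)) {
      write_vol(study$mri$dsc$signal, study$pet$voxel_size_mm, file.path(dir, "dsc.nii.gz"))
      mri_params$dsc <- study$mri$dsc[setdiff(names(study$mri$dsc), "signal")]
    }
    if (!is.null(study$mri$asl)) {
      write_vol(study$mri$asl$delta_M, study$pet$voxel_size_mm, file.path(dir, "asl_deltam.nii.gz"))
      write_vol(study$mri$asl$M0, study$pet$voxel_size_mm, file.path(dir, "asl_m0.nii.gz"))
      mri_params$asl <- study$mri$asl[setdiff(names(study$mri$asl), c("delta_M", "M0"))]
    }
    if (!is.null(study$mri$dwi)) {
      write_vol(study$mri$dwi$signal, study$pet$voxel_size_mm, file.path(dir, "dwi.nii.gz"))
      mri_params$dwi <- study$mri$dwi[setdiff(names(study$mri$dwi), "signal")]
    }
  }
  jsonlite::write_json(list(geometry = geom, mri = mri_params),
                       file.path(dir, "study.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(study$truth)) {
    jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.csv"]
  manifest <- tibble::tibble(
    file = sub(paste0("^", dir, "/?"), "", files),
    md5 = unname(tools::md5sum(files))
  )
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' Load a study directory
#'
#' Reads a directory written by [write_study()] back into a study list,
#' validating geometry: every mask must either share the PET grid or be
#' resampled onto it by nearest neighbour; the schedule length must match the
#' PET frame axis.
#'
#' @param dir Study directory.
#' @return A study list with elements `pet`, `masks`, `blood`, `meta`, `mri`
#'   and (if present) `truth`.
#' @export
load_study <- function(dir) {
  need <- c("pet.nii.gz", "schedule.csv", "blood_continuous.csv",
            "blood_discrete.csv", "meta.json", "study.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0) {
    stop("study directory is missing required file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  info <- jsonlite::read_json(file.path(dir, "study.json"), simplifyVector = TRUE)
  vs <- as.numeric(info$geometry$voxel_size_mm)
  affine <- matrix(unlist(info$geometry$affine), 4, 4)

  sched_tab <- readr::read_csv(file.path(dir, "schedule.csv"), show_col_types = FALSE)
  schedule <- schedule_from_frames(sched_tab$start_s, sched_tab$duration_s)

  pet_arr <- read_vol(file.path(dir, "pet.nii.gz"))
  if (length(dim(pet_arr)) != 4 || dim(pet_arr)[4] != nrow(schedule)) {
    stop("frame-count mismatch between pet.nii.gz and schedule.csv", call. = FALSE)
  }
  pet <- dynamic_image(pet_arr, schedule, voxel_size_mm = vs, affine = affine)

  mask_files <- list.files(file.path(dir, "masks"), pattern = "\\.nii(\\.gz)?$",
                           full.names = TRUE)
  masks <- list()
  for (f in mask_files) {
    role <- sub("\\.nii(\\.gz)?$", "", basename(f))
    arr <- read_vol(f)
    m <- voi_mask(arr > 0.5, role = role, voxel_size_mm = vs, affine = affine)
    masks[[role]] <- resample_mask(m, pet)
  }

  meta_raw <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  meta <- patient_meta(meta_raw$patient_id, meta_raw$injected_activity_MBq,
                       meta_raw$body_weight_kg, meta_raw$who_grade)

  blood <- blood_series(
    continuous = readr::read_csv(file.path(dir, "blood_continuous.csv"), show_col_types = FALSE),
    discrete = readr::read_csv(file.path(dir, "blood_discrete.csv"), show_col_types = FALSE)
  )

  mri <- list()
  if (file.exists(file.path(dir, "dce.nii.gz"))) {
    mri$dce <- c(list(signal = read_vol(file.path(dir, "dce.nii.gz"))), info$mri$dce)
  }
  if (file.exists(file.path(dir, "dsc.nii.gz"))) {
    mri$dsc <- c(list(signal = read_vol(file.path(dir, "dsc.nii.gz"))), info$mri$dsc)
  }
  if (file.exists(file.path(dir, "asl_deltam.nii.gz"))) {
    mri$asl <- c(list(delta_M = read_vol(file.path(dir, "asl_deltam.nii.gz")),
                      M0 = read_vol(file.path(dir, "asl_m0.nii.gz"))), info$mri$asl)
  }
  if (file.exists(file.path(dir, "dwi.nii.gz"))) {
    mri$dwi <- c(list(signal = read_vol(file.path(dir, "dwi.nii.gz"))), info$mri$dwi)
  }

  truth <- NULL
  if (file.exists(file.path(dir, "truth.json"))) {
    truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  }
  list(pet = pet, masks = masks, blood = blood, meta = meta,
       mri = if (length(mri)) mri else NULL, truth = truth)
}

schedule_from_frames <- function(start_s, duration_s) {
  out <- tibble::tibble(
    frame = seq_along(start_s), start_s = start_s, duration_s = duration_s,
    end_s = start_s + duration_s, mid_min = (start_s + duration_s / 2) / 60
  )
  class(out) <- c("frame_schedule", class(out))
  validate_frame_schedule(out)
}

write_vol <- function(arr, voxel_size_mm, path) {
  img <- RNifti::asNifti(arr, pixdim = voxel_size_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_vol <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  attributes(arr) <- list(dim = dim(arr))
  arr
}
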