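## File-format interfaces: NIfTI volumes (RNifti), TIFF sections (tiff),
## tidy CSV tables, YAML configuration and JSON ground-truth sidecars.

#' Write a 3-D/4-D array or label volume as NIfTI
#'
#' @param x `label_volume`, `multiecho_image`, `t2_map` (writes the T2
#'   array), or a numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing voxel spacing in mm (taken from the object if present).
#' @return the path, invisibly.
#' @export
write_nifti_volume <- function(x, path, spacing = NULL) {
  if (inherits(x, "label_volume")) {
    a <- x$labels; spacing <- x$spacing
  } else if (inherits(x, "multiecho_image")) {
    a <- x$data; spacing <- x$spacing
  } else if (inherits(x, "t2_map")) {
    a <- x$t2; a[!x$valid] <- NA_real_
  } else {
    a <- x
  }
  if (is.null(spacing)) spacing <- rep(1, min(length(dim(a)), 3))
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(spacing, rep(1, length(dim(a)) - length(spacing)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file.
#' @return numeric array with attribute `spacing` (mm per axis).
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim(img))
  attr(a, "spacing") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(a))))]
  a
}

#' Write a section image as TIFF
#'
#' Stores the 0-255 transmitted-light values as 8-bit grayscale. TIFF rasters
#' are row-major (first index = row = y), so the matrix is transposed on the
#' way out and back.
#'
#' @param section a `section_image` or numeric matrix (0-255).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_section_tiff <- function(section, path) {
  px <- if (inherits(section, "section_image")) section$pixels else section
  tiff::writeTIFF(t(px) / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a TIFF section image back to the 0-255 scale
#'
#' @param path TIFF file.
#' @param pixel_size_um pixel size to attach (um).
#' @return a `section_image` (without ground-truth annotations).
#' @export
read_section_tiff <- function(path, pixel_size_um = NA_real_) {
  r <- tiff::readTIFF(path)
  if (length(dim(r)) == 3) r <- r[, , 1]
  structure(list(pixels = t(r * 255), pixel_size_um = pixel_size_um,
                 truth = NULL),
            class = "section_image")
}

#' Write a cohort to disk
#'
#' Behaviour and subject tables as CSV plus a JSON sidecar with the
#' generating trajectory ground truth (true effect sizes, noise levels,
#' seed).
#'
#' @param cohort an `hd_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$behaviour, file.path(dir, "behaviour.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$scans, file.path(dir, "scans.csv"),
                   row.names = FALSE)
  tr <- cohort$trajectory
  sidecar <- list(
    seed = cohort$seed,
    declines = lapply(tr$regions, function(r) r$HD$decline),
    behavioural_deficits = lapply(tr$behaviour, `[[`, "deficit"),
    noise = tr$noise, missingness = tr$missingness,
    outlier_rate = tr$outlier_rate
  )
  jsonlite::write_json(sidecar, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a trajectory configuration from YAML
#'
#' Accepts a file with optional top-level keys `regions`, `behaviour`,
#' `sex_factor`, `noise`, `missingness`, `outlier_rate`, `outlier_sd`;
#' anything omitted keeps its default. Region and measure entries are merged
#' into the defaults field by field.
#'
#' @param path YAML file.
#' @return a [trajectory_config()].
#' @export
read_trajectory_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  tc <- trajectory_config()
  merge_into <- function(base, upd) {
    for (k in names(upd)) {
      base[[k]] <- if (is.list(upd[[k]]) && is.list(base[[k]])) {
        merge_into(base[[k]], upd[[k]])
      } else upd[[k]]
    }
    base
  }
  for (k in intersect(names(cfg), c("regions", "behaviour", "noise"))) {
    tc[[k]] <- merge_into(tc[[k]], cfg[[k]])
  }
  for (k in intersect(names(cfg),
                      c("missingness", "outlier_rate", "outlier_sd"))) {
    tc[[k]] <- cfg[[k]]
  }
  if (!is.null(cfg$sex_factor)) tc$sex_factor <- unlist(cfg$sex_factor)
  tc
}
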