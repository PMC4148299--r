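# Disk interchange: NIfTI images, BIDS-style events TSV, plain-text motion
# parameters, JSON ground truth.

run_basename <- function(subject_id, session_id) {
  sprintf("sub-%02d_ses-%d", subject_id, session_id)
}

# time x in-brain matrix -> 4D array in the geometry's grid (0 outside brain)
run_to_4d <- function(run) {
  geom <- run$geometry
  vol <- prod(geom$shape)
  arr <- array(0, c(vol, run$n_volumes))
  arr[geom$brain_idx, ] <- t(run$data)
  array(arr, c(geom$shape, run$n_volumes))
}

#' Write one BOLD run to disk
#'
#' NIfTI-1 image (`.nii.gz`) plus a whitespace-delimited 6-column motion
#' file.
#'
#' @param run A `bold_run`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, run_basename(run$subject_id, run$session_id))
  img <- RNifti::asNifti(run_to_4d(run))
  RNifti::pixdim(img) <- c(run$geometry$voxel_size, run$tr)
  bold_path <- paste0(base, "_bold.nii.gz")
  RNifti::writeNifti(img, bold_path)
  motion_path <- paste0(base, "_motion.txt")
  motion_chr <- apply(run$motion, 2, formatC, digits = 17, format = "g")
  utils::write.table(motion_chr, motion_path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(c(bold = bold_path, motion = motion_path))
}

#' Write a simulated cohort to disk
#'
#' Writes every run (NIfTI + motion text), the shared events TSV (`onset`,
#' `duration`, `trial_type`; seconds from the first volume), the region-label
#' image, the ground truth as JSON, and a `manifest.tsv` indexing the runs.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  geom <- cohort$geometry
  readr::write_tsv(cohort$schedule[c("onset", "duration", "trial_type")],
                   file.path(dir, "events.tsv"))
  labels_img <- RNifti::asNifti(geom$labels + 0)
  RNifti::pixdim(labels_img) <- geom$voxel_size
  RNifti::writeNifti(labels_img, file.path(dir, "labels.nii.gz"))
  manifest <- purrr::map_dfr(cohort$runs, function(run) {
    paths <- write_run(run, dir)
    tibble(subject = run$subject_id, session = run$session_id,
           bold = basename(paths[["bold"]]), motion = basename(paths[["motion"]]))
  })
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(true_icc_by_region = as.list(gt$true_icc_by_region),
         subject_amplitudes = gt$subject_amplitudes,
         subject_hrf_params = gt$subject_hrf_params,
         confound_series = gt$confound_series),
    file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

# Rebuild a phantom_geometry from a region-label image.
geometry_from_labels <- function(labels, voxel_size) {
  labels <- array(as.integer(round(labels)), dim(labels))
  brain <- labels > 0
  structure(
    list(shape = dim(labels), voxel_size = voxel_size, labels = labels,
         brain_mask = brain, high_var = array(FALSE, dim(labels)),
         brain_idx = which(brain), affine = diag(c(voxel_size, 1))),
    class = "phantom_geometry"
  )
}

#' Load study inputs from disk
#'
#' Reads a directory in the layout produced by [write_cohort()] (or
#' assembled by hand for real data): `manifest.tsv` with `subject`,
#' `session`, `bold`, `motion` columns, `events.tsv`, and `labels.nii.gz`.
#' The loaded runs feed [run_study()] in place of the phantom.
#'
#' @param dir Input directory.
#' @return A list with `runs`, `geometry`, `schedule`.
#' @export
load_real_inputs <- function(dir) {
  manifest_path <- file.path(dir, "manifest.tsv")
  assert_that(file.exists(manifest_path), paste("no manifest.tsv in", dir))
  manifest <- readr::read_tsv(manifest_path, show_col_types = FALSE)
  sessions_per_subject <- manifest |>
    dplyr::count(.data$subject)
  orphans <- sessions_per_subject$subject[sessions_per_subject$n != 2]
  assert_that(length(orphans) == 0,
              paste("subject(s) without exactly 2 sessions:",
                    paste(orphans, collapse = ", ")))
  labels_img <- RNifti::readNifti(file.path(dir, "labels.nii.gz"))
  voxel_size <- RNifti::pixdim(labels_img)[1:3]
  geometry <- geometry_from_labels(as.array(labels_img), voxel_size)
  schedule <- readr::read_tsv(file.path(dir, "events.tsv"), show_col_types = FALSE)
  schedule$block <- cumsum(c(TRUE, diff(schedule$onset) > 1 |
                               schedule$trial_type[-1] != schedule$trial_type[-nrow(schedule)]))
  runs <- purrr::pmap(manifest, function(subject, session, bold, motion) {
    bold_path <- file.path(dir, bold)
    motion_path <- file.path(dir, motion)
    assert_that(file.exists(bold_path),
                paste("missing BOLD file for subject", subject, "session", session))
    assert_that(file.exists(motion_path),
                paste("missing motion file for subject", subject, "session", session))
    img <- RNifti::readNifti(bold_path)
    dims <- dim(img)
    assert_that(length(dims) == 4, paste(bold, "is not a 4D image"))
    assert_that(all(dims[1:3] == geometry$shape), "run geometry does not match labels image")
    tr <- RNifti::pixdim(img)[4]
    n_volumes <- dims[4]
    assert_that(max(schedule$onset + schedule$duration) <= n_volumes * tr,
                paste("events extend beyond the run for subject", subject,
                      "session", session))
    mo <- as.matrix(utils::read.table(motion_path))
    assert_that(nrow(mo) == n_volumes, "motion series length does not match run")
    data <- t(matrix(img, prod(geometry$shape), n_volumes)[geometry$brain_idx, ,
                                                           drop = FALSE])
    structure(list(data = data, geometry = geometry, motion = mo, tr = tr,
                   n_volumes = n_volumes, subject_id = subject,
                   session_id = session),
              class = "bold_run")
  })
  list(runs = runs, geometry = geometry,
       schedule = structure(schedule,
                            n_volumes = runs[[1]]$n_volumes, tr = runs[[1]]$tr))
}
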