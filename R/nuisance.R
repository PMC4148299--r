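# mCompCor: a single pooled physiological-noise regressor formed from the
# mean series of high-temporal-SD voxels and WM/CSF voxels.

#' Per-voxel temporal standard deviation
#'
#' Sample SD (n-1 denominator) of each voxel's time series within a mask.
#'
#' @param run A [simulate_session()] run (or any `bold_run`).
#' @param mask Optional 3D logical mask; defaults to the brain mask.
#' @return Numeric vector over the run's in-brain voxels, `NA` outside the
#'   mask.
#' @export
temporal_sd_map <- function(run, mask = NULL) {
  stopifnot(inherits(run, "bold_run"))
  assert_that(nrow(run$data) >= 2, "need at least 2 volumes")
  geom <- run$geometry
  mask <- mask %||% geom$brain_mask
  keep <- mask[geom$brain_idx]
  assert_that(any(keep), "empty mask")
  out <- rep(NA_real_, ncol(run$data))
  out[keep] <- col_sds(run$data[, keep, drop = FALSE])
  out
}

#' Select the pooled mCompCor voxel set
#'
#' The union of (a) the top `fraction` of in-brain voxels by temporal SD
#' (default top 2%; ties broken by canonical voxel order) and (b) the WM/CSF
#' mask.
#'
#' @param sd_map Per-voxel SD vector from [temporal_sd_map()] (over the
#'   geometry's in-brain voxels).
#' @param geometry The [phantom_geometry()].
#' @param wm_csf_mask Optional 3D logical mask; defaults to the geometry's
#'   WM+CSF labels.
#' @param fraction Fraction of the brain selected by SD, in (0, 1).
#' @return An object of class `mcompcor_selection` with integer column
#'   positions `high_sd`, `tissue`, `pooled` (into the in-brain voxel
#'   ordering).
#' @export
select_pooled_voxels <- function(sd_map, geometry, wm_csf_mask = NULL,
                                 fraction = 0.02) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  assert_that(fraction > 0 && fraction < 1, "fraction must be in (0, 1)")
  n_brain <- length(geometry$brain_idx)
  assert_that(length(sd_map) == n_brain, "sd_map length must match in-brain voxel count")
  if (fraction * n_brain < 1) {
    warn("brain mask smaller than 1/fraction voxels; selecting 1 voxel")
  }
  m <- max(1L, ceiling(fraction * n_brain))
  ok <- which(!is.na(sd_map))
  high_sd <- ok[order(-sd_map[ok], ok)][seq_len(min(m, length(ok)))]
  wm_csf_mask <- wm_csf_mask %||% region_mask(geometry, c("white", "csf"))
  tissue <- match(which(wm_csf_mask), geometry$brain_idx)
  tissue <- tissue[!is.na(tissue)]
  structure(list(high_sd = sort(high_sd), tissue = sort(tissue),
                 pooled = sort(union(high_sd, tissue)), fraction = fraction),
            class = "mcompcor_selection")
}

#' Compute the mCompCor regressor
#'
#' Mean time series over the pooled voxel set, demeaned. The regressor is
#' deliberately not variance-normalized (its scale is absorbed by the beta).
#'
#' @param run A `bold_run`.
#' @param selection A [select_pooled_voxels()] result; defaults to selecting
#'   from this run's own SD map.
#' @return Numeric series of length `n_volumes`.
#' @export
mcompcor_regressor <- function(run, selection = NULL) {
  stopifnot(inherits(run, "bold_run"))
  selection <- selection %||%
    select_pooled_voxels(temporal_sd_map(run), run$geometry)
  assert_that(length(selection$pooled) > 0, "empty pooled voxel set")
  s <- rowMeans(run$data[, selection$pooled, drop = FALSE])
  s - mean(s)
}
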