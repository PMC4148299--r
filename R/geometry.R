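# Region label codes used throughout the phantom.
REGION_CODES <- c(background = 0L, gray = 1L, white = 2L, csf = 3L,
                  visual = 4L, amygdala = 5L)

#' Phantom geometry: voxel grid, tissue labels, and regions of interest
#'
#' Defines the spatial layout of the synthetic brain: an ellipsoidal brain
#' mask containing a central CSF compartment, a white-matter shell around it,
#' gray matter elsewhere, a posterior "visual" active region (stand-in for
#' the bilateral visual/fusiform activation cluster), and two small lateral
#' "amygdala" regions (stand-in for the anatomical amygdala mask). A sparse,
#' deterministic subset of gray-matter voxels is flagged as the
#' high-physiological-variance set.
#'
#' @param shape Integer grid dimensions (3 values). Default 20 x 20 x 12.
#' @param voxel_size Voxel edge lengths in mm (3 values).
#' @return An object of class `phantom_geometry`: `shape`, `voxel_size`,
#'   `labels` (3D integer array with the codes in `region_table()`),
#'   `brain_mask` (3D logical), `high_var` (3D logical), `brain_idx`
#'   (linear indices of in-brain voxels, the canonical voxel ordering used by
#'   all per-voxel outputs), and `affine`.
#' @export
phantom_geometry <- function(shape = c(20L, 20L, 12L), voxel_size = c(3, 3, 3)) {
  assert_that(length(shape) == 3 && all(shape >= 4), "shape must be 3 dimensions, each >= 4")
  shape <- as.integer(shape)
  idx <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]), z = seq_len(shape[3]))
  centre <- (shape + 1) / 2
  radius <- pmax((shape / 2 - 0.5) * 0.9, 1)
  nx <- (idx$x - centre[1]) / radius[1]
  ny <- (idx$y - centre[2]) / radius[2]
  nz <- (idx$z - centre[3]) / radius[3]
  s2 <- nx^2 + ny^2 + nz^2
  labels <- integer(nrow(idx))
  labels[s2 <= 1] <- REGION_CODES[["gray"]]
  labels[s2 <= 0.55^2] <- REGION_CODES[["white"]]
  labels[s2 <= 0.25^2] <- REGION_CODES[["csf"]]
  # Posterior band of gray matter -> active "visual" region.
  labels[labels == REGION_CODES[["gray"]] & ny <= -0.55] <- REGION_CODES[["visual"]]
  # Two small lateral "amygdala" regions: nearest gray voxels to fixed
  # normalized centres, guaranteed nonempty on any grid.
  for (cx in c(-0.55, 0.55)) {
    d2 <- (nx - cx)^2 + (ny - 0.17)^2 + nz^2
    gray <- which(labels == REGION_CODES[["gray"]])
    take <- gray[order(d2[gray])][seq_len(min(8, length(gray)))]
    labels[take] <- REGION_CODES[["amygdala"]]
  }
  labels <- array(labels, dim = shape)
  brain <- labels > 0
  # Deterministic ~2% sprinkle of gray-matter voxels with heavy physiological
  # loading (the "high temporal SD" set the mCompCor pool should find).
  hv <- array(FALSE, dim = shape)
  hv_cand <- (idx$x + 2 * idx$y + 3 * idx$z) %% 47 == 0
  hv[array(hv_cand, dim = shape) & labels == REGION_CODES[["gray"]]] <- TRUE
  affine <- diag(c(voxel_size, 1))
  structure(
    list(shape = shape, voxel_size = voxel_size, labels = labels,
         brain_mask = brain, high_var = hv,
         brain_idx = which(brain), affine = affine),
    class = "phantom_geometry"
  )
}

#' Region label lookup table
#' @return A tibble mapping region names to integer codes.
#' @export
region_table <- function() {
  tibble(region = names(REGION_CODES), code = unname(REGION_CODES))
}

# Logical 3D mask for a set of region names.
region_mask <- function(geometry, regions) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  codes <- REGION_CODES[regions]
  assert_that(!anyNA(codes), paste("unknown region:", paste(regions[is.na(codes)], collapse = ", ")))
  array(geometry$labels %in% codes, dim = geometry$shape)
}

# Positions (within the brain_idx ordering) of voxels of given regions.
region_cols <- function(geometry, regions) {
  m <- region_mask(geometry, regions)
  match(which(m), geometry$brain_idx)
}

# Map a per-brain-voxel vector back to a 3D array (NA outside the brain).
brain_vec_to_array <- function(geometry, values, fill = NA_real_) {
  out <- array(fill, dim = geometry$shape)
  out[geometry$brain_idx] <- values
  out
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat("<phantom_geometry> ", paste(x$shape, collapse = " x "),
      " voxels (", sum(x$brain_mask), " in brain)\n", sep = "")
  counts <- table(factor(x$labels[x$brain_mask],
                         levels = REGION_CODES[-1], labels = names(REGION_CODES)[-1]))
  for (nm in names(counts)) cat("  ", nm, ": ", counts[[nm]], "\n", sep = "")
  invisible(x)
}
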