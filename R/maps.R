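# Statistic-map thresholding, connected-component cluster labeling, and
# cross-pipeline overlap masks.

#' Threshold a t-map and label suprathreshold clusters
#'
#' Voxelwise threshold at the upper t quantile for `voxel_p` (one-sided,
#' activation), connected-component labeling (face/6-neighbor connectivity
#' by default), and removal of components smaller than `min_extent` voxels.
#'
#' @param t_map 3D array of t-values (`NA`/`-Inf` outside the mask is fine).
#' @param df Error degrees of freedom of the t-values.
#' @param voxel_p Cluster-forming voxel threshold (default 0.001).
#' @param min_extent Minimum cluster extent in voxels (default 5).
#' @param connectivity 6 (faces), 18, or 26.
#' @return A list of class `cluster_result`: `mask` (3D logical of surviving
#'   voxels), `labels` (3D integer, 0 = background), `clusters` tibble
#'   (`label`, `n_voxels`, `peak_t`, `peak_x/y/z`, 0-based coordinates),
#'   `threshold`.
#' @export
threshold_clusters <- function(t_map, df, voxel_p = 0.001, min_extent = 5,
                               connectivity = 6) {
  assert_that(df > 0, "df must be positive")
  assert_that(min_extent > 0, "min_extent must be positive")
  assert_that(length(dim(t_map)) == 3, "t_map must be a 3D array")
  u <- qt(1 - voxel_p, df)
  supra <- !is.na(t_map) & t_map > u
  labels <- label_components(supra, connectivity)
  keep_tab <- table(labels[labels > 0])
  keep <- as.integer(names(keep_tab)[keep_tab >= min_extent])
  relabel <- integer(max(labels, 1))
  relabel[keep] <- seq_along(keep)
  out_labels <- array(0L, dim(t_map))
  pos <- labels > 0
  out_labels[pos] <- relabel[labels[pos]]
  clusters <- purrr::map_dfr(seq_along(keep), function(i) {
    idx <- which(out_labels == i)
    peak <- idx[which.max(t_map[idx])]
    co <- arrayInd(peak, dim(t_map)) - 1L
    tibble(label = i, n_voxels = length(idx), peak_t = max(t_map[idx]),
           peak_x = co[1], peak_y = co[2], peak_z = co[3])
  })
  if (nrow(clusters) > 0) clusters <- dplyr::arrange(clusters, dplyr::desc(.data$n_voxels))
  structure(list(mask = out_labels > 0, labels = out_labels,
                 clusters = clusters, threshold = u,
                 connectivity = connectivity, voxel_p = voxel_p,
                 min_extent = min_extent),
            class = "cluster_result")
}

# Neighbor offsets for the requested connectivity.
connectivity_offsets <- function(connectivity = 6) {
  assert_that(connectivity %in% c(6, 18, 26), "connectivity must be 6, 18 or 26")
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  dist <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = dist == 1,
                 "18" = dist >= 1 & rowSums(off != 0) <= 2,
                 "26" = dist >= 1)
  off[keep, , drop = FALSE]
}

# Connected components of a 3D logical array (iterative BFS).
label_components <- function(mask, connectivity = 6) {
  dims <- dim(mask)
  off <- connectivity_offsets(connectivity)
  labels <- array(0L, dims)
  nxt <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    labels[start] <- nxt
    while (length(queue) > 0) {
      cur <- queue
      queue <- integer()
      co <- arrayInd(cur, dims)
      for (o in seq_len(nrow(off))) {
        nb <- sweep(co, 2, off[o, ], "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
        if (!any(ok)) next
        lin <- nb[ok, 1] + (nb[ok, 2] - 1) * dims[1] +
          (nb[ok, 3] - 1) * dims[1] * dims[2]
        new <- lin[mask[lin] & labels[lin] == 0L]
        if (length(new) > 0) {
          labels[new] <- nxt
          queue <- c(queue, unique(new))
        }
      }
    }
  }
  labels
}

#' Intersection mask across pipelines
#'
#' Voxelwise intersection of suprathreshold masks, the common ROI in which
#' pipelines are compared.
#'
#' @param masks List of 3D logical arrays (identical geometry), e.g. the
#'   `mask` elements of [threshold_clusters()] results.
#' @return 3D logical array with attribute `provenance = "overlap"`.
#' @export
overlap_mask <- function(masks) {
  assert_that(length(masks) >= 1, "need at least one mask")
  dims <- lapply(masks, dim)
  assert_that(all(purrr::map_lgl(dims, identical, dims[[1]])),
              "masks have mismatched geometry")
  out <- Reduce(`&`, masks)
  if (!any(out)) {
    counts <- purrr::map_int(masks, ~ sum(.x))
    abort(paste0("empty overlap; per-pipeline suprathreshold counts: ",
                 paste(counts, collapse = ", ")))
  }
  attr(out, "provenance") <- "overlap"
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", nrow(x$clusters), " cluster(s), ",
      sum(x$mask), " voxels above t = ", signif(x$threshold, 4),
      " (", x$connectivity, "-connectivity, extent >= ", x$min_extent, ")\n", sep = "")
  if (nrow(x$clusters) > 0) print(x$clusters)
  invisible(x)
}
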