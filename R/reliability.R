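# ICC(3,1) test-retest reliability: two-way ANOVA (subjects random, sessions
# fixed), voxelwise maps, median-voxel region summaries, and the Cicchetti
# qualitative categories.

#' Two-way ANOVA decomposition for a subjects x sessions table
#'
#' One observation per cell; sums of squares partition the total exactly.
#'
#' @param values Numeric matrix, subjects in rows, sessions in columns.
#' @return An object of class `icc_anova` with mean squares `BMS` (between
#'   subjects), `WMS` (within subjects), `SMS` (between sessions), `EMS`
#'   (residual), their degrees of freedom, `n`, and `k`.
#' @export
two_way_anova <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  assert_that(n >= 2, "need at least 2 subjects")
  assert_that(k >= 2, "need at least 2 sessions")
  assert_that(!anyNA(values), "missing cells are not supported")
  gm <- mean(values)
  row_m <- rowMeans(values); col_m <- colMeans(values)
  ss_subj <- k * sum((row_m - gm)^2)
  ss_sess <- n * sum((col_m - gm)^2)
  ss_tot <- sum((values - gm)^2)
  ss_err <- ss_tot - ss_subj - ss_sess
  structure(
    list(BMS = ss_subj / (n - 1),
         WMS = (ss_sess + ss_err) / (n * (k - 1)),
         SMS = ss_sess / (k - 1),
         EMS = ss_err / ((n - 1) * (k - 1)),
         df = c(subjects = n - 1, within = n * (k - 1),
                sessions = k - 1, error = (n - 1) * (k - 1)),
         n = n, k = k),
    class = "icc_anova"
  )
}

#' ICC(3,1): consistency intraclass correlation
#'
#' `(BMS - EMS) / (BMS + (k - 1) * EMS)` from the two-way table with
#' subjects random and sessions fixed. Measures consistency (rank ordering)
#' across sessions, not absolute agreement; negative estimates are retained.
#'
#' @param x A subjects x sessions matrix or a [two_way_anova()] result.
#' @return ICC value in `[-1, 1]` for k = 2; `NA` when the denominator is 0.
#' @export
icc31 <- function(x) {
  tab <- if (inherits(x, "icc_anova")) x else two_way_anova(x)
  denom <- tab$BMS + (tab$k - 1) * tab$EMS
  if (denom <= 0) return(NA_real_)
  (tab$BMS - tab$EMS) / denom
}

#' Voxelwise ICC(3,1) map from two-session contrast maps
#'
#' @param contrasts_t1,contrasts_t2 Subjects x voxels matrices of per-voxel
#'   contrast estimates, rownames = subject identifiers. Subjects are
#'   matched by identity: the rowname vectors must be identical.
#' @param geometry Optional [phantom_geometry()] carried for plotting/IO.
#' @return An object of class `icc_map`: `icc` (per-voxel vector),
#'   `n_subjects`, `n_undefined`, `geometry`.
#' @export
icc_map <- function(contrasts_t1, contrasts_t2, geometry = NULL) {
  m1 <- as.matrix(contrasts_t1); m2 <- as.matrix(contrasts_t2)
  assert_that(all(dim(m1) == dim(m2)), "session maps must share dimensions")
  assert_that(!is.null(rownames(m1)) && !is.null(rownames(m2)),
              "subject identifiers (rownames) are required in both sessions")
  assert_that(identical(rownames(m1), rownames(m2)),
              "subject identifiers differ between sessions (order or membership)")
  n <- nrow(m1)
  assert_that(n >= 2, "need at least 2 subjects")
  # Vectorized two-way ANOVA over voxels, k = 2 sessions.
  gm <- (colMeans(m1) + colMeans(m2)) / 2
  row_m <- (m1 + m2) / 2
  ss_subj <- 2 * colSums(sweep(row_m, 2, gm)^2)
  ss_sess <- n * ((colMeans(m1) - gm)^2 + (colMeans(m2) - gm)^2)
  ss_tot <- colSums(sweep(m1, 2, gm)^2) + colSums(sweep(m2, 2, gm)^2)
  ss_err <- pmax(ss_tot - ss_subj - ss_sess, 0)
  bms <- ss_subj / (n - 1)
  ems <- ss_err / (n - 1)
  denom <- bms + ems
  icc <- ifelse(denom > 0, (bms - ems) / denom, NA_real_)
  structure(
    list(icc = icc, n_subjects = n, n_undefined = sum(is.na(icc)),
         geometry = geometry),
    class = "icc_map"
  )
}

#' Median voxelwise ICC in a region
#'
#' The region's reliability summary: the median of the defined voxelwise ICC
#' estimates inside the ROI (midpoint convention for even counts). Voxels
#' with undefined ICC are excluded and counted.
#'
#' @param map An [icc_map()] result.
#' @param roi Integer voxel positions (into the map's voxel ordering) or a
#'   logical vector.
#' @return The median ICC (scalar), with attribute `n_voxels` (defined
#'   voxels used).
#' @export
mvicc <- function(map, roi) {
  stopifnot(inherits(map, "icc_map"))
  vals <- map$icc[roi]
  assert_that(length(vals) > 0, "empty ROI")
  n_na <- sum(is.na(vals))
  if (n_na > 0) inform(paste("mvicc: excluding", n_na, "voxel(s) with undefined ICC"))
  vals <- vals[!is.na(vals)]
  assert_that(length(vals) > 0, "no defined ICC values in ROI")
  structure(median(vals), n_voxels = length(vals))
}

#' Cicchetti qualitative reliability category
#'
#' Poor (ICC < 0.40), Fair (0.40 <= ICC < 0.60), Good (0.60 <= ICC < 0.75),
#' Excellent (ICC >= 0.75); negative estimates are Poor.
#'
#' @param icc Numeric vector of ICC values.
#' @return Factor with levels Poor, Fair, Good, Excellent.
#' @export
cicchetti_category <- function(icc) {
  cut(icc, breaks = c(-Inf, 0.40, 0.60, 0.75, Inf),
      labels = c("Poor", "Fair", "Good", "Excellent"), right = FALSE)
}

#' Subject-level bootstrap standard error of an mvICC
#'
#' Resamples subjects with replacement and recomputes the region median ICC.
#' Provided as a labeled bootstrap SE (the analytic sampling distribution of
#' a median of correlated voxelwise ICCs is intractable).
#'
#' @param contrasts_t1,contrasts_t2 As in [icc_map()].
#' @param roi ROI voxel positions.
#' @param n_boot Number of bootstrap replicates.
#' @param seed RNG seed.
#' @return Bootstrap standard error (scalar).
#' @export
mvicc_bootstrap_se <- function(contrasts_t1, contrasts_t2, roi,
                               n_boot = 200, seed = 1) {
  m1 <- as.matrix(contrasts_t1); m2 <- as.matrix(contrasts_t2)
  n <- nrow(m1)
  reps <- with_seed(seed, {
    replicate(n_boot, {
      idx <- sample.int(n, replace = TRUE)
      b1 <- m1[idx, , drop = FALSE]; b2 <- m2[idx, , drop = FALSE]
      rownames(b1) <- rownames(b2) <- seq_len(n)
      as.numeric(mvicc(icc_map(b1, b2), roi))
    })
  })
  sd(reps)
}

#' @export
print.icc_map <- function(x, ...) {
  cat("<icc_map> ", length(x$icc), " voxels, ", x$n_subjects, " subjects",
      if (x$n_undefined > 0) paste0(" (", x$n_undefined, " undefined)"), "\n", sep = "")
  invisible(x)
}

#' Tidy a voxelwise ICC map
#' @param x An `icc_map`.
#' @param ... Unused.
#' @return A tibble with `voxel`, `icc`, `category` (and voxel coordinates
#'   when the map carries a geometry).
#' @method tidy icc_map
#' @export
tidy.icc_map <- function(x, ...) {
  out <- tibble(voxel = seq_along(x$icc), icc = x$icc,
                category = cicchetti_category(x$icc))
  if (!is.null(x$geometry)) {
    coords <- arrayInd(x$geometry$brain_idx, x$geometry$shape)
    out$x <- coords[, 1]; out$y <- coords[, 2]; out$z <- coords[, 3]
  }
  out
}

#' One-row ICC map summary
#' @param x An `icc_map`.
#' @param ... Unused.
#' @return A tibble with `n_voxels`, `n_subjects`, `median_icc`.
#' @method glance icc_map
#' @export
glance.icc_map <- function(x, ...) {
  tibble(n_voxels = length(x$icc), n_subjects = x$n_subjects,
         median_icc = median(x$icc, na.rm = TRUE))
}
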