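# Nonparametric pipeline comparison: Friedman omnibus test over matched
# blocks (voxels or subjects) and Nemenyi all-pairs post-hoc tests.

#' Friedman rank test for matched treatments
#'
#' Within-block average ranks; the chi-square statistic
#' `12/(n k (k+1)) * sum_j (R_j - n(k+1)/2)^2`, divided by the standard tie
#' correction `1 - sum(t^3 - t) / (n k (k^2 - 1))`; df = k - 1.
#'
#' @param values Blocks x treatments numeric matrix (no missing cells).
#' @return An object of class `friedman_test`: `chi_square`, `df`,
#'   `p_value`, `mean_ranks`, `n_blocks`.
#' @export
friedman_rank_test <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  assert_that(k >= 2, "need at least 2 treatments")
  assert_that(n >= 2, "need at least 2 blocks")
  assert_that(!anyNA(values), "missing cells are not supported")
  ranks <- t(apply(values, 1, rank))
  r_col <- colSums(ranks)
  s <- sum((r_col - n * (k + 1) / 2)^2)
  tie_term <- sum(apply(values, 1, function(row) {
    tt <- table(row)
    sum(tt^3 - tt)
  }))
  correction <- 1 - tie_term / (n * k * (k^2 - 1))
  chi <- if (s == 0) 0 else (12 * s / (n * k * (k + 1))) / correction
  structure(
    list(chi_square = chi, df = k - 1,
         p_value = if (s == 0) 1 else pchisq(chi, k - 1, lower.tail = FALSE),
         mean_ranks = setNames(r_col / n, colnames(values)),
         n_blocks = n),
    class = "friedman_test"
  )
}

#' Nemenyi all-pairs post-hoc test
#'
#' Compares mean ranks of every treatment pair using the studentized-range
#' distribution at infinite degrees of freedom: the pair statistic is
#' `|Rbar_i - Rbar_j| / sqrt(k (k + 1) / (12 n))`, referred to the range of
#' `k` standard normals, which controls the family-wise error across all
#' pairs.
#'
#' @param values Blocks x treatments matrix (k >= 3).
#' @return An object of class `nemenyi_test`: symmetric `p_values` matrix
#'   (unit diagonal), `mean_ranks`, `critical_difference` at alpha = 0.05.
#' @export
nemenyi_test <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  assert_that(k >= 3, "post-hoc tests need at least 3 treatments")
  ranks <- t(apply(values, 1, rank))
  r_bar <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (12 * n))
  q_obs <- abs(outer(r_bar, r_bar, "-")) / se
  p <- ptukey(q_obs, nmeans = k, df = Inf, lower.tail = FALSE)
  diag(p) <- 1
  nms <- colnames(values) %||% paste0("treatment", seq_len(k))
  dimnames(p) <- list(nms, nms)
  structure(
    list(p_values = p, mean_ranks = setNames(r_bar, nms),
         critical_difference = qtukey(0.95, k, Inf) * se,
         n_blocks = n),
    class = "nemenyi_test"
  )
}

#' @export
print.friedman_test <- function(x, ...) {
  cat("Friedman chi-square = ", signif(x$chi_square, 5), ", df = ", x$df,
      ", p = ", format.pval(x$p_value), " (", x$n_blocks, " blocks)\n", sep = "")
  invisible(x)
}

#' @export
print.nemenyi_test <- function(x, ...) {
  cat("Nemenyi all-pairs p-values (", x$n_blocks, " blocks):\n", sep = "")
  print(round(x$p_values, 4))
  invisible(x)
}

#' @method glance friedman_test
#' @export
glance.friedman_test <- function(x, ...) {
  tibble(chi_square = x$chi_square, df = x$df, p_value = x$p_value,
         n_blocks = x$n_blocks)
}

#' @method tidy nemenyi_test
#' @export
tidy.nemenyi_test <- function(x, ...) {
  nms <- rownames(x$p_values)
  pairs <- which(upper.tri(x$p_values), arr.ind = TRUE)
  tibble(treatment1 = nms[pairs[, 1]], treatment2 = nms[pairs[, 2]],
         rank_difference = x$mean_ranks[pairs[, 2]] - x$mean_ranks[pairs[, 1]],
         p_value = x$p_values[pairs])
}

#' Compare pipelines on matched per-voxel or per-subject statistics
#'
#' Builds the matched blocks x pipelines matrix (voxel-blocked for t or ICC
#' statistics; subject-blocked for violation proportions), runs the Friedman
#' omnibus test and, when more than two pipelines are present, Nemenyi
#' post-hoc tests.
#'
#' @param stats A named list (one element per pipeline) of equal-length
#'   numeric vectors (matched blocks), or a blocks x pipelines matrix.
#' @param stat_kind Label for what is being compared (`"t_value"`, `"icc"`,
#'   `"violation_proportion"`, ...).
#' @param block_kind Label for the blocking unit (`"voxel"` or `"subject"`).
#' @return An object of class `pipeline_comparison`: `friedman`, `nemenyi`
#'   (or NULL for k = 2), `summary` tibble with mean ranks (higher rank =
#'   larger statistic).
#' @export
compare_pipelines <- function(stats, stat_kind = "t_value", block_kind = "voxel") {
  m <- if (is.matrix(stats)) stats else {
    lens <- lengths(stats)
    assert_that(length(unique(lens)) == 1,
                "pipelines supply different numbers of blocks (geometry mismatch)")
    do.call(cbind, stats)
  }
  fr <- friedman_rank_test(m)
  nem <- if (ncol(m) >= 3) nemenyi_test(m) else NULL
  summary <- tibble(pipeline = names(fr$mean_ranks) %||% paste0("p", seq_len(ncol(m))),
                    mean_rank = unname(fr$mean_ranks),
                    mean_value = colMeans(m)) |>
    dplyr::arrange(dplyr::desc(.data$mean_rank))
  structure(list(friedman = fr, nemenyi = nem, summary = summary,
                 stat_kind = stat_kind, block_kind = block_kind),
            class = "pipeline_comparison")
}

#' @export
print.pipeline_comparison <- function(x, ...) {
  cat("Pipeline comparison on ", x$stat_kind, " (blocks: ", x$block_kind, ")\n", sep = "")
  print(x$friedman)
  print(x$summary)
  if (!is.null(x$nemenyi)) print(x$nemenyi)
  invisible(x)
}

#' @method glance pipeline_comparison
#' @export
glance.pipeline_comparison <- function(x, ...) {
  glance(x$friedman) |>
    dplyr::mutate(stat_kind = x$stat_kind, block_kind = x$block_kind)
}
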