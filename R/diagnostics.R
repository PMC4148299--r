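# Residual assumption tests: normality (Shapiro-Wilk), homoscedasticity
# (Breusch-Pagan), independence (Durbin-Watson), applied per voxel to the
# whitened residuals of a fitted model, plus violation-proportion summaries.

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard Royston implementation with the guards
#' the voxelwise pipeline needs (3 <= n <= 5000, nonconstant input).
#'
#' @param residuals Numeric vector.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(residuals) {
  n <- length(residuals)
  assert_that(n >= 3 && n <= 5000, "Shapiro-Wilk requires 3 <= n <= 5000")
  assert_that(sd(residuals) > 0, "constant residuals: normality test undefined")
  st <- shapiro.test(residuals)
  list(W = unname(st$statistic), p = st$p.value)
}

#' Breusch-Pagan homoscedasticity test
#'
#' Lagrange-multiplier form: regress squared residuals on the design (with a
#' genuine intercept); `LM = n * R^2` is referred to a chi-square with
#' degrees of freedom equal to the non-intercept column count. Constant
#' squared residuals give `LM = 0`, `p = 1`.
#'
#' @param residuals Numeric vector.
#' @param design Matrix (or `design_matrix`) with rows matching
#'   `residuals`. An intercept column is replaced by/combined into a true
#'   constant for the auxiliary regression.
#' @return List with `LM`, `df`, and `p`.
#' @export
breusch_pagan <- function(residuals, design) {
  x <- if (inherits(design, "design_matrix")) design$values else as.matrix(design)
  assert_that(nrow(x) == length(residuals), "design rows must equal residual length")
  aux <- bp_aux_design(x)
  qa <- qr(aux)
  assert_that(qa$rank == ncol(aux), "rank-deficient auxiliary design")
  e2 <- residuals^2
  tss <- sum((e2 - mean(e2))^2)
  if (tss == 0) return(list(LM = 0, df = ncol(aux) - 1L, p = 1))
  rss <- sum(qr.resid(qa, e2)^2)
  r2 <- 1 - rss / tss
  lm_stat <- length(e2) * r2
  df <- ncol(aux) - 1L
  list(LM = lm_stat, df = df, p = pchisq(lm_stat, df, lower.tail = FALSE))
}

# Auxiliary design: constant + non-intercept columns. Detects an intercept
# label when present, otherwise drops any constant column.
bp_aux_design <- function(x) {
  labs <- colnames(x) %||% rep("", ncol(x))
  keep <- labs != "intercept" & apply(x, 2, function(v) sd(v) > 0)
  cbind(`(aux intercept)` = 1, x[, keep, drop = FALSE])
}

#' Durbin-Watson independence test
#'
#' `d = sum(diff(e)^2) / sum(e^2)`, with a two-sided p-value from the normal
#' approximation. When the design is supplied the approximation uses the
#' exact null mean and variance of `d` given the design (computed from the
#' residual projection matrix); otherwise it falls back to `N(2, 4/n)`.
#'
#' @param residuals Numeric vector, `n >= 3`, nonconstant.
#' @param design Optional design matrix (or `design_matrix`) the residuals
#'   came from.
#' @param moments Optional precomputed result of [dw_null_moments()] (saves
#'   recomputation across voxels).
#' @return List with `d` and `p`.
#' @export
durbin_watson <- function(residuals, design = NULL, moments = NULL) {
  n <- length(residuals)
  assert_that(n >= 3, "Durbin-Watson requires n >= 3")
  denom <- sum(residuals^2)
  assert_that(denom > 0, "all-zero residuals: d undefined")
  d <- sum(diff(residuals)^2) / denom
  if (is.null(moments)) {
    moments <- if (is.null(design)) list(mean = 2, var = 4 / n) else dw_null_moments(design)
  }
  z <- (d - moments$mean) / sqrt(moments$var)
  list(d = d, p = 2 * pnorm(-abs(z)))
}

#' Exact null moments of the Durbin-Watson statistic for a design
#'
#' For residuals `e = M u` with `M` the residual projection of the design and
#' iid normal `u`, `d = e'Ae / e'e` has mean `tr(AM)/(n-k)` and variance
#' `2[tr((AM)^2) - tr(AM) * mean] / ((n-k)(n-k+2))`.
#'
#' @param design Matrix or `design_matrix`.
#' @return List with `mean` and `var`.
#' @export
dw_null_moments <- function(design) {
  x <- if (inherits(design, "design_matrix")) design$values else as.matrix(design)
  n <- nrow(x)
  qx <- qr(x)
  k <- qx$rank
  # A = D'D for the first-difference matrix D; AM computed without forming A
  # explicitly on both sides: AM = A - A H with H the hat matrix.
  h <- x %*% chol2inv(chol(crossprod(x))) %*% t(x)
  a_mult <- function(m) { # A %*% m for the DW tridiagonal A
    up <- rbind(m[-1, , drop = FALSE], 0)
    dn <- rbind(0, m[-n, , drop = FALSE])
    main <- m * c(1, rep(2, n - 2), 1)
    main - up - dn
  }
  am <- a_mult(diag(n) - h)
  p1 <- sum(diag(am))
  p2 <- sum(am * t(am))
  mean_d <- p1 / (n - k)
  var_d <- 2 * (p2 - p1 * mean_d) / ((n - k) * (n - k + 2))
  list(mean = mean_d, var = var_d)
}

#' Voxelwise residual diagnostics for a fitted model
#'
#' Runs the three assumption tests on each voxel's (whitened) residual
#' series: Shapiro-Wilk normality, Breusch-Pagan homoscedasticity against
#' the whitened design, and Durbin-Watson independence with design-corrected
#' null moments.
#'
#' @param fit A [fit_voxelwise()] result.
#' @param voxels Optional integer positions (into the fit's voxel columns)
#'   to test; default all.
#' @param alpha Significance level for violation flags.
#' @param pipeline Optional pipeline name recorded in the report.
#' @return A `diagnostic_report` tibble: one row per voxel with the three
#'   p-values and violation flags; attributes `alpha`, `pipeline`,
#'   `subject_id`, `session_id`.
#' @export
diagnose_fit <- function(fit, voxels = NULL, alpha = 0.05,
                         pipeline = fit$design$spec$name) {
  stopifnot(inherits(fit, "bold_glm"))
  voxels <- voxels %||% seq_along(fit$contrast_value)
  e <- fit$residuals[, voxels, drop = FALSE]
  n <- nrow(e)
  xw <- fit$whitened_design
  colnames(xw) <- fit$design$labels

  p_norm <- apply(e, 2, function(v) shapiro.test(v)$p.value)

  # Breusch-Pagan, vectorized: one auxiliary regression of all e^2 columns.
  aux <- bp_aux_design(xw)
  qa <- qr(aux)
  assert_that(qa$rank == ncol(aux), "rank-deficient auxiliary design")
  e2 <- e^2
  tss <- colSums(sweep(e2, 2, colMeans(e2))^2)
  rss <- colSums(qr.resid(qa, e2)^2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, 0)
  lm_stat <- n * r2
  bp_df <- ncol(aux) - 1L
  p_homo <- pchisq(lm_stat, bp_df, lower.tail = FALSE)

  # Durbin-Watson, vectorized with shared design moments.
  mom <- dw_null_moments(xw)
  d <- colSums(diff(e)^2) / colSums(e^2)
  p_indep <- 2 * pnorm(-abs((d - mom$mean) / sqrt(mom$var)))

  rep <- tibble(
    voxel = voxels,
    p_normality = p_norm,
    p_homoscedasticity = p_homo,
    p_independence = p_indep,
    violated_normality = p_norm < alpha,
    violated_homoscedasticity = p_homo < alpha,
    violated_independence = p_indep < alpha
  )
  attr(rep, "alpha") <- alpha
  attr(rep, "pipeline") <- pipeline
  attr(rep, "subject_id") <- fit$subject_id
  attr(rep, "session_id") <- fit$session_id
  class(rep) <- c("diagnostic_report", class(rep))
  rep
}

#' Summarize assumption violations across fits
#'
#' Pools diagnostic reports over subjects, sessions, and voxels and returns
#' the fraction of fits whose assumption test rejected, per pipeline and
#' assumption (the Table-1-style summary). The denominator for each
#' pipeline is `n_subjects x n_sessions x n_voxels`.
#'
#' @param reports A list of `diagnostic_report` objects (or one tibble that
#'   already has `pipeline`, `subject_id`, `session_id` columns).
#' @return A tibble with `pipeline`, `assumption`, `n_models`, `proportion`.
#' @export
summarize_violations <- function(reports) {
  if (inherits(reports, "data.frame")) reports <- list(reports)
  alphas <- unique(purrr::map_dbl(reports, ~ attr(.x, "alpha") %||% NA_real_))
  assert_that(length(alphas[!is.na(alphas)]) <= 1,
              "reports were flagged at different alpha levels")
  combined <- purrr::map_dfr(reports, function(r) {
    dplyr::mutate(as_tibble(r),
                  pipeline = attr(r, "pipeline") %||% "unknown",
                  subject_id = attr(r, "subject_id") %||% NA_integer_,
                  session_id = attr(r, "session_id") %||% NA_integer_)
  })
  combined |>
    tidyr::pivot_longer(dplyr::starts_with("violated_"),
                        names_to = "assumption", values_to = "violated",
                        names_prefix = "violated_") |>
    dplyr::group_by(.data$pipeline, .data$assumption) |>
    dplyr::summarise(n_models = dplyr::n(),
                     proportion = mean(.data$violated), .groups = "drop")
}

# Subject-level violation proportions (blocks for the Friedman comparison).
violations_by_subject <- function(reports) {
  if (inherits(reports, "data.frame")) reports <- list(reports)
  purrr::map_dfr(reports, function(r) {
    dplyr::mutate(as_tibble(r),
                  pipeline = attr(r, "pipeline") %||% "unknown",
                  subject_id = attr(r, "subject_id") %||% NA_integer_)
  }) |>
    tidyr::pivot_longer(dplyr::starts_with("violated_"),
                        names_to = "assumption", values_to = "violated",
                        names_prefix = "violated_") |>
    dplyr::group_by(.data$pipeline, .data$subject_id, .data$assumption) |>
    dplyr::summarise(proportion = mean(.data$violated), .groups = "drop")
}
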