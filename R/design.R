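#' Pipeline specification
#'
#' The four first-level modeling pipelines compared by the package:
#' `default` (canonical HRF, block model), `flexhrf` (adds temporal and
#' dispersion derivative bases, mixed block/event model), `mcompcor` (block
#' model plus the pooled physiological nuisance regressor), and `combined`
#' (both modifications).
#'
#' @param name One of `"default"`, `"flexhrf"`, `"mcompcor"`, `"combined"`,
#'   or a custom name if the flags are given explicitly.
#' @param use_derivatives Include HRF derivative bases.
#' @param use_mcompcor Include the mCompCor nuisance regressor.
#' @param event_model `"block"` or `"mixed"` (per-stimulus events).
#' @return An object of class `pipeline_spec`.
#' @export
pipeline_spec <- function(name = c("default", "flexhrf", "mcompcor", "combined"),
                          use_derivatives = NULL, use_mcompcor = NULL,
                          event_model = NULL) {
  if (is.null(use_derivatives) && is.null(use_mcompcor) && is.null(event_model)) {
    name <- match.arg(name)
    presets <- list(
      default  = list(FALSE, FALSE, "block"),
      flexhrf  = list(TRUE, FALSE, "mixed"),
      mcompcor = list(FALSE, TRUE, "block"),
      combined = list(TRUE, TRUE, "mixed")
    )
    p <- presets[[name]]
    use_derivatives <- p[[1]]; use_mcompcor <- p[[2]]; event_model <- p[[3]]
  }
  event_model <- match.arg(event_model, c("block", "mixed"))
  assert_that(!use_derivatives || event_model == "mixed",
              "derivative bases require the mixed block/event model")
  structure(list(name = name, use_derivatives = use_derivatives,
                 use_mcompcor = use_mcompcor, event_model = event_model),
            class = "pipeline_spec")
}

#' The four study pipelines
#' @return A named list of [pipeline_spec()] objects.
#' @export
study_pipelines <- function() {
  nms <- c("default", "flexhrf", "mcompcor", "combined")
  setNames(lapply(nms, pipeline_spec), nms)
}

# Convolve a set of (onset, duration) intervals with a kernel at microtime
# resolution, then sample at mid-volume times. Overlapping intervals add, so
# the regressor is linear in the schedule.
convolve_intervals <- function(onsets, durations, n_volumes, tr, kernel_values, dt) {
  span <- n_volumes * tr
  m <- ceiling(span / dt) + 1
  tt <- (seq_len(m) - 1) * dt
  u <- numeric(m)
  for (i in seq_along(onsets)) {
    cover <- tt >= onsets[i] & tt < onsets[i] + durations[i]
    u[cover] <- u[cover] + 1
  }
  full <- convolve(u, rev(kernel_values), type = "open")[seq_len(m)] * dt
  vol_t <- (seq_len(n_volumes) - 0.5) * tr
  full[pmin(round(vol_t / dt) + 1, m)]
}

# Per-condition convolved regressors (time x condition matrix).
condition_regressors <- function(schedule, n_volumes, tr, params = hrf_params(dt = tr / 16),
                                 kernel = NULL, event_model = "block") {
  kernel <- kernel %||% canonical_hrf(params)$values
  events <- if (event_model == "block") schedule_blocks(schedule) else schedule
  conds <- unique(schedule$trial_type)
  out <- sapply(conds, function(cn) {
    rows <- events[events$trial_type == cn, ]
    convolve_intervals(rows$onset, rows$duration, n_volumes, tr, kernel, params$dt)
  })
  matrix(out, nrow = n_volumes, dimnames = list(NULL, conds))
}

#' Discrete-cosine drift basis for high-pass filtering
#'
#' Orthonormal DCT columns spanning fluctuations slower than `cutoff_s`
#' seconds; including them as regressors removes low-frequency drift. The
#' number of non-constant columns is `floor(2 * n_volumes * tr / cutoff_s) + 1`
#' (the constant is carried by the model intercept).
#'
#' @param n_volumes,tr Run length and repetition time.
#' @param cutoff_s High-pass cutoff period in seconds (default 128).
#' @return A time x K matrix with columns `drift1..driftK`.
#' @export
dct_drift_basis <- function(n_volumes, tr, cutoff_s = 128) {
  assert_that(is_count(n_volumes, 2), "n_volumes must be an integer >= 2")
  assert_that(cutoff_s > 2 * tr, "high-pass cutoff must exceed 2 * TR")
  k_max <- floor(2 * n_volumes * tr / cutoff_s) + 1
  t_idx <- seq_len(n_volumes)
  cols <- sapply(seq_len(k_max), function(k) {
    v <- cos(pi * (2 * t_idx - 1) * k / (2 * n_volumes))
    v / sqrt(sum(v^2))
  })
  colnames(cols) <- paste0("drift", seq_len(k_max))
  cols
}

#' Build the first-level design matrix for a pipeline
#'
#' Assembles task regressors (per-condition boxcars, or per-stimulus events
#' under the mixed block/event model, convolved with the canonical HRF and,
#' for flexible-HRF pipelines, with its temporal and dispersion derivative
#' kernels), six motion covariates, the optional mCompCor regressor, the DCT
#' drift basis, and an intercept.
#'
#' @param schedule Stimulus schedule from [make_paradigm()].
#' @param spec A [pipeline_spec()].
#' @param n_volumes,tr Run length and repetition time.
#' @param motion Optional time x 6 motion-parameter matrix (demeaned before
#'   entry).
#' @param mcompcor Optional mCompCor series (required iff
#'   `spec$use_mcompcor`).
#' @param hrf [hrf_params()] for the basis kernels (microtime `dt` defaults
#'   to TR/16).
#' @param highpass_cutoff High-pass cutoff in seconds.
#' @param orthogonalize_derivatives Orthogonalize each derivative column
#'   against its canonical column (off by default so betas stay
#'   interpretable; the contrast reads canonical betas either way).
#' @return An object of class `design_matrix` with `values`, `labels`,
#'   `groups`, `tr`, `highpass_cutoff`, `spec`.
#' @export
build_design <- function(schedule, spec, n_volumes, tr,
                         motion = NULL, mcompcor = NULL,
                         hrf = hrf_params(dt = tr / 16),
                         highpass_cutoff = 128,
                         orthogonalize_derivatives = FALSE) {
  stopifnot(inherits(spec, "pipeline_spec"))
  assert_that(nrow(schedule) > 0, "empty schedule")
  required <- c(EMOTION_CONDITIONS, SHAPE_CONDITION)
  missing_cond <- setdiff(required, unique(schedule$trial_type))
  assert_that(length(missing_cond) == 0,
              paste("schedule is missing condition(s):", paste(missing_cond, collapse = ", ")))
  assert_that(max(schedule$onset + schedule$duration) <= n_volumes * tr,
              "schedule extends beyond the run")
  if (spec$use_mcompcor) {
    assert_that(!is.null(mcompcor), "pipeline requires an mcompcor series")
    assert_that(length(mcompcor) == n_volumes, "mcompcor length must equal n_volumes")
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    assert_that(nrow(motion) == n_volumes, "motion series length must equal n_volumes")
  }

  canon <- condition_regressors(schedule, n_volumes, tr, hrf,
                                event_model = spec$event_model)
  conds <- colnames(canon)
  cols <- list(); labels <- character(); groups <- character()
  add <- function(x, lab, grp) {
    cols[[length(cols) + 1]] <<- x
    labels <<- c(labels, lab); groups <<- c(groups, rep(grp, length(lab)))
  }
  if (spec$use_derivatives) {
    dk <- hrf_derivatives(hrf)
    tder <- condition_regressors(schedule, n_volumes, tr, hrf,
                                 kernel = dk$temporal, event_model = spec$event_model)
    dder <- condition_regressors(schedule, n_volumes, tr, hrf,
                                 kernel = dk$dispersion, event_model = spec$event_model)
    if (orthogonalize_derivatives) {
      for (cn in conds) {
        tder[, cn] <- residualize_on(tder[, cn], canon[, cn])
        dder[, cn] <- residualize_on(dder[, cn], canon[, cn])
      }
    }
    for (cn in conds) {
      add(canon[, cn], cn, "task-canonical")
      add(tder[, cn], paste0(cn, "_tder"), "task-temporal-derivative")
      add(dder[, cn], paste0(cn, "_dder"), "task-dispersion-derivative")
    }
  } else {
    for (cn in conds) add(canon[, cn], cn, "task-canonical")
  }
  if (!is.null(motion)) {
    mo <- sweep(motion, 2, colMeans(motion))
    for (j in 1:ncol(mo)) add(mo[, j], paste0("motion", j), "motion")
  }
  if (spec$use_mcompcor) add(mcompcor - mean(mcompcor), "mcompcor", "mcompcor")
  drift <- dct_drift_basis(n_volumes, tr, highpass_cutoff)
  for (j in 1:ncol(drift)) add(drift[, j], colnames(drift)[j], "drift")
  add(rep(1, n_volumes), "intercept", "intercept")

  values <- do.call(cbind, cols)
  colnames(values) <- labels
  assert_that(!anyDuplicated(labels), "duplicate design column labels")
  zero_cols <- labels[colSums(abs(values)) == 0]
  assert_that(length(zero_cols) == 0,
              paste("all-zero design column(s):", paste(zero_cols, collapse = ", ")))
  structure(list(values = values, labels = labels, groups = groups,
                 tr = tr, highpass_cutoff = highpass_cutoff, spec = spec),
            class = "design_matrix")
}

residualize_on <- function(y, x) {
  y - x * sum(x * y) / sum(x^2)
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> ", nrow(x$values), " volumes x ", ncol(x$values),
      " regressors (pipeline '", x$spec$name, "')\n", sep = "")
  print(table(x$groups))
  invisible(x)
}

#' Contrast weight vector over design columns
#'
#' The study contrast `emotions_minus_shapes`: +1/4 on each canonical
#' emotion column, -1 on the canonical shapes column, 0 on every derivative,
#' nuisance, drift, and intercept column. Weights sum to zero.
#'
#' @param design A [build_design()] result.
#' @param contrast_name Currently only `"emotions_minus_shapes"`.
#' @return Named numeric vector of length `ncol(design$values)`.
#' @export
contrast_vector <- function(design, contrast_name = "emotions_minus_shapes") {
  stopifnot(inherits(design, "design_matrix"))
  assert_that(identical(contrast_name, "emotions_minus_shapes"),
              paste("unknown contrast:", contrast_name))
  w <- setNames(numeric(length(design$labels)), design$labels)
  needed <- c(EMOTION_CONDITIONS, SHAPE_CONDITION)
  canonical <- design$labels[design$groups == "task-canonical"]
  missing_cols <- setdiff(needed, canonical)
  assert_that(length(missing_cols) == 0,
              paste("design lacks canonical column(s):", paste(missing_cols, collapse = ", ")))
  w[EMOTION_CONDITIONS] <- 1 / 4
  w[SHAPE_CONDITION] <- -1
  w
}

#' Tidy a design matrix into long format
#' @param x A `design_matrix`.
#' @param ... Unused.
#' @return A tibble with `volume`, `time`, `regressor`, `group`, `value`.
#' @method tidy design_matrix
#' @export
tidy.design_matrix <- function(x, ...) {
  tibble(
    volume = rep(seq_len(nrow(x$values)), times = ncol(x$values)),
    time = (rep(seq_len(nrow(x$values)), times = ncol(x$values)) - 0.5) * x$tr,
    regressor = rep(x$labels, each = nrow(x$values)),
    group = rep(x$groups, each = nrow(x$values)),
    value = as.vector(x$values)
  )
}
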