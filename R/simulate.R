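# Synthetic BOLD generation: per-run simulation and cohort assembly.
# All randomness is drawn from named substreams of config$seed so that any
# run is reproducible in isolation (and cohorts can be streamed).

# ---- internal draws ---------------------------------------------------------

subject_draws <- function(config, geometry, subject_id) {
  n_active <- sum(region_mask(geometry, c("visual", "amygdala")))
  hrf <- with_seed(substream_seed(config$seed, "hrf", subject_id), {
    c(latency = rnorm(1, 0, config$hrf_latency_sd),
      log_disp = rnorm(1, 0, config$hrf_dispersion_sd))
  })
  b <- with_seed(substream_seed(config$seed, "b", subject_id),
                 rnorm(1, 0, sqrt(config$sigma2_between)))
  b_vox <- with_seed(substream_seed(config$seed, "bv", subject_id),
                     rnorm(n_active, 0, sqrt(config$sigma2_between)))
  list(hrf = hrf, b = b, b_vox = b_vox)
}

session_draws <- function(config, geometry, subject_id, session_id) {
  n_active <- sum(region_mask(geometry, c("visual", "amygdala")))
  t_n <- config$n_volumes
  w <- with_seed(substream_seed(config$seed, "w", subject_id, session_id),
                 rnorm(1, 0, sqrt(config$sigma2_within)))
  w_vox <- with_seed(substream_seed(config$seed, "wv", subject_id, session_id),
                     rnorm(n_active, 0, sqrt(config$sigma2_within)))
  confound <- with_seed(substream_seed(config$seed, "confound", subject_id, session_id),
                        band_limited_series(t_n, config$tr_seconds,
                                            config$physio_bands,
                                            config$physio_band_weights))
  motion <- with_seed(substream_seed(config$seed, "motion", subject_id, session_id),
                      apply(matrix(rnorm(t_n * 6, 0, config$motion_amplitude), t_n, 6),
                            2, cumsum))
  list(w = w, w_vox = w_vox, confound = confound, motion = motion)
}

# Unit-variance sum of band-limited Gaussian processes (Fourier masking).
band_limited_series <- function(n, tr, bands, weights) {
  freq <- seq(0, n - 1) / (n * tr)
  freq <- pmin(freq, 1 / tr - freq) # two-sided spectrum folding
  out <- numeric(n)
  for (i in seq_along(bands)) {
    z <- fft(rnorm(n))
    keep <- freq >= bands[[i]][1] & freq <= bands[[i]][2]
    z[!keep] <- 0
    comp <- Re(fft(z, inverse = TRUE)) / n
    if (sd(comp) > 0) comp <- comp / sd(comp)
    out <- out + weights[i] * comp
  }
  if (sd(out) > 0) out <- (out - mean(out)) / sd(out) else out
}

# Stationary AR(1) noise matrix (time x voxels) with marginal variance s2.
ar1_noise <- function(t_n, n_vox, rho, s2) {
  if (s2 == 0 || n_vox == 0) return(matrix(0, t_n, n_vox))
  burn <- 25L
  innov_sd <- sqrt(s2 * (1 - rho^2))
  x <- matrix(rnorm((t_n + burn) * n_vox, 0, innov_sd), t_n + burn, n_vox)
  if (rho != 0) x <- stats::filter(x, rho, method = "recursive")
  matrix(x[(burn + 1):(burn + t_n), ], t_n, n_vox)
}

# Tissue-dependent baseline image (percent units, brain only).
baseline_values <- function(geometry) {
  base <- c(gray = 100, white = 95, csf = 105, visual = 100, amygdala = 100)
  lab <- geometry$labels[geometry$brain_idx]
  unname(base[match(lab, REGION_CODES[names(base)])])
}

# Separable 3D Gaussian smoothing of one volume (array), FWHM in mm.
gaussian_smooth_3d <- function(vol, fwhm_mm, voxel_size) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    r <- max(1L, ceiling(3 * sigma[ax]))
    k <- exp(-0.5 * ((-r:r) / sigma[ax])^2)
    k <- k / sum(k)
    vol <- apply(vol, setdiff(1:3, ax), function(v) {
      as.numeric(stats::filter(c(rep(v[1], r), v, rep(v[length(v)], r)),
                               k, sides = 2))[(r + 1):(r + length(v))]
    })
    vol <- aperm(vol, order(c(ax, setdiff(1:3, ax))))
  }
  vol
}

# ---- simulation -------------------------------------------------------------

#' Simulate one subject-session BOLD run
#'
#' Generates `baseline + task signal + physiological confound + AR(1) noise`
#' on the phantom grid. Task signal is the per-condition boxcar convolved
#' with the subject's own (jittered) double-gamma HRF, scaled by the
#' subject-session contrast amplitude in the active regions. The confound is
#' a session-specific band-limited series loading on WM/CSF, the designated
#' high-variance voxels, and (more weakly) the rest of the brain. The run is
#' fully determined by `(config$seed, subject_id, session_id)`.
#'
#' @param geometry A [phantom_geometry()].
#' @param schedule A stimulus schedule from [make_paradigm()].
#' @param config A [sim_config()].
#' @param subject_id,session_id Integer identifiers (session 1 or 2).
#' @return An object of class `bold_run`: `data` (time x in-brain-voxel
#'   matrix), `geometry`, `motion` (time x 6), `tr`, ids.
#' @export
simulate_session <- function(geometry, schedule, config, subject_id, session_id) {
  stopifnot(inherits(geometry, "phantom_geometry"), inherits(config, "sim_config"))
  t_n <- config$n_volumes
  tr <- config$tr_seconds
  assert_that(max(schedule$onset + schedule$duration) <= t_n * tr,
              "schedule extends beyond the run (truncated paradigm)")
  n_brain <- length(geometry$brain_idx)

  sub <- subject_draws(config, geometry, subject_id)
  ses <- session_draws(config, geometry, subject_id, session_id)

  y <- matrix(rep(baseline_values(geometry), each = t_n), t_n, n_brain)

  # Task signal in the active regions, convolved with the subject's HRF.
  params <- hrf_params(peak_delay = max(6 + sub$hrf["latency"], 1),
                       peak_disp = exp(sub$hrf["log_disp"]),
                       dt = tr / 16)
  regs <- condition_regressors(schedule, t_n, tr, params)
  phi <- config$voxel_effect_frac
  act_cols <- list(visual = region_cols(geometry, "visual"),
                   amygdala = region_cols(geometry, "amygdala"))
  all_act <- unlist(act_cols, use.names = FALSE)
  vox_amp <- setNames(numeric(length(all_act)), NULL) # contrast amplitude per active voxel
  pos <- 0
  for (r in names(act_cols)) {
    nr <- length(act_cols[[r]])
    idx_in_act <- pos + seq_len(nr)
    mu <- config$amplitude_mean[[r]]
    vox_amp[idx_in_act] <- mu +
      sqrt(1 - phi) * (sub$b + ses$w) +
      sqrt(phi) * (sub$b_vox[idx_in_act] + ses$w_vox[idx_in_act])
    pos <- pos + nr
  }
  shape_reg <- regs[, SHAPE_CONDITION]
  emo_sum <- rowSums(regs[, EMOTION_CONDITIONS, drop = FALSE])
  all_sum <- rowSums(regs)
  # every condition carries shape_amplitude; emotions add the contrast amplitude
  y[, all_act] <- y[, all_act] +
    config$shape_amplitude * all_sum +
    outer(emo_sum, vox_amp)

  # Physiological confound.
  if (config$physio_amplitude > 0) {
    loading <- rep(config$gm_physio_loading, n_brain)
    heavy <- region_mask(geometry, c("white", "csf")) | geometry$high_var
    loading[match(which(heavy), geometry$brain_idx)] <- 1
    y <- y + outer(ses$confound * config$physio_amplitude, loading)
  }

  # Motion leak (off by default; proportional to baseline gradient magnitude).
  if (config$motion_leak > 0) {
    base_arr <- brain_vec_to_array(geometry, baseline_values(geometry), fill = 0)
    sh <- geometry$shape
    shift_diff <- function(a, ax) {
      d <- array(0, dim(a))
      if (ax == 1) d[-1, , ] <- a[-1, , ] - a[-sh[1], , ]
      if (ax == 2) d[, -1, ] <- a[, -1, ] - a[, -sh[2], ]
      if (ax == 3) d[, , -1] <- a[, , -1] - a[, , -sh[3]]
      d
    }
    g2 <- shift_diff(base_arr, 1)^2 + shift_diff(base_arr, 2)^2 +
      shift_diff(base_arr, 3)^2
    grad <- sqrt(g2)[geometry$brain_idx]
    y <- y + config$motion_leak * outer(rowSums(ses$motion), grad)
  }

  # AR(1) + white noise.
  if (config$sigma2_noise > 0) {
    noise <- with_seed(substream_seed(config$seed, "noise", subject_id, session_id),
                       ar1_noise(t_n, n_brain, config$ar1_rho, config$sigma2_noise))
    y <- y + noise
  }

  if (config$smoothing_fwhm_mm > 0) {
    for (ti in seq_len(t_n)) {
      vol <- brain_vec_to_array(geometry, y[ti, ], fill = 0)
      sm <- gaussian_smooth_3d(vol, config$smoothing_fwhm_mm, geometry$voxel_size)
      y[ti, ] <- sm[geometry$brain_idx]
    }
  }

  structure(
    list(data = y, geometry = geometry, motion = ses$motion, tr = tr,
         n_volumes = t_n, subject_id = subject_id, session_id = session_id),
    class = "bold_run"
  )
}

#' @export
print.bold_run <- function(x, ...) {
  cat("<bold_run> subject ", x$subject_id, " session ", x$session_id, ": ",
      x$n_volumes, " volumes x ", ncol(x$data), " in-brain voxels, TR ",
      x$tr, " s\n", sep = "")
  invisible(x)
}

# Ground-truth record for a cohort, derived from the same substreams the
# simulator uses.
cohort_ground_truth <- function(config, geometry) {
  phi <- config$voxel_effect_frac
  amps <- purrr::map_dfr(seq_len(config$n_subjects), function(i) {
    sub <- subject_draws(config, geometry, i)
    purrr::map_dfr(1:2, function(s) {
      ses <- session_draws(config, geometry, i, s)
      tibble(subject = i, session = s,
             region = names(config$amplitude_mean),
             amplitude = unname(config$amplitude_mean) +
               sqrt(1 - phi) * (sub$b + ses$w))
    })
  })
  hrf <- purrr::map_dfr(seq_len(config$n_subjects), function(i) {
    h <- subject_draws(config, geometry, i)$hrf
    tibble(subject = i, latency_shift = unname(h["latency"]),
           dispersion_multiplier = exp(unname(h["log_disp"])))
  })
  confounds <- sapply(seq_len(config$n_subjects), function(i) {
    sapply(1:2, function(s) session_draws(config, geometry, i, s)$confound)
  })
  confounds <- matrix(confounds, nrow = config$n_volumes)
  colnames(confounds) <- paste0("sub-", rep(seq_len(config$n_subjects), each = 2),
                                "_ses-", rep(1:2, config$n_subjects))
  list(true_icc_by_region = true_icc(config),
       subject_amplitudes = amps,
       subject_hrf_params = hrf,
       confound_series = confounds)
}

#' Simulate a full two-session cohort
#'
#' Materializes every subject-session run plus the ground-truth record. For
#' large grids prefer [run_study()], which streams runs one at a time.
#'
#' @param config A [sim_config()] (needs `n_subjects >= 2`).
#' @param geometry A [phantom_geometry()].
#' @param schedule Optional schedule; defaults to
#'   `make_paradigm(config$seed, config$n_volumes, config$tr_seconds)`.
#' @return A list with `runs` (list of [simulate_session()] results, sessions
#'   nested within subjects), `ground_truth`, `schedule`, `config`,
#'   `geometry`.
#' @export
simulate_cohort <- function(config, geometry = phantom_geometry(), schedule = NULL) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(config$n_subjects >= 2, "a cohort needs at least 2 subjects")
  schedule <- schedule %||%
    make_paradigm(config$seed, config$n_volumes, config$tr_seconds)
  runs <- list()
  for (i in seq_len(config$n_subjects)) {
    for (s in 1:2) {
      runs[[length(runs) + 1]] <- simulate_session(geometry, schedule, config, i, s)
    }
  }
  list(runs = runs, ground_truth = cohort_ground_truth(config, geometry),
       schedule = schedule, config = config, geometry = geometry)
}
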