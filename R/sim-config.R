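#' Simulation configuration for the synthetic BOLD cohort
#'
#' Parameters of the generative model. A subject's emotions-minus-shapes
#' contrast amplitude in an active region is
#' `mu_region + b_subject + w_{subject,session}` with
#' `b ~ N(0, sigma2_between)` and `w ~ N(0, sigma2_within)`, so the true
#' test-retest reliability is the analytic variance ratio
#' `sigma2_between / (sigma2_between + sigma2_within)`. A fraction
#' `voxel_effect_frac` of that amplitude variance is drawn independently per
#' voxel at the same between/within ratio (spatial amplitude heterogeneity;
#' per-voxel true ICC is unchanged). Noise is AR(1) with lag-1 correlation
#' `ar1_rho` and marginal variance `sigma2_noise`; a shared band-limited
#' physiological confound (unit variance, scaled by `physio_amplitude`) loads
#' fully on WM/CSF and the designated high-variance voxels and with weight
#' `gm_physio_loading` elsewhere in the brain. Per-subject HRF jitter shifts
#' the response latency by `N(0, hrf_latency_sd)` seconds and scales the peak
#' dispersion log-normally with `hrf_dispersion_sd`.
#'
#' All signal units are percent of a baseline of 100.
#'
#' @param n_subjects Number of subjects (each scanned in 2 sessions).
#' @param n_volumes Volumes per run.
#' @param tr_seconds Repetition time, seconds.
#' @param amplitude_mean Named mean contrast amplitude per active region
#'   (percent signal change at the event-response peak).
#' @param shape_amplitude Amplitude of the shape-control condition (all
#'   conditions share it; emotions add the subject contrast amplitude).
#' @param sigma2_between,sigma2_within Between-subject and session-to-session
#'   variance of the contrast amplitude.
#' @param voxel_effect_frac Fraction of amplitude variance that is
#'   voxel-specific (same between/within ratio).
#' @param ar1_rho Lag-1 autocorrelation of voxel noise.
#' @param sigma2_noise Marginal variance of voxel noise.
#' @param hrf_latency_sd Per-subject HRF peak-latency jitter, seconds.
#' @param hrf_dispersion_sd Per-subject log-scale HRF width jitter.
#' @param physio_amplitude Scale of the shared physiological confound.
#' @param gm_physio_loading Confound loading in brain voxels outside the
#'   WM/CSF and high-variance sets.
#' @param physio_bands List of two frequency bands (Hz) whose sum forms the
#'   confound process.
#' @param physio_band_weights Relative weight of each band.
#' @param motion_amplitude Innovation SD of the 6 simulated motion series.
#' @param motion_leak Coupling of motion into the signal (0 = covariates
#'   written but no leak), proportional to the local baseline gradient.
#' @param smoothing_fwhm_mm Optional isotropic Gaussian smoothing FWHM.
#' @param seed Integer root seed; fully determines the cohort.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 48,
                       n_volumes = 378,
                       tr_seconds = 2,
                       amplitude_mean = c(visual = 0.6, amygdala = 0.3),
                       shape_amplitude = 0.25,
                       sigma2_between = 0.045,
                       sigma2_within = 0.045,
                       voxel_effect_frac = 0.6,
                       ar1_rho = 0.3,
                       sigma2_noise = 1,
                       hrf_latency_sd = 1,
                       hrf_dispersion_sd = 0.25,
                       physio_amplitude = 5,
                       gm_physio_loading = 0.5,
                       physio_bands = list(c(0.01, 0.05), c(0.20, 0.25)),
                       physio_band_weights = c(0.8, 0.6),
                       motion_amplitude = 0.02,
                       motion_leak = 0,
                       smoothing_fwhm_mm = 0,
                       seed = 1) {
  assert_that(is_count(n_subjects, 1), "n_subjects must be a positive integer")
  assert_that(is_count(n_volumes, 2), "n_volumes must be an integer >= 2")
  assert_that(tr_seconds > 0, "tr_seconds must be positive")
  assert_that(all(c(sigma2_between, sigma2_within, sigma2_noise) >= 0),
              "variances must be nonnegative")
  assert_that(abs(ar1_rho) < 1, "|ar1_rho| must be < 1")
  assert_that(voxel_effect_frac >= 0 && voxel_effect_frac <= 1,
              "voxel_effect_frac must be in [0, 1]")
  assert_that(all(c(hrf_latency_sd, hrf_dispersion_sd, physio_amplitude,
                    motion_amplitude, smoothing_fwhm_mm) >= 0),
              "scale parameters must be nonnegative")
  assert_that(is_count(abs(seed), 0), "seed must be an integer")
  structure(
    list(n_subjects = as.integer(n_subjects), n_volumes = as.integer(n_volumes),
         tr_seconds = tr_seconds, amplitude_mean = amplitude_mean,
         shape_amplitude = shape_amplitude,
         sigma2_between = sigma2_between, sigma2_within = sigma2_within,
         voxel_effect_frac = voxel_effect_frac,
         ar1_rho = ar1_rho, sigma2_noise = sigma2_noise,
         hrf_latency_sd = hrf_latency_sd, hrf_dispersion_sd = hrf_dispersion_sd,
         physio_amplitude = physio_amplitude,
         gm_physio_loading = gm_physio_loading,
         physio_bands = physio_bands, physio_band_weights = physio_band_weights,
         motion_amplitude = motion_amplitude, motion_leak = motion_leak,
         smoothing_fwhm_mm = smoothing_fwhm_mm, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' True regional reliability implied by a configuration
#'
#' The analytic variance ratio `sigma2_between / (sigma2_between +
#' sigma2_within)`; 0 when there is no between-subject variance.
#'
#' @param config A [sim_config()] object.
#' @return Named numeric vector, one value per active region.
#' @export
true_icc <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tot <- config$sigma2_between + config$sigma2_within
  val <- if (config$sigma2_between == 0) 0 else config$sigma2_between / tot
  setNames(rep(val, length(config$amplitude_mean)), names(config$amplitude_mean))
}
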