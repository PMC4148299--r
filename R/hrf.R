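#' Hemodynamic response function parameters
#'
#' Parameters of the canonical double-gamma HRF: a positive gamma density for
#' the peak minus a scaled gamma density for the post-stimulus undershoot.
#' Defaults follow the conventional parameterization (peak at ~5 s,
#' undershoot at ~15 s, undershoot ratio 1/6).
#'
#' @param peak_delay Peak gamma delay in seconds (shape*scale of the gamma).
#' @param undershoot_delay Undershoot gamma delay in seconds.
#' @param peak_disp Dispersion (gamma scale) of the peak, seconds.
#' @param undershoot_disp Dispersion of the undershoot, seconds.
#' @param undershoot_ratio Relative amplitude of the undershoot.
#' @param kernel_length Support of the sampled kernel, seconds.
#' @param dt Microtime sampling resolution, seconds.
#' @return An object of class `hrf_params`.
#' @export
#' @examples
#' p <- hrf_params()
#' h <- canonical_hrf(p)
#' h$time[which.max(h$values)] # peak near 5 s
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_disp = 1, undershoot_disp = 1,
                       undershoot_ratio = 1 / 6,
                       kernel_length = 32, dt = 0.125) {
  assert_that(dt > 0, "hrf dt must be positive")
  assert_that(all(c(peak_delay, undershoot_delay, peak_disp, undershoot_disp) > 0),
              "hrf delays and dispersions must be positive")
  assert_that(kernel_length > 0, "kernel_length must be positive")
  structure(
    list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
         peak_disp = peak_disp, undershoot_disp = undershoot_disp,
         undershoot_ratio = undershoot_ratio,
         kernel_length = kernel_length, dt = dt),
    class = "hrf_params"
  )
}

# Unnormalized double-gamma evaluated on an arbitrary time grid.
double_gamma <- function(t, params, peak_disp = NULL) {
  pd <- peak_disp %||% params$peak_disp
  h <- dgamma(t, shape = params$peak_delay / pd, scale = pd) -
    params$undershoot_ratio *
      dgamma(t, shape = params$undershoot_delay / params$undershoot_disp,
             scale = params$undershoot_disp)
  h[t < 0] <- 0
  h
}

# Peak of the unnormalized canonical kernel, used as the common scale for the
# canonical and derivative kernels so that contrasts are unit-consistent.
canonical_peak <- function(params) {
  tt <- seq(0, params$kernel_length, by = params$dt)
  max(double_gamma(tt, params))
}

#' Canonical double-gamma HRF kernel
#'
#' Samples the canonical double-gamma kernel at the microtime resolution
#' `params$dt` over `params$kernel_length` seconds, scaled so the canonical
#' peak equals 1 (beta units only; contrasts are invariant to this scale).
#'
#' @param params An [hrf_params()] object.
#' @return A list with `time` and `values`.
#' @export
canonical_hrf <- function(params = hrf_params()) {
  stopifnot(inherits(params, "hrf_params"))
  tt <- seq(0, params$kernel_length, by = params$dt)
  h <- double_gamma(tt, params) / canonical_peak(params)
  list(time = tt, values = h)
}

#' Temporal and dispersion derivative kernels of the HRF
#'
#' Finite-difference basis functions that absorb small shifts in response
#' latency (onset shift by `delta_t`) and width (peak dispersion perturbed by
#' `delta_disp`). Both are scaled by the canonical peak so all three bases
#' share units.
#'
#' @param params An [hrf_params()] object.
#' @param delta_t Onset-shift step in seconds for the temporal derivative.
#' @param delta_disp Dispersion perturbation for the dispersion derivative.
#' @return A list with `time`, `temporal`, and `dispersion` kernels.
#' @export
hrf_derivatives <- function(params = hrf_params(), delta_t = 1, delta_disp = 0.01) {
  stopifnot(inherits(params, "hrf_params"))
  assert_that(delta_t != 0, "delta_t must be nonzero (degenerate finite difference)")
  assert_that(delta_disp != 0, "delta_disp must be nonzero (degenerate finite difference)")
  tt <- seq(0, params$kernel_length, by = params$dt)
  scale <- canonical_peak(params)
  h0 <- double_gamma(tt, params) / scale
  h_shift <- double_gamma(tt - delta_t, params) / scale
  temporal <- (h0 - h_shift) / delta_t
  h_disp <- double_gamma(tt, params, peak_disp = params$peak_disp + delta_disp) / scale
  dispersion <- (h0 - h_disp) / delta_disp
  list(time = tt, temporal = temporal, dispersion = dispersion)
}
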