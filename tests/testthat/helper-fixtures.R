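# Shared fixtures. Heavy objects are cached in a session-local environment so
# several test files can reuse one simulated run.

.fixtures <- new.env(parent = emptyenv())

cache_fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

small_geometry <- function() cache_fixture("geom_small", phantom_geometry(c(12, 12, 8)))

# A configuration with every pipeline-relevant disturbance switched off:
# white Gaussian noise, canonical HRF, no confound, no amplitude variance.
quiet_config <- function(...) {
  defaults <- list(n_subjects = 2, sigma2_between = 0, sigma2_within = 0,
                   voxel_effect_frac = 0, ar1_rho = 0, hrf_latency_sd = 0,
                   hrf_dispersion_sd = 0, physio_amplitude = 0, seed = 42)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

default_schedule <- function() cache_fixture("sched", make_paradigm(42))

# One simulated run + default-pipeline fit on the small grid (white noise,
# no confound/jitter, with task signal), reused across test files.
quiet_run <- function() {
  cache_fixture("quiet_run", {
    cfg <- sim_config(n_subjects = 2, ar1_rho = 0, hrf_latency_sd = 0,
                      hrf_dispersion_sd = 0, physio_amplitude = 0, seed = 42)
    simulate_session(small_geometry(), default_schedule(), cfg,
                     subject_id = 1, session_id = 1)
  })
}

quiet_fit <- function() {
  cache_fixture("quiet_fit", {
    run <- quiet_run()
    des <- build_design(default_schedule(), pipeline_spec("default"),
                        run$n_volumes, run$tr, motion = run$motion)
    fit_voxelwise(des, run)
  })
}

# Small design matrix for diagnostics tests.
small_design <- function() {
  cache_fixture("design_default", {
    run <- quiet_run()
    build_design(default_schedule(), pipeline_spec("default"),
                 run$n_volumes, run$tr, motion = run$motion)
  })
}

# ICC(3,1) oracle: independent route via stats::aov mean squares.
icc31_oracle <- function(values) {
  n <- nrow(values); k <- ncol(values)
  df <- data.frame(y = as.vector(values),
                   subject = factor(rep(seq_len(n), k)),
                   session = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ session + subject, data = df))[[1]]
  bms <- tab["subject", "Mean Sq"]
  ems <- tab["Residuals", "Mean Sq"]
  (bms - ems) / (bms + (k - 1) * ems)
}
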