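test_that("global AR(1) estimation is unbiased for white and AR(1) noise", {
  g <- small_geometry()
  sched <- default_schedule()
  des <- small_design()
  x <- des$values
  for (rho in c(0, 0.3)) {
    cfg <- quiet_config(amplitude_mean = c(visual = 0, amygdala = 0),
                        shape_amplitude = 0, ar1_rho = rho)
    run <- simulate_session(g, sched, cfg, 1, 1)
    resid0 <- run$data - x %*% qr.coef(qr(x), run$data)
    rho_hat <- estimate_global_ar1(resid0, x)
    expect_lt(abs(rho_hat - rho), 0.05)
  }
  expect_error(estimate_global_ar1(matrix(1, 2, 5)), "3 time points")
  expect_error(estimate_global_ar1(matrix(1, 10, 5)), "constant")
})

test_that("prewhitening is the AR(1) inverse square root transform", {
  x <- matrix(rnorm(30), 10, 3)
  y <- matrix(rnorm(20), 10, 2)
  # rho = 0 is the identity
  w0 <- prewhiten(x, y, 0)
  expect_identical(w0$design, x)
  expect_identical(w0$data, y)
  # whitening true AR(1) noise kills the lag-1 autocorrelation
  nser <- boldicc:::ar1_noise(400, 200, 0.5, 1)
  ww <- withr::with_seed(1, prewhiten(matrix(1, 400, 1), nser, 0.5))
  expect_lt(abs(boldicc:::pooled_lag1(ww$data)), 0.03)
  # the transform is not an involution: rho then -rho is not the identity
  v <- matrix(c(1, 2, 3))
  back <- prewhiten(v, v, -0.4)$data
  there <- prewhiten(back, back, 0.4)$data
  expect_false(isTRUE(all.equal(v, there)))
  expect_error(prewhiten(x, y, 1), "rho")
})

test_that("noise-free task data is recovered exactly", {
  g <- small_geometry()
  sched <- default_schedule()
  cfg <- quiet_config(sigma2_noise = 0)
  run <- simulate_session(g, sched, cfg, 1, 1)
  des <- build_design(sched, pipeline_spec("default"), run$n_volumes, run$tr,
                      motion = run$motion)
  fit <- fit_voxelwise(des, run, prewhiten = FALSE)
  vis <- boldicc:::region_cols(g, "visual")
  expect_equal(fit$contrast_value[vis],
               rep(cfg$amplitude_mean[["visual"]], length(vis)),
               tolerance = 1e-8)
  amy <- boldicc:::region_cols(g, "amygdala")
  expect_equal(fit$contrast_value[amy],
               rep(cfg$amplitude_mean[["amygdala"]], length(amy)),
               tolerance = 1e-8)
  outside <- setdiff(seq_along(fit$contrast_value), c(vis, amy))
  expect_lt(max(abs(fit$contrast_value[outside])), 1e-8)
})

test_that("rank-deficient designs are reported with the collinear columns", {
  run <- quiet_run()
  des <- small_design()
  des2 <- des
  des2$values <- cbind(des$values, des$values[, "anger"])
  des2$labels <- c(des$labels, "anger_copy")
  des2$groups <- c(des$groups, "task-canonical")
  colnames(des2$values) <- des2$labels
  expect_error(fit_voxelwise(des2, run$data,
                             contrast = c(contrast_vector(des), 0)),
               "anger_copy|collinear")
})

test_that("whitened residuals are orthogonal to the whitened design", {
  fit <- quiet_fit()
  x <- fit$whitened_design
  e <- fit$residuals
  xe <- abs(crossprod(x, e))
  bound <- norm(x, "F") * sqrt(colSums(e^2))
  expect_lt(max(sweep(xe, 2, bound, "/")), 1e-8)
  expect_equal(fit$df_error, nrow(x) - ncol(x))
  expect_true(all(fit$sigma2 >= 0))
})

test_that("the GLS path at rho = 0 equals ordinary least squares bit for bit", {
  run <- quiet_run()
  des <- small_design()
  f1 <- fit_voxelwise(des, run$data, contrast_vector(des), prewhiten = FALSE)
  beta_ols <- qr.coef(qr(des$values), run$data)
  expect_identical(f1$rho_hat, 0)
  expect_identical(drop(crossprod(contrast_vector(des), beta_ols)),
                   f1$contrast_value)
})

test_that("lower noise strictly increases in-ROI |t|", {
  g <- small_geometry()
  sched <- default_schedule()
  vis <- boldicc:::region_cols(g, "visual")
  med_t <- sapply(c(1, 0.25), function(s2) {
    cfg <- quiet_config(sigma2_noise = s2, sigma2_between = 0.045,
                        sigma2_within = 0.045, seed = 8)
    run <- simulate_session(g, sched, cfg, 1, 1)
    des <- build_design(sched, pipeline_spec("default"), run$n_volumes,
                        run$tr, motion = run$motion)
    median(abs(fit_voxelwise(des, run)$t_value[vis]))
  })
  expect_gt(med_t[2], med_t[1])
})

test_that("contrast estimates are unbiased over a noisy cohort", {
  g <- phantom_geometry(c(10, 10, 6))
  cfg <- sim_config(n_subjects = 6, voxel_effect_frac = 0, sigma2_within = 0,
                    hrf_latency_sd = 0, hrf_dispersion_sd = 0,
                    physio_amplitude = 0, seed = 13)
  sched <- make_paradigm(cfg$seed)
  gt <- boldicc:::cohort_ground_truth(cfg, g)
  vis <- boldicc:::region_cols(g, "visual")
  err <- c()
  for (i in 1:6) {
    run <- simulate_session(g, sched, cfg, i, 1)
    des <- build_design(sched, pipeline_spec("default"), run$n_volumes,
                        run$tr, motion = run$motion)
    fit <- fit_voxelwise(des, run)
    truth <- gt$subject_amplitudes$amplitude[
      gt$subject_amplitudes$subject == i &
        gt$subject_amplitudes$session == 1 &
        gt$subject_amplitudes$region == "visual"]
    err <- c(err, mean(fit$contrast_value[vis]) - truth)
  }
  expect_lt(abs(mean(err)), 0.05 * cfg$amplitude_mean[["visual"]])
})
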