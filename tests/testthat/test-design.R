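test_that("DCT drift basis matches the column-count formula and is orthonormal", {
  d <- dct_drift_basis(378, 2, 128)
  expect_equal(ncol(d), floor(2 * 378 * 2 / 128) + 1) # 12
  expect_equal(crossprod(d), diag(12), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(dct_drift_basis(378, 2, cutoff_s = 3), "cutoff")
})

test_that("drift basis removes slow fluctuations", {
  n <- 378; tr <- 2
  basis <- cbind(1, dct_drift_basis(n, tr))
  project_out <- function(y) y - basis %*% qr.coef(qr(basis), y)
  tt <- (seq_len(n) - 0.5) * tr
  # linear trend
  trend <- scale(tt, scale = FALSE)
  expect_lt(var(project_out(trend)) / var(trend), 0.01)
  # slow sinusoid (period 400 s, slower than the 128 s cutoff)
  slow <- sin(2 * pi * tt / 400)
  expect_lt(var(project_out(slow)) / var(slow), 0.01)
})

test_that("pipeline design matrices have the specified column structure", {
  run <- quiet_run()
  sched <- default_schedule()
  for (pn in names(study_pipelines())) {
    spec <- pipeline_spec(pn)
    mc <- if (spec$use_mcompcor) mcompcor_regressor(run) else NULL
    des <- build_design(sched, spec, run$n_volumes, run$tr,
                        motion = run$motion, mcompcor = mc)
    expect_equal(nrow(des$values), run$n_volumes)
    expect_equal(sum(des$groups == "task-canonical"), 5)
    n_deriv <- if (spec$use_derivatives) 5 else 0
    expect_equal(sum(des$groups == "task-temporal-derivative"), n_deriv)
    expect_equal(sum(des$groups == "task-dispersion-derivative"), n_deriv)
    expect_equal(sum(des$groups == "motion"), 6)
    expect_equal(sum(des$groups == "mcompcor"), as.integer(spec$use_mcompcor))
    expect_equal(sum(des$groups == "drift"), 12)
    expect_equal(sum(des$groups == "intercept"), 1)
    expect_false(anyDuplicated(des$labels) > 0)
    expect_true(all(colSums(abs(des$values)) > 0))
  }
})

test_that("degenerate design inputs are rejected", {
  run <- quiet_run()
  sched <- default_schedule()
  expect_error(build_design(sched[0, ], pipeline_spec("default"), 378, 2),
               "empty schedule")
  no_shapes <- sched[sched$trial_type != "shapes", ]
  expect_error(build_design(no_shapes, pipeline_spec("default"), 378, 2),
               "shapes")
  expect_error(build_design(sched, pipeline_spec("mcompcor"), 378, 2),
               "mcompcor")
  expect_error(build_design(sched, pipeline_spec("default"), 378, 2,
                            motion = run$motion[1:10, ]),
               "motion")
  expect_error(pipeline_spec("flexhrf", use_derivatives = TRUE,
                             use_mcompcor = FALSE, event_model = "block"),
               "mixed")
})

test_that("contrast vector averages emotions against shapes", {
  des <- small_design()
  w <- contrast_vector(des)
  expect_equal(sum(w), 0)
  expect_equal(unname(w[c("anger", "fear", "sad", "happy")]), rep(0.25, 4))
  expect_equal(unname(w[["shapes"]]), -1)
  expect_true(all(w[setdiff(names(w), c("anger", "fear", "sad", "happy", "shapes"))] == 0))
  expect_error(contrast_vector(des, "faces_minus_houses"), "unknown contrast")
})

test_that("derivative columns get zero contrast weight and labels drive lookup", {
  run <- quiet_run()
  des <- build_design(default_schedule(), pipeline_spec("flexhrf"),
                      run$n_volumes, run$tr, motion = run$motion)
  w <- contrast_vector(des)
  expect_true(all(w[grepl("_tder|_dder", names(w))] == 0))
  # permuting columns permutes weights identically (label-based lookup)
  perm <- sample(seq_along(des$labels))
  des_p <- des
  des_p$values <- des$values[, perm]
  des_p$labels <- des$labels[perm]
  des_p$groups <- des$groups[perm]
  expect_equal(contrast_vector(des_p), w[perm])
})

test_that("task regressors are linear in the schedule", {
  sched <- default_schedule()
  half1 <- sched[sched$block <= 9, ]
  half2 <- sched[sched$block > 9, ]
  r_all <- boldicc:::condition_regressors(sched, 378, 2)
  r1 <- boldicc:::condition_regressors(half1, 378, 2)
  r2 <- boldicc:::condition_regressors(half2, 378, 2)
  common <- intersect(colnames(r1), colnames(r2))
  expect_equal(r_all[, common], r1[, common] + r2[, common], tolerance = 1e-12)
  # empty interval list gives a zero regressor
  p <- hrf_params(dt = 0.125)
  z <- boldicc:::convolve_intervals(numeric(0), numeric(0), 378, 2,
                                    canonical_hrf(p)$values, p$dt)
  expect_equal(z, rep(0, 378))
})

test_that("microtime block regressors track the exact continuous response", {
  p <- hrf_params(dt = 2 / 16)
  onsets <- c(20, 100); durs <- c(12, 12); n <- 200; tr <- 2
  fine <- boldicc:::convolve_intervals(onsets, durs, n, tr,
                                       canonical_hrf(p)$values, p$dt)
  # exact block response from the integrated kernel:
  # (u * h)(t) = H(t - onset) - H(t - onset - duration)
  tt <- seq(0, n * tr, by = 0.001)
  big_h <- cumsum(boldicc:::double_gamma(tt, p) / boldicc:::canonical_peak(p)) * 0.001
  h_int <- function(x) approx(tt, big_h, pmax(x, 0), yleft = 0, rule = 2)$y
  vol_t <- (seq_len(n) - 0.5) * tr
  exact <- rowSums(sapply(seq_along(onsets), function(i) {
    h_int(vol_t - onsets[i]) - h_int(vol_t - onsets[i] - durs[i])
  }))
  expect_lt(max(abs(fine - exact)), 0.02 * max(exact))
})

test_that("per-stimulus event model equals the block model for contiguous stimuli", {
  sched <- default_schedule()
  blocky <- boldicc:::condition_regressors(sched, 378, 2, event_model = "block")
  eventy <- boldicc:::condition_regressors(sched, 378, 2, event_model = "mixed")
  expect_equal(blocky, eventy, tolerance = 1e-10)
})
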