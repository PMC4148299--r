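# Small, fast study configurations for orchestration tests: few subjects,
# small grid, low noise, and a lenient cluster-forming threshold so the
# group maps have suprathreshold voxels at n = 6.
tiny_sim <- function(seed = 101, ...) {
  sim_config(n_subjects = 6, sigma2_noise = 0.25, sigma2_between = 0.02,
             sigma2_within = 0.02, physio_amplitude = 0.5, seed = seed, ...)
}
tiny_study <- function(pipelines = c("default", "mcompcor"), seed = 101, ...) {
  study_config(simulation = tiny_sim(seed), pipelines = pipelines,
               voxel_p = 0.05, min_extent = 3, ...)
}

test_that("run_study is deterministic given the seed", {
  g <- small_geometry()
  res1 <- run_study(tiny_study(), geometry = g)
  res2 <- run_study(tiny_study(), geometry = g)
  expect_identical(res1$mvicc_table, res2$mvicc_table)
  expect_identical(res1$violation_table, res2$violation_table)
  expect_identical(res1$comparisons$icc$summary, res2$comparisons$icc$summary)
  # a different seed changes the numbers
  res3 <- run_study(tiny_study(seed = 102), geometry = g)
  expect_false(identical(res1$mvicc_table$mvicc, res3$mvicc_table$mvicc))
})

test_that("a single-pipeline study skips the comparison stage with a notice", {
  g <- small_geometry()
  expect_message(
    res <- run_study(tiny_study(pipelines = "default"), geometry = g,
                     verbose = TRUE),
    "comparison stage skipped")
  expect_null(res$comparisons)
  expect_equal(sort(unique(res$mvicc_table$pipeline)), "default")
  expect_equal(sort(unique(res$mvicc_table$region)), c("amygdala", "overlap"))
})

test_that("study results carry consistent structures", {
  g <- small_geometry()
  res <- run_study(tiny_study(), geometry = g)
  expect_s3_class(res$mvicc_table, "tbl_df")
  expect_equal(nrow(res$mvicc_table), 2 * 2) # pipelines x regions
  expect_equal(nrow(res$violation_table), 2 * 3)
  expect_true(all(res$violation_table$n_models ==
                    6 * 2 * length(unique(c(res$rois$overlap, res$rois$amygdala)))))
  expect_true(all(res$mvicc_table$category %in%
                    c("Poor", "Fair", "Good", "Excellent")))
  expect_equal(dim(res$group_t$default), g$shape)
})

test_that("a phantom written to disk and reloaded reproduces the analysis", {
  g <- phantom_geometry(c(10, 10, 6))
  cfg <- tiny_sim(seed = 103)
  cfg$n_subjects <- 3L
  cohort <- simulate_cohort(cfg, g)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  inputs <- load_real_inputs(dir)
  expect_length(inputs$runs, 6)
  study <- study_config(simulation = cfg, pipelines = c("default", "mcompcor"),
                        voxel_p = 0.05, min_extent = 3)
  res_mem <- run_study(study, geometry = g)
  res_disk <- run_study(study, inputs = inputs)
  expect_equal(res_disk$mvicc_table, res_mem$mvicc_table, tolerance = 1e-8)
  expect_equal(res_disk$violation_table$proportion,
               res_mem$violation_table$proportion, tolerance = 1e-8)
})

test_that("malformed on-disk inputs are rejected with informative errors", {
  g <- phantom_geometry(c(10, 10, 6))
  cfg <- tiny_sim(seed = 104)
  cfg$n_subjects <- 2L
  cohort <- simulate_cohort(cfg, g)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)

  # orphan subject: one session removed from the manifest
  manifest <- readr::read_tsv(file.path(dir, "manifest.tsv"),
                              show_col_types = FALSE)
  readr::write_tsv(manifest[-1, ], file.path(dir, "manifest.tsv"))
  expect_error(load_real_inputs(dir), "exactly 2 sessions")
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))

  # missing motion file
  motion_path <- file.path(dir, manifest$motion[1])
  file.rename(motion_path, paste0(motion_path, ".bak"))
  expect_error(load_real_inputs(dir), "missing motion file")
  file.rename(paste0(motion_path, ".bak"), motion_path)

  # events extending beyond the run
  events <- readr::read_tsv(file.path(dir, "events.tsv"), show_col_types = FALSE)
  events$onset[nrow(events)] <- 1e5
  readr::write_tsv(events, file.path(dir, "events.tsv"))
  expect_error(load_real_inputs(dir), "beyond the run")
})

test_that("non-empty output directories are protected against overwrite", {
  g <- small_geometry()
  dir <- withr::local_tempdir()
  writeLines("x", file.path(dir, "leftover.txt"))
  expect_error(run_study(tiny_study(output_dir = dir), geometry = g),
               "resume")
})

test_that("study outputs are written when an output directory is given", {
  g <- phantom_geometry(c(10, 10, 6))
  dir <- file.path(withr::local_tempdir(), "out")
  cfg <- tiny_study(seed = 105, output_dir = dir)
  cfg$simulation$n_subjects <- 3L
  res <- run_study(cfg, geometry = g)
  expect_true(file.exists(file.path(dir, "mvicc.csv")))
  expect_true(file.exists(file.path(dir, "violations.csv")))
  expect_true(file.exists(file.path(dir, "overlap_mask.nii.gz")))
  expect_true(file.exists(file.path(dir, "default", "icc.nii.gz")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  on_disk <- readr::read_csv(file.path(dir, "mvicc.csv"), show_col_types = FALSE)
  expect_equal(on_disk$mvicc, res$mvicc_table$mvicc)
})
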