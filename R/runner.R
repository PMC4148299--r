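# End-to-end study orchestration: simulate (or load) -> fit all pipelines x
# two sessions -> group maps and overlap ROI -> ICC -> residual diagnostics
# -> nonparametric pipeline comparisons.

#' Study configuration
#'
#' @param simulation A [sim_config()] (carries the root seed).
#' @param pipelines Character vector of pipeline names (see
#'   [study_pipelines()]).
#' @param alpha Significance level for assumption-violation flags.
#' @param voxel_p Cluster-forming voxel threshold for the group maps.
#' @param min_extent Minimum cluster extent (voxels).
#' @param connectivity Cluster connectivity (6, 18 or 26).
#' @param highpass_cutoff High-pass cutoff, seconds.
#' @param output_dir Optional directory for on-disk outputs.
#' @param resume Allow writing into a non-empty `output_dir`.
#' @return An object of class `study_config`.
#' @export
study_config <- function(simulation = sim_config(),
                         pipelines = c("default", "flexhrf", "mcompcor", "combined"),
                         alpha = 0.05, voxel_p = 0.001, min_extent = 5,
                         connectivity = 6, highpass_cutoff = 128,
                         output_dir = NULL, resume = FALSE) {
  stopifnot(inherits(simulation, "sim_config"))
  assert_that(!anyDuplicated(pipelines), "pipeline names must be unique")
  assert_that(all(pipelines %in% names(study_pipelines())),
              paste("unknown pipeline(s):",
                    paste(setdiff(pipelines, names(study_pipelines())), collapse = ", ")))
  structure(list(simulation = simulation, pipelines = pipelines,
                 alpha = alpha, voxel_p = voxel_p, min_extent = min_extent,
                 connectivity = connectivity, highpass_cutoff = highpass_cutoff,
                 output_dir = output_dir, resume = resume,
                 seed = simulation$seed),
            class = "study_config")
}

#' Run the full reliability study
#'
#' Simulates (or takes) every subject-session run, fits each requested
#' pipeline, builds session-1 group t-maps and the cross-pipeline overlap
#' ROI, estimates voxelwise ICC(3,1) per pipeline with mvICC summaries in
#' the overlap and amygdala ROIs, tests residual assumptions at the ROI
#' voxels, and compares pipelines with Friedman/Nemenyi tests on matched
#' voxel t-values, voxel ICCs, and subject-level violation proportions.
#' Runs are streamed (each run is regenerated from its seed substream when
#' needed), so memory stays flat in the cohort size.
#'
#' @param config A [study_config()].
#' @param geometry A [phantom_geometry()] (ignored when `inputs` given).
#' @param inputs Optional [load_real_inputs()] result to analyze instead of
#'   simulating.
#' @param verbose Print stage progress.
#' @return An object of class `study_result`; see the elements `mvicc_table`,
#'   `violation_table`, `comparisons`, `icc_maps`, `group_t`, `masks`,
#'   `overlap_roi`, `ground_truth`, `manifest`.
#' @export
run_study <- function(config, geometry = phantom_geometry(), inputs = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  sim <- config$simulation
  say <- function(...) if (verbose) message(...)
  t0 <- Sys.time()

  if (!is.null(config$output_dir)) {
    if (dir.exists(config$output_dir) &&
        length(list.files(config$output_dir)) > 0 && !config$resume) {
      abort("output_dir is non-empty; pass resume = TRUE to write into it")
    }
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  }

  if (!is.null(inputs)) {
    geometry <- inputs$geometry
    schedule <- inputs$schedule
    subjects <- sort(unique(purrr::map_dbl(inputs$runs, "subject_id")))
    run_index <- setNames(seq_along(inputs$runs),
                          purrr::map_chr(inputs$runs,
                                         ~ paste(.x$subject_id, .x$session_id)))
    get_run <- function(i, s) inputs$runs[[run_index[[paste(i, s)]]]]
    n_volumes <- inputs$runs[[1]]$n_volumes
    tr <- inputs$runs[[1]]$tr
  } else {
    schedule <- make_paradigm(sim$seed, sim$n_volumes, sim$tr_seconds)
    subjects <- seq_len(sim$n_subjects)
    get_run <- function(i, s) simulate_session(geometry, schedule, sim, i, s)
    n_volumes <- sim$n_volumes
    tr <- sim$tr_seconds
  }
  specs <- study_pipelines()[config$pipelines]
  n_brain <- length(geometry$brain_idx)

  fit_run <- function(run, spec) {
    mc <- if (spec$use_mcompcor) mcompcor_regressor(run) else NULL
    des <- build_design(schedule, spec, run$n_volumes, run$tr,
                        motion = run$motion, mcompcor = mc,
                        highpass_cutoff = config$highpass_cutoff)
    fit_voxelwise(des, run)
  }

  # ---- pass 1: contrast and t maps per run x pipeline -----------------------
  say("fitting ", length(specs), " pipeline(s) x ", 2 * length(subjects), " runs")
  contrast_maps <- lapply(specs, function(spec) {
    lapply(1:2, function(s) {
      matrix(NA_real_, length(subjects), n_brain, dimnames = list(subjects, NULL))
    })
  })
  t1_maps <- lapply(specs, function(spec) {
    matrix(NA_real_, length(subjects), n_brain, dimnames = list(subjects, NULL))
  })
  for (i_pos in seq_along(subjects)) {
    i <- subjects[i_pos]
    for (s in 1:2) {
      run <- get_run(i, s)
      for (pn in names(specs)) {
        fit <- fit_run(run, specs[[pn]])
        contrast_maps[[pn]][[s]][i_pos, ] <- fit$contrast_value
        if (s == 1) t1_maps[[pn]][i_pos, ] <- fit$t_value
      }
    }
  }
  # per-voxel median first-level t (session 1): the matched t statistic
  # pipelines are compared on
  median_t1 <- lapply(t1_maps, function(m) apply(m, 2, median))

  # ---- group maps, cluster masks, overlap ROI -------------------------------
  say("group maps and overlap ROI")
  n_sub <- length(subjects)
  group_t <- lapply(contrast_maps, function(cm) {
    m <- cm[[1]]
    tv <- colMeans(m) / (col_sds(m) / sqrt(n_sub))
    brain_vec_to_array(geometry, tv)
  })
  cluster_results <- lapply(group_t, threshold_clusters, df = n_sub - 1,
                            voxel_p = config$voxel_p,
                            min_extent = config$min_extent,
                            connectivity = config$connectivity)
  overlap <- overlap_mask(lapply(cluster_results, `[[`, "mask"))
  roi_overlap <- match(which(overlap), geometry$brain_idx)
  roi_amygdala <- region_cols(geometry, "amygdala")
  rois <- list(overlap = roi_overlap, amygdala = roi_amygdala)

  # ---- ICC maps and mvICC ---------------------------------------------------
  say("voxelwise ICC(3,1)")
  icc_maps <- lapply(contrast_maps, function(cm) icc_map(cm[[1]], cm[[2]], geometry))
  mvicc_table <- purrr::map_dfr(names(icc_maps), function(pn) {
    purrr::map_dfr(names(rois), function(rn) {
      mv <- mvicc(icc_maps[[pn]], rois[[rn]])
      tibble(pipeline = pn, region = rn, mvicc = as.numeric(mv),
             n_voxels = attr(mv, "n_voxels"),
             category = as.character(cicchetti_category(as.numeric(mv))))
    })
  })

  # ---- pass 2: residual diagnostics at ROI voxels ---------------------------
  say("residual diagnostics")
  diag_voxels <- sort(unique(c(roi_overlap, roi_amygdala)))
  reports <- list()
  for (i_pos in seq_along(subjects)) {
    i <- subjects[i_pos]
    for (s in 1:2) {
      run <- get_run(i, s)
      for (pn in names(specs)) {
        fit <- fit_run(run, specs[[pn]])
        reports[[length(reports) + 1]] <-
          diagnose_fit(fit, voxels = diag_voxels, alpha = config$alpha,
                       pipeline = pn)
      }
    }
  }
  violation_table <- summarize_violations(reports)
  violations_subject <- violations_by_subject(reports)

  # ---- pipeline comparisons -------------------------------------------------
  comparisons <- NULL
  if (length(specs) >= 2) {
    say("pipeline comparisons")
    t_mat <- sapply(names(specs), function(pn) median_t1[[pn]][roi_overlap])
    icc_mat <- sapply(names(specs), function(pn) icc_maps[[pn]]$icc[roi_overlap])
    viol_cmp <- lapply(split(violations_subject, violations_subject$assumption),
                       function(d) {
                         m <- tidyr::pivot_wider(d, id_cols = "subject_id",
                                                 names_from = "pipeline",
                                                 values_from = "proportion")
                         compare_pipelines(as.matrix(m[config$pipelines]),
                                           stat_kind = "violation_proportion",
                                           block_kind = "subject")
                       })
    comparisons <- list(
      t_value = compare_pipelines(t_mat, "t_value", "voxel"),
      icc = compare_pipelines(icc_mat, "icc", "voxel"),
      violations = viol_cmp
    )
  } else {
    say("single pipeline: comparison stage skipped")
  }

  ground_truth <- if (is.null(inputs)) cohort_ground_truth(sim, geometry) else NULL
  manifest <- list(
    package = "boldicc",
    version = as.character(utils::packageVersion("boldicc")),
    seed = config$seed, n_subjects = n_sub,
    pipelines = config$pipelines, n_volumes = n_volumes, tr = tr,
    alpha = config$alpha, voxel_p = config$voxel_p,
    min_extent = config$min_extent, connectivity = config$connectivity,
    grid = paste(geometry$shape, collapse = "x"),
    simulated = is.null(inputs)
  )

  result <- structure(
    list(mvicc_table = mvicc_table, violation_table = violation_table,
         violations_by_subject = violations_subject,
         comparisons = comparisons, icc_maps = icc_maps,
         group_t = group_t, median_t1 = median_t1,
         cluster_results = cluster_results,
         masks = lapply(cluster_results, `[[`, "mask"),
         overlap = overlap, rois = rois,
         ground_truth = ground_truth, config = config, geometry = geometry,
         manifest = manifest),
    class = "study_result"
  )
  if (!is.null(config$output_dir)) write_study_outputs(result, config$output_dir)
  say("done in ", round(as.numeric(difftime(Sys.time(), t0, units = "secs"))), " s")
  result
}

write_study_outputs <- function(result, dir) {
  readr::write_csv(result$mvicc_table, file.path(dir, "mvicc.csv"))
  readr::write_csv(result$violation_table, file.path(dir, "violations.csv"))
  geom <- result$geometry
  for (pn in names(result$group_t)) {
    pdir <- file.path(dir, pn)
    dir.create(pdir, showWarnings = FALSE)
    tmap <- result$group_t[[pn]]
    tmap[is.na(tmap)] <- 0
    write_map <- function(arr, path) {
      img <- RNifti::asNifti(arr)
      RNifti::pixdim(img) <- geom$voxel_size
      RNifti::writeNifti(img, path)
    }
    write_map(tmap, file.path(pdir, "group_t_ses1.nii.gz"))
    write_map(brain_vec_to_array(geom, result$icc_maps[[pn]]$icc, fill = 0),
              file.path(pdir, "icc.nii.gz"))
    write_map(result$masks[[pn]] + 0, file.path(pdir, "mask_ses1.nii.gz"))
  }
  {
    img <- RNifti::asNifti(result$overlap + 0)
    RNifti::pixdim(img) <- geom$voxel_size
    RNifti::writeNifti(img, file.path(dir, "overlap_mask.nii.gz"))
  }
  if (!is.null(result$comparisons)) {
    jsonlite::write_json(
      list(t_value = glance(result$comparisons$t_value),
           icc = glance(result$comparisons$icc),
           violations = lapply(result$comparisons$violations, glance)),
      file.path(dir, "comparisons.json"), digits = NA, auto_unbox = TRUE)
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result> ", x$manifest$n_subjects, " subjects x 2 sessions, ",
      length(x$config$pipelines), " pipeline(s), grid ", x$manifest$grid, "\n",
      sep = "")
  cat("\nmvICC by region and pipeline:\n")
  print(x$mvicc_table)
  cat("\nAssumption violation proportions (ROI voxels):\n")
  print(x$violation_table)
  invisible(x)
}
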