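# End-to-end orchestration: synthetic cohort -> two-channel volumes -> ROIs
# -> CAE-FC -> histograms -> EFA -> QCT -> subject clusters -> statistics ->
# airway surrogate, with per-stage seeds fanned out from one master seed and
# a manifest recording parameters and output checksums.

#' Default pipeline configuration
#'
#' All stage parameters with their defaults; pass overrides to
#' [run_pipeline] as a modified copy (or a YAML file with the same keys).
#' The per-stage seeds are derived from `seed` by fixed offsets, so toggling
#' one stage does not silently change another stage's draws.
#'
#' @param seed master seed.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    synth = list(enabled = TRUE,
                 n_per_group = c(exposed = 10, control = 10),
                 shape = c(64, 64, 64), spacing = c(1, 1, 1),
                 mixture_jitter = 0.15,
                 gender_prob = c(exposed = 0.6, control = 0.2),
                 height_shift = c(exposed = -3, control = 3),
                 airway_scale = c(exposed = 0.88, control = 1)),
    rois = list(roi_mm = 12, n_train_per_subject = 30, stride_mm = 6,
                min_lung_fraction = 0.5),
    caefc = list(C = 4, candidate_Cs = NULL, epochs = 12, batch_size = 32,
                 learning_rate = 1e-3, channels = c(16, 32)),
    efa = list(n_factors = 2, rotation = "varimax", threshold = 0.4),
    clusters = list(n_clusters = "auto", n_restarts = 10, minor_size = 5,
                    tree_max_depth = 3, tree_folds = 3),
    airway = list(particle_um = 0.5, density_g_cm3 = 1, split_rule = "symmetric")
  )
}

#' Run the full pipeline
#'
#' Executes every enabled stage against a synthetic cohort (or a pre-built
#' cohort passed in), writing all stage outputs and a JSON manifest
#' (parameters, seeds, package version, per-file MD5 checksums) into
#' `out_dir`. Stage failures halt with a stage-scoped error; outputs of the
#' completed stages remain on disk.
#'
#' @param config list from [default_pipeline_config] (possibly modified) or
#'   the path to a YAML file of overrides.
#' @param out_dir run directory (created).
#' @param cohort optional pre-generated [generate_cohort] result; when NULL
#'   the synth stage must be enabled.
#' @return invisibly, a list of in-memory stage results (`cohort`, `model`,
#'   `histograms`, `efa`, `qct`, `clusters`, `stats`, `airway`, `manifest`).
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir, cohort = NULL) {
  if (is.character(config)) {
    ov <- yaml::read_yaml(config)
    config <- utils::modifyList(default_pipeline_config(), ov)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # 1. synthetic cohort ----------------------------------------------------
  if (is.null(cohort)) {
    stop_if(!isTRUE(config$synth$enabled),
            "stage 'synth': no cohort given and synthesis disabled")
    cohort <- stage("synth", do.call(generate_cohort, c(
      list(n_per_group = config$synth$n_per_group,
           shape = config$synth$shape, spacing = config$synth$spacing,
           seed = child_seed(seed, 101),
           mixture_jitter = config$synth$mixture_jitter),
      config$synth[intersect(names(config$synth),
                             c("gender_prob", "height_shift", "airway_scale"))])))
  }
  meta <- cohort$metadata
  utils::write.csv(meta, file.path(out_dir, "metadata.csv"), row.names = FALSE)

  # 2-3. two-channel volumes and ROIs --------------------------------------
  rois_cfg <- config$rois
  roi_sets <- stage("rois", lapply(seq_along(cohort$subjects), function(i) {
    s <- cohort$subjects[[i]]
    tc <- build_two_channel(s$scan)
    attr(tc, "subject_id") <- s$profile$subject_id
    list(train = sample_random_rois(
           tc, n = rois_cfg$n_train_per_subject, roi_mm = rois_cfg$roi_mm,
           min_lung_fraction = rois_cfg$min_lung_fraction,
           seed = child_seed(seed, 200 + i)),
         windows = sliding_window_rois(
           tc, roi_mm = rois_cfg$roi_mm, stride_mm = rois_cfg$stride_mm,
           min_lung_fraction = rois_cfg$min_lung_fraction))
  }))
  train_patches <- do.call(c, lapply(roi_sets, `[[`, "train"))
  windows <- lapply(roi_sets, `[[`, "windows")

  # 4. CAE-FC ---------------------------------------------------------------
  cc <- config$caefc
  C <- cc$C
  model <- stage("caefc", {
    if (!is.null(cc$candidate_Cs)) {
      C <- as.integer(select_cluster_count(
        train_patches, cc$candidate_Cs, epochs = cc$epochs,
        batch_size = cc$batch_size, learning_rate = cc$learning_rate,
        channels = cc$channels, seed = child_seed(seed, 300)))
    }
    train_caefc(train_patches, C, epochs = cc$epochs, batch_size = cc$batch_size,
                learning_rate = cc$learning_rate, channels = cc$channels,
                seed = child_seed(seed, 301))
  })
  utils::write.csv(model$training_log, file.path(out_dir, "caefc_loss.csv"),
                   row.names = FALSE)

  # 5. histograms -----------------------------------------------------------
  hist_mat <- stage("histograms", {
    assignments <- do.call(rbind, lapply(windows, function(w) {
      if (length(w)) assign_patches(model, w) else NULL
    }))
    histogram_matrix(assignments, model$C)
  })
  utils::write.csv(hist_mat, file.path(out_dir, "histograms.csv"))

  # 6. EFA -------------------------------------------------------------------
  ec <- config$efa
  fm <- stage("efa", fit_efa(hist_mat, n_factors = ec$n_factors,
                             rotation = ec$rotation,
                             seed = child_seed(seed, 400)))
  utils::write.csv(fm$loadings, file.path(out_dir, "efa_loadings.csv"))
  utils::write.csv(fm$scores, file.path(out_dir, "efa_scores.csv"))
  assoc <- factor_associations(fm, ec$threshold)
  corr <- stage("efa", factor_variable_correlations(
    fm$scores[meta$subject_id, , drop = FALSE],
    meta[, c("age", "gender", "height", "weight", "bmi", "fvc_pct", "fev1_pct",
             "exposure")],
    binary = c("gender", "exposure")))
  utils::write.csv(corr, file.path(out_dir, "factor_correlations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(associations = assoc,
                            masked = corr[!is.na(corr$r_masked), ]),
                       file.path(out_dir, "factor_correlations.json"),
                       auto_unbox = TRUE, digits = NA)

  # 7. QCT metrics -----------------------------------------------------------
  qct <- stage("qct", do.call(rbind, lapply(cohort$subjects, function(s) {
    qct_record(s$scan, airway_ml = airway_tree_volume(s$tree))
  })))
  utils::write.csv(qct, file.path(out_dir, "qct.csv"), row.names = FALSE)

  # 8. subject clusters + decision tree --------------------------------------
  kc <- config$clusters
  clus <- stage("clusters", kmeans_factor_space(
    fm$scores, n_clusters = kc$n_clusters, seed = child_seed(seed, 500),
    n_restarts = kc$n_restarts, minor_size = kc$minor_size))
  utils::write.csv(clus$assignments, file.path(out_dir, "clusters.csv"),
                   row.names = FALSE)
  tree_fit <- stage("clusters", {
    lab <- clus$assignments$cluster[match(meta$subject_id,
                                          clus$assignments$subject_id)]
    main <- names(sort(table(lab[!clus$assignments$minor_flag[
      match(meta$subject_id, clus$assignments$subject_id)]]), decreasing = TRUE))
    grouped <- ifelse(lab %in% main[seq_len(min(2, length(main)))], lab, "other")
    if (length(unique(grouped)) >= 2 && all(table(grouped) >= kc$tree_folds)) {
      feats <- cbind(meta[, c("age", "gender", "height", "weight", "bmi",
                              "fvc_pct", "fev1_pct")],
                     qct[, c("Tissue_pct_Total", "LAA_TLC_pct_Total",
                             "LAA_RV_pct_Total", "fSAD_pct_Total", "RV_TLC")])
      fit <- train_cluster_tree(feats, grouped, max_depth = kc$tree_max_depth,
                                n_folds = kc$tree_folds,
                                seed = child_seed(seed, 501))
      write_cluster_tree(fit, file.path(out_dir, "cluster_tree.json"))
      write_cluster_tree(fit, file.path(out_dir, "cluster_tree.dot"))
      fit
    } else NULL
  })

  # 9. cohort statistics ------------------------------------------------------
  stats_out <- stage("stats", {
    dat <- cbind(meta, qct[match(meta$subject_id, qct$subject_id), -1],
                 cluster = clus$assignments$cluster[
                   match(meta$subject_id, clus$assignments$subject_id)])
    vars <- c("age", "height", "weight", "bmi", "fvc_pct", "fev1_pct",
              "Tissue_pct_Total", "RV_TLC")
    minor <- clus$assignments$minor_flag[
      match(dat$subject_id, clus$assignments$subject_id)]
    rep_tab <- cohort_report(dat[!minor, , drop = FALSE], vars, "cluster")
    utils::write.csv(rep_tab, file.path(out_dir, "cluster_report.csv"),
                     row.names = FALSE)
    ct <- table(dat$cluster, dat$exposure)
    chi <- if (all(dim(ct) >= 2)) chi_square(unclass(ct)) else NULL
    list(report = rep_tab, exposure_table = ct, exposure_chisq = chi)
  })

  # 10. airway surrogate -------------------------------------------------------
  ac <- config$airway
  airway <- stage("airway", do.call(rbind, lapply(cohort$subjects, function(s) {
    wf <- breathing_waveform(s$profile$weight)
    dp <- pressure_drop(s$tree, wf$peak_flow_mls, ac$split_rule)
    dep <- deposition_1d(s$tree, wf, diameter_um = ac$particle_um,
                         density_g_cm3 = ac$density_g_cm3,
                         split_rule = ac$split_rule)
    data.frame(subject_id = s$profile$subject_id,
               tidal_volume_ml = wf$tidal_volume_ml,
               peak_flow_mls = wf$peak_flow_mls,
               total_path_dp_pa = max(dp$path_dp_pa),
               total_df = dep$total_df, escape = dep$escape,
               stringsAsFactors = FALSE)
  })))
  utils::write.csv(airway, file.path(out_dir, "airway.csv"), row.names = FALSE)

  # manifest -------------------------------------------------------------------
  files <- list.files(out_dir, recursive = TRUE)
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    package = as.character(utils::packageVersion("hdlungct")),
    r_version = R.version.string,
    seed = seed,
    config = config,
    checksums = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, model = model, histograms = hist_mat,
                 efa = fm, associations = assoc, correlations = corr,
                 qct = qct, clusters = clus, tree = tree_fit,
                 stats = stats_out, airway = airway, manifest = manifest))
}
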