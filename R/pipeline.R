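#' End-to-end analysis driver
#'
#' `run_pipeline()` ties the stages together for a cohort (in memory or
#' on disk): temporal preprocessing per session, seed eigenvariate
#' extraction and first-level GLMs, criticism-minus-standard contrast
#' maps, second-level inference for the four directional contrasts
#' (criticism > standard, standard > criticism, +/- neuroticism
#' modulation), cluster tables, and the seed clustering (matrix D,
#' model-order estimates, FCM, dual flags, similarity graph).  All
#' randomness flows from `rng_seed`; a JSON manifest of every parameter
#' is written when an output directory is given.
#'
#' @name reporting_cli
NULL

#' Pipeline configuration
#'
#' Every analysis constant is a config field (nothing hard-coded): band
#' edges 0.008-0.08 Hz, 6 mm seed radius and smoothing kernel,
#' cluster-forming p < 0.001, extent k > 20, 13-seed Bonferroni,
#' fuzzifier 2, 20 restarts, dual gap 0.15.  `read_run_config()` loads
#' the same fields from a YAML file (see
#' `system.file("extdata", "default_config.yaml", package = "seedfc")`).
#'
#' @param low_hz,high_hz band-pass edges, Hz.
#' @param fwhm_mm smoothing kernel FWHM, mm (applied only when volumes
#'   are read from disk; in-memory cohorts are generated directly on the
#'   common grid).
#' @param n_keep volumes kept per session before processing (`NULL` =
#'   all).
#' @param voxel_p,k_min,n_perm,n_seeds_bonferroni inference parameters.
#' @param fcm_c number of clusters (`NULL` = estimate from the profile
#'   log-likelihood).
#' @param fcm_m,fcm_n_init,dual_gap clustering parameters.
#' @param run_inference run the (permutation-heavy) second-level stage.
#' @param rng_seed integer seed for permutations and FCM restarts.
#' @return a `seedfc_run_config` list.
#' @export
run_config <- function(low_hz = 0.008, high_hz = 0.08, fwhm_mm = 6,
                       n_keep = NULL, voxel_p = 0.001, k_min = 20,
                       n_perm = 1000, n_seeds_bonferroni = 13,
                       fcm_c = NULL, fcm_m = 2, fcm_n_init = 20,
                       dual_gap = 0.15, run_inference = TRUE,
                       rng_seed = 1) {
  structure(
    list(
      low_hz = low_hz, high_hz = high_hz, fwhm_mm = fwhm_mm,
      n_keep = n_keep, voxel_p = voxel_p, k_min = k_min, n_perm = n_perm,
      n_seeds_bonferroni = n_seeds_bonferroni, fcm_c = fcm_c,
      fcm_m = fcm_m, fcm_n_init = fcm_n_init, dual_gap = dual_gap,
      run_inference = run_inference, rng_seed = as.integer(rng_seed)
    ),
    class = "seedfc_run_config"
  )
}

#' @rdname run_config
#' @param path YAML config path.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, y)
}

#' Run the full analysis on a cohort
#'
#' @param cohort a `seedfc_cohort` from [generate_cohort()] /
#'   [read_cohort()].
#' @param config a [run_config()].
#' @param out_dir optional output directory; when given, contrast-map
#'   NIfTIs, cluster-table/membership/partition/edge TSV-JSON files and
#'   the run manifest are written there.
#' @param write_maps also write per-subject contrast NIfTIs (large).
#' @return a `seedfc_run`: list with `contrasts` (per seed,
#'   n_subjects x V), `design`, `stat` (per contrast name, per seed
#'   `seedfc_statmap`s) unless inference is disabled, `tables` (tibble),
#'   `D`, `spectrum`, `k_profile`, `k_scree`, `fcm`, `assignments`,
#'   `graph`, `config`, and `manifest`.
#' @export
run_pipeline <- function(cohort, config = run_config(), out_dir = NULL,
                         write_maps = FALSE) {
  stopifnot(inherits(cohort, "seedfc_cohort"))
  t0 <- Sys.time()
  log_stage <- function(...) {
    message(sprintf("[seedfc %5.1fs] ", as.numeric(Sys.time() - t0)), ...)
  }

  # ---- preprocessing + first level, subject by subject ----------------
  log_stage(
    "preprocess + first level: ", length(cohort$subjects), " subjects, ",
    length(cohort$seed_cols), " seeds"
  )
  n_sub <- length(cohort$subjects)
  Vb <- length(cohort$brain_cols)
  contrasts_by_seed <- lapply(cohort$seed_cols, function(...) {
    matrix(NA_real_, n_sub, Vb)
  })
  for (i in seq_len(n_sub)) {
    sub <- cohort$subjects[[i]]
    clean <- lapply(c(standard = "standard", criticism = "criticism"),
      function(session) {
        Y <- sub$sessions[[session]]
        if (is.null(Y)) {
          stop(
            "first level failed for ", sub$subject_id,
            ": missing session '", session, "'"
          )
        }
        preprocess_session(
          Y, sub$motion[[session]],
          wm_cols = cohort$wm_cols, csf_cols = cohort$csf_cols,
          brain_cols = cohort$brain_cols, tr_s = cohort$config$tr_s,
          low_hz = config$low_hz, high_hz = config$high_hz,
          n_keep = config$n_keep
        )[, cohort$brain_cols, drop = FALSE]
      }
    )
    cmaps <- subject_contrasts(clean$standard, clean$criticism, cohort$seed_cols)
    for (s in names(cohort$seed_cols)) {
      contrasts_by_seed[[s]][i, ] <- cmaps[, s]
    }
  }

  design <- build_design(cohort$covariates)
  voxel_index <- cohort$voxel_index[cohort$brain_cols, , drop = FALSE]

  # ---- second level ---------------------------------------------------
  stat <- NULL
  tables <- NULL
  if (isTRUE(config$run_inference)) {
    contrast_defs <- list(
      criticism_gt_standard = design$contrasts$session_mean,
      standard_gt_criticism = -design$contrasts$session_mean,
      neuroticism_pos = design$contrasts$neuro_pos,
      neuroticism_neg = design$contrasts$neuro_neg
    )
    stat <- lapply(names(contrast_defs), function(cname) {
      log_stage("second level (", cname, "), ", config$n_perm, " permutations")
      lapply(names(contrasts_by_seed), function(s) {
        sm <- permutation_cluster_fwe(
          contrasts_by_seed[[s]], design, contrast_defs[[cname]],
          voxel_p = config$voxel_p, k_min = config$k_min,
          n_perm = config$n_perm, rng_seed = config$rng_seed,
          voxel_index = voxel_index, grid = cohort$grid
        )
        sm
      }) |> stats::setNames(names(contrasts_by_seed))
    }) |> stats::setNames(names(contrast_defs))
    tables <- dplyr::bind_rows(lapply(names(stat), function(cname) {
      dplyr::bind_rows(lapply(names(stat[[cname]]), function(s) {
        tab <- cluster_table(stat[[cname]][[s]], seed_name = s)
        if (nrow(tab)) dplyr::mutate(tab, contrast = cname, .before = 1) else NULL
      }))
    }))
  }

  # ---- clustering -----------------------------------------------------
  log_stage("seed clustering")
  D <- build_profile_matrix(contrasts_by_seed)
  spectrum <- eigen_spectrum(D)
  k_profile <- estimate_k_profile_loglik(spectrum)
  k_scree <- estimate_k_scree(spectrum)
  c_use <- if (is.null(config$fcm_c)) k_profile else config$fcm_c
  fit <- fcm(
    D, c = c_use, m = config$fcm_m, n_init = config$fcm_n_init,
    rng_seed = config$rng_seed
  )
  assignments <- assign_clusters(fit, dual_gap = config$dual_gap)
  graph <- seed_similarity_graph(D)

  manifest <- list(
    package_version = as.character(utils::packageVersion("seedfc")),
    r_version = R.version.string,
    config = unclass(config),
    cohort = list(
      n_subjects = n_sub,
      n_seeds = length(cohort$seed_cols),
      grid_shape = cohort$grid$shape,
      voxel_mm = cohort$grid$voxel_mm,
      tr_s = cohort$config$tr_s,
      n_volumes = cohort$config$n_volumes,
      cohort_rng_seed = cohort$config$rng_seed
    ),
    k_profile = k_profile,
    k_scree = k_scree,
    fcm_c = c_use
  )

  run <- structure(
    list(
      contrasts = contrasts_by_seed, design = design, stat = stat,
      tables = tables, D = D, spectrum = spectrum,
      k_profile = k_profile, k_scree = k_scree, fcm = fit,
      assignments = assignments, graph = graph,
      voxel_index = voxel_index, grid = cohort$grid,
      config = config, manifest = manifest
    ),
    class = "seedfc_run"
  )

  if (!is.null(out_dir)) {
    write_run(run, out_dir, cohort = cohort, write_maps = write_maps)
  }
  log_stage("done")
  run
}

#' @export
print.seedfc_run <- function(x, ...) {
  cat(
    "<seedfc_run> ", nrow(x$D), " seeds, ", ncol(x$D), " voxels; ",
    "k (profile loglik) = ", x$k_profile, ", k (scree) = ", x$k_scree,
    "; FCM c = ", x$fcm$c, "\n", sep = ""
  )
  if (!is.null(x$tables)) {
    cat("  ", nrow(x$tables), " reported peak row(s) across contrasts\n", sep = "")
  }
  invisible(x)
}

write_run <- function(run, out_dir, cohort = NULL, write_maps = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) {
    write.table(
      x, file.path(out_dir, name),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
  }
  if (!is.null(run$tables)) tsv(run$tables, "cluster_tables.tsv")
  U <- run$fcm$U
  tsv(
    cbind(cluster = seq_len(nrow(U)), as.data.frame(U)),
    "memberships.tsv"
  )
  tsv(run$assignments, "partition.tsv")
  jsonlite::write_json(
    split(run$assignments$cluster, run$assignments$seed),
    file.path(out_dir, "partition.json"), auto_unbox = TRUE
  )
  tsv(run$graph$edges, "seed_graph_edges.tsv")
  tsv(
    tibble::tibble(component = seq_along(run$spectrum), eigenvalue = run$spectrum),
    "eigen_spectrum.tsv"
  )
  jsonlite::write_json(
    run$manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  if (write_maps && !is.null(cohort)) {
    lin <- index_to_linear(run$grid, run$voxel_index)
    for (s in names(run$contrasts)) {
      M <- run$contrasts[[s]]
      for (i in seq_len(nrow(M))) {
        vol <- array(0, run$grid$shape)
        vol[lin] <- M[i, ]
        write_volume(
          vol, run$grid,
          file.path(
            out_dir,
            paste0(cohort$covariates$subject_id[i], "_", s, "_contrast.nii.gz")
          )
        )
      }
    }
  }
  invisible(out_dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return a `seedfc_cohort` (without the truth manifest's in-memory
#'   time courses; planted parameters are reloaded from `truth.json`).
#' @export
read_cohort <- function(dir) {
  truth_path <- file.path(dir, "truth.json")
  if (!file.exists(truth_path)) stop("no truth.json in ", dir)
  manifest <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
  cfg_l <- manifest$config
  cfg <- cohort_config(
    n_subjects = cfg_l$n_subjects, grid_shape = cfg_l$grid_shape,
    voxel_size_mm = cfg_l$voxel_size_mm, n_volumes = cfg_l$n_volumes,
    tr_s = cfg_l$tr_s,
    planted_partition = tibble::as_tibble(manifest$partition),
    session_effect = cfg_l$session_effect,
    covariate_slope = cfg_l$covariate_slope, base_gain = cfg_l$base_gain,
    target_radii = as.list(cfg_l$target_radii),
    noise_sd = cfg_l$noise_sd, drift_amp = cfg_l$drift_amp,
    global_amp = cfg_l$global_amp, motion_amp = cfg_l$motion_amp,
    seed_radius_mm = cfg_l$seed_radius_mm,
    network_band = cfg_l$network_band, rng_seed = cfg_l$rng_seed
  )
  ext <- if (file.exists(file.path(dir, "mask_brain.nii.gz"))) {
    ".nii.gz"
  } else {
    ".nii"
  }
  read_mask <- function(name) {
    read_volume(file.path(dir, paste0(name, ext)))
  }
  brain <- read_mask("mask_brain")
  grid <- brain$grid
  lin_brain <- which(brain$data > 0)
  lin_wm <- which(read_mask("mask_wm")$data > 0)
  lin_csf <- which(read_mask("mask_csf")$data > 0)
  lin_all <- c(lin_brain, lin_wm, lin_csf)
  covariates <- tibble::as_tibble(
    read.delim(file.path(dir, "covariates.tsv"), sep = "\t")
  )
  seeds <- unique(manifest$partition$seed)
  seed_cols <- lapply(seeds, function(s) {
    m <- read_mask(paste0("seed_", s))
    match(which(m$data > 0), lin_all)
  })
  names(seed_cols) <- seeds
  subjects <- lapply(seq_len(nrow(covariates)), function(i) {
    sid <- covariates$subject_id[i]
    sess <- list()
    motion <- list()
    for (session in c("standard", "criticism")) {
      vol_path <- file.path(dir, paste0(sid, "_", session, ext))
      mot_path <- file.path(dir, paste0(sid, "_", session, "_motion.txt"))
      if (!file.exists(vol_path)) {
        stop("missing session volume for ", sid, ": ", vol_path)
      }
      if (!file.exists(mot_path)) {
        stop("missing motion file for ", sid, ": ", mot_path)
      }
      v <- read_volume(vol_path)
      T_ <- dim(v$data)[4]
      Y <- matrix(NA_real_, T_, length(lin_all))
      step <- prod(grid$shape)
      for (t in seq_len(T_)) {
        Y[t, ] <- v$data[lin_all + (t - 1L) * step]
      }
      sess[[session]] <- Y
      motion[[session]] <- as.matrix(read.table(mot_path))
    }
    list(subject_id = sid, sessions = sess, motion = motion)
  })
  structure(
    list(
      config = cfg, grid = grid, subjects = subjects,
      covariates = covariates,
      voxel_index = linear_to_index(grid, lin_all),
      brain_cols = seq_along(lin_brain),
      wm_cols = length(lin_brain) + seq_along(lin_wm),
      csf_cols = length(lin_brain) + length(lin_wm) + seq_along(lin_csf),
      seed_cols = seed_cols,
      truth = manifest
    ),
    class = "seedfc_cohort"
  )
}
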