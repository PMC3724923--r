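#' Synthetic two-session resting-state cohorts
#'
#' The generator emulates the study design the analysis assumes: each
#' subject contributes two eyes-closed resting sessions ("standard", then
#' "criticism", the second preceded by critical remarks), acquired on a
#' common 2 mm grid.  Voxel time series are built from band-limited
#' network time courses (0.01-0.06 Hz, inside the analysis pass-band)
#' whose coupling gain differs between sessions and is modulated by each
#' subject's centred neuroticism score, plus slow drift, a shared global
#' fluctuation, a motion-correlated component and white noise.  A truth
#' manifest records every planted quantity so downstream estimates can be
#' checked against ground truth.
#'
#' @name synthetic_data
NULL

#' Default planted seed-to-network grouping
#'
#' Thirteen seeds in four networks — a prefrontal pair, a fronto-temporal
#' triple, an occipito-parietal pair and a subcortical
#' amygdala/hippocampal quadruple — plus two seeds (ACC, SFG_BA10) with
#' mixed 50/50 loading on the first two networks.
#'
#' @return tibble with columns `seed`, `network`, `weight`; weights per
#'   seed sum to 1.
#' @export
default_partition <- function() {
  tibble::tribble(
    ~seed,       ~network, ~weight,
    "SFG_BA9",   1L, 1.0,
    "L_SFG",     1L, 1.0,
    "L_IFG",     2L, 1.0,
    "L_Ins",     2L, 1.0,
    "L_TP",      2L, 1.0,
    "PCC_Prec",  3L, 1.0,
    "Cun",       3L, 1.0,
    "L_Amy",     4L, 1.0,
    "R_Amy",     4L, 1.0,
    "L_Hip",     4L, 1.0,
    "R_Hip",     4L, 1.0,
    "ACC",       1L, 0.5,
    "ACC",       2L, 0.5,
    "SFG_BA10",  1L, 0.5,
    "SFG_BA10",  2L, 0.5
  )
}

#' Configure a synthetic cohort
#'
#' Defaults are the desk-scale study conditions: 12 subjects (2:1
#' women:men, mirroring the 32/16 split of the emulated cohort), a
#' 24 x 28 x 24 grid at 2 mm, 150 volumes per session at TR 2 s, 13 seeds
#' in the 4-network grouping of [default_partition()] with two mixed
#' seeds.  Neuroticism scores are drawn with gender-specific means
#' (women 144.4 +/- 17.7, men 127.4 +/- 21.6, NEO-PI-R-like).
#'
#' @param n_subjects number of subjects.
#' @param grid_shape voxels per axis (length 3).
#' @param voxel_size_mm isotropic voxel edge, mm.
#' @param n_volumes volumes per session (>= 20).
#' @param tr_s repetition time, seconds.
#' @param planted_partition tibble (`seed`, `network`, `weight`); weights
#'   per seed must sum to 1.
#' @param session_effect per-network coupling-gain difference
#'   (criticism - standard), length = number of networks.
#' @param covariate_slope per-network modulation of the session effect
#'   per point of centred neuroticism.
#' @param target_radii list (one element per network) of sphere radii
#'   (mm) for the network's anticorrelated target regions.  The default
#'   sizes balance the variance share that each network contributes to
#'   the seed-profile matrix given the unequal seed counts (2/3/2/4 plus
#'   two mixed seeds), so no single network dominates the eigenvalue
#'   spectrum.
#' @param base_gain coupling gain common to both sessions.
#' @param noise_sd white-noise standard deviation, BOLD units.
#' @param drift_amp,global_amp,motion_amp amplitudes of the slow drift,
#'   shared global fluctuation and motion-correlated nuisance components.
#' @param seed_radius_mm radius of the planted seed (and network-target)
#'   spheres.
#' @param network_band frequency band of the network time courses, Hz;
#'   kept inside the analysis pass-band so planted signal survives
#'   filtering, and above the generator's nuisance spectra (drift,
#'   global, motion random walks concentrate below ~0.03 Hz) so nuisance
#'   regression removes nuisance rather than planted signal.
#' @param rng_seed integer seed; the same seed reproduces every array
#'   bit-for-bit.
#' @return a validated `seedfc_cohort_config`.
#' @export
cohort_config <- function(n_subjects = 12,
                          grid_shape = c(24, 28, 24),
                          voxel_size_mm = 2,
                          n_volumes = 150,
                          tr_s = 2,
                          planted_partition = default_partition(),
                          session_effect = c(0.8, 0.8, -0.8, 0.6),
                          covariate_slope = c(0.0064, 0.0064, -0.0064, 0.0048),
                          target_radii = list(6.5, c(6, 6), 4, 6),
                          base_gain = 1.8,
                          noise_sd = 0.5,
                          drift_amp = 0.5,
                          global_amp = 0.3,
                          motion_amp = 0.2,
                          seed_radius_mm = 6,
                          network_band = c(0.03, 0.07),
                          rng_seed = 1) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    grid_shape = as.integer(grid_shape),
    voxel_size_mm = voxel_size_mm,
    n_volumes = as.integer(n_volumes),
    tr_s = tr_s,
    planted_partition = tibble::as_tibble(planted_partition),
    session_effect = session_effect,
    covariate_slope = covariate_slope,
    base_gain = base_gain,
    target_radii = target_radii,
    noise_sd = noise_sd,
    drift_amp = drift_amp,
    global_amp = global_amp,
    motion_amp = motion_amp,
    seed_radius_mm = seed_radius_mm,
    network_band = network_band,
    rng_seed = as.integer(rng_seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "seedfc_cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(
    cfg$n_subjects >= 2L, length(cfg$grid_shape) == 3L,
    cfg$n_volumes >= 20L, cfg$tr_s > 0, cfg$voxel_size_mm > 0
  )
  pp <- cfg$planted_partition
  stopifnot(all(c("seed", "network", "weight") %in% names(pp)))
  wsum <- tapply(pp$weight, pp$seed, sum)
  if (any(abs(wsum - 1) > 1e-9)) {
    stop(
      "planted_partition weights must sum to 1 per seed; offending: ",
      paste(names(wsum)[abs(wsum - 1) > 1e-9], collapse = ", ")
    )
  }
  n_net <- max(pp$network)
  if (length(cfg$session_effect) != n_net ||
      length(cfg$covariate_slope) != n_net) {
    stop(
      "session_effect and covariate_slope must have one entry per network (",
      n_net, ")"
    )
  }
  if (length(cfg$target_radii) != n_net) {
    stop("target_radii must have one element per network (", n_net, ")")
  }
  # the layout itself errors (naming the seed) if spheres do not fit
  invisible(cohort_layout(cfg))
  invisible(cfg)
}

# Deterministic spatial layout: seed spheres, one target sphere per
# network, and WM/CSF blobs on a lattice spaced so all spheres are
# disjoint and stay inside the brain box (grid minus a 1-voxel shell).
cohort_layout <- function(cfg) {
  grid <- make_grid(cfg$grid_shape, cfg$voxel_size_mm)
  r_vox <- ceiling(cfg$seed_radius_mm / cfg$voxel_size_mm)
  margin <- r_vox + 1L
  spacing <- 2L * r_vox + 1L
  axes <- lapply(cfg$grid_shape, function(n) {
    hi <- n - 1L - margin
    if (hi < margin) integer(0) else seq(margin, hi, by = spacing)
  })
  cells <- as.matrix(expand.grid(i = axes[[1]], j = axes[[2]], k = axes[[3]]))
  seeds <- unique(cfg$planted_partition$seed)
  n_net <- max(cfg$planted_partition$network)
  n_targets <- sum(lengths(cfg$target_radii))
  n_needed <- length(seeds) + n_targets + 2L
  if (nrow(cells) < n_needed) {
    short <- c(
      seeds,
      rep(paste0("target_net", seq_len(n_net)), lengths(cfg$target_radii)),
      "wm", "csf"
    )
    stop(
      "grid too small: no room for seed sphere '",
      short[min(nrow(cells) + 1L, n_needed)],
      "' (", nrow(cells), " lattice cells for ", n_needed, " regions)"
    )
  }
  centers_mm <- index_to_mm(grid, cells)
  idx <- seq_along(seeds)
  tgt_rows <- length(seeds) + seq_len(n_targets)
  tgt_net <- rep(seq_len(n_net), lengths(cfg$target_radii))
  list(
    grid = grid,
    seed_center_mat = centers_mm[idx, , drop = FALSE],
    target_center_mat = centers_mm[tgt_rows, , drop = FALSE],
    target_net = tgt_net,
    target_radius = unlist(cfg$target_radii),
    wm_center = cells[length(seeds) + n_targets + 1L, ],
    csf_center = cells[length(seeds) + n_targets + 2L, ]
  )
}

# random series with support only on DFT bins inside [low, high] Hz,
# standardised to exactly unit sd (stays unit after an ideal band-pass
# covering the band)
band_limited_series <- function(T_, tr_s, low_hz, high_hz) {
  ks <- seq_len(floor(T_ / 2) - 1L)
  f <- ks / (T_ * tr_s)
  ks <- ks[f >= low_hz & f <= high_hz]
  if (length(ks) == 0L) stop("band contains no DFT bins at this length/TR")
  z <- complex(length.out = T_)
  coef <- complex(real = rnorm(length(ks)), imaginary = rnorm(length(ks)))
  z[ks + 1L] <- coef
  z[T_ + 1L - ks] <- Conj(coef)
  x <- Re(fft(z, inverse = TRUE)) / T_
  x / sd(x)
}

# Orthonormal basis of the DFT bins inside [low, high] Hz (cos/sin pairs)
band_basis <- function(T_, tr_s, low_hz, high_hz) {
  ks <- seq_len(floor(T_ / 2) - 1L)
  f <- ks / (T_ * tr_s)
  ks <- ks[f >= low_hz & f <= high_hz]
  if (length(ks) == 0L) stop("band contains no DFT bins at this length/TR")
  tt <- seq_len(T_) - 1L
  B <- do.call(cbind, lapply(ks, function(k) {
    cbind(cos(2 * pi * k * tt / T_), sin(2 * pi * k * tt / T_))
  }))
  sweep(B, 2L, sqrt(colSums(B^2)), "/")
}

# n_net unit-sd network time courses drawn from the in-band subspace
# orthogonal to the session's nuisance design (and to each other), so
# the analysis pipeline — nuisance regression, detrend, band-pass — is
# exactly transparent to the planted dynamics: whatever survives those
# projections is all a seed GLM can ever recover, and the generator
# plants its signal there.  Mutual orthogonality makes the planted
# cross-network connectivity exactly zero (the band holds only ~26 real
# degrees of freedom, so independent draws would carry spurious
# correlations of order 0.2).
network_series <- function(T_, tr_s, n_net, band, nuisance = NULL) {
  B <- band_basis(T_, tr_s, band[1], band[2])
  raw <- matrix(rnorm(ncol(B) * n_net), ncol(B), n_net)
  if (!is.null(nuisance)) {
    C <- crossprod(B, as.matrix(nuisance))
    keep <- sqrt(colSums(C^2)) > 1e-10
    if (any(keep)) raw <- qr.resid(qr(C[, keep, drop = FALSE]), raw)
  }
  if (qr(raw)$rank < n_net) {
    stop("nuisance design leaves fewer than n_net free in-band dimensions")
  }
  S <- B %*% qr.Q(qr(raw))[, seq_len(n_net), drop = FALSE]
  sweep(S, 2L, apply(S, 2L, sd), "/")
}

#' Generate a synthetic cohort
#'
#' @param config a [cohort_config()].
#' @return a `seedfc_cohort`: list with `config`, `grid`, per-subject
#'   session matrices (`subjects[[i]]$sessions$standard` /
#'   `$criticism`, each T x V over the analysis columns), motion tables,
#'   column bookkeeping (`brain_cols`, `wm_cols`, `csf_cols`, named
#'   `seed_cols`, `target_cols`, and the voxel index matrix
#'   `voxel_index`), a covariate tibble and the `truth` manifest.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "seedfc_cohort_config"))
  with_seed(config$rng_seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  lay <- cohort_layout(cfg)
  grid <- lay$grid
  pp <- cfg$planted_partition
  seeds <- unique(pp$seed)
  n_net <- max(pp$network)
  T_ <- cfg$n_volumes

  seed_rois <- lapply(seq_along(seeds), function(i) {
    build_sphere_roi(
      lay$seed_center_mat[i, ], cfg$seed_radius_mm, grid, name = seeds[i]
    )
  })
  names(seed_rois) <- seeds
  target_rois <- lapply(seq_along(lay$target_net), function(r) {
    build_sphere_roi(
      lay$target_center_mat[r, ], lay$target_radius[r], grid,
      name = paste0("target_net", lay$target_net[r], "_", r)
    )
  })
  blob <- function(center, half = 1L) {
    as.matrix(expand.grid(
      i = (center[1] - half):(center[1] + half),
      j = (center[2] - half):(center[2] + half),
      k = (center[3] - half):(center[3] + half)
    ))
  }
  wm_idx <- blob(lay$wm_center)
  csf_idx <- blob(lay$csf_center)

  # analysis columns: brain box (minus the WM/CSF blobs), then WM, then CSF
  shell <- 1L
  brain_all <- as.matrix(expand.grid(
    i = shell:(cfg$grid_shape[1] - 1L - shell),
    j = shell:(cfg$grid_shape[2] - 1L - shell),
    k = shell:(cfg$grid_shape[3] - 1L - shell)
  ))
  lin_brain <- index_to_linear(grid, brain_all)
  lin_wm <- index_to_linear(grid, wm_idx)
  lin_csf <- index_to_linear(grid, csf_idx)
  lin_brain <- setdiff(lin_brain, c(lin_wm, lin_csf))
  lin_all <- c(lin_brain, lin_wm, lin_csf)
  voxel_index <- linear_to_index(grid, lin_all)
  Vb <- length(lin_brain)
  Vall <- length(lin_all)
  brain_cols <- seq_len(Vb)
  wm_cols <- Vb + seq_along(lin_wm)
  csf_cols <- Vb + length(lin_wm) + seq_along(lin_csf)
  col_of <- function(roi) {
    match(index_to_linear(grid, roi$voxel_indices), lin_all)
  }
  seed_cols <- lapply(seed_rois, col_of)
  target_cols <- lapply(seq_len(n_net), function(j) {
    unlist(lapply(target_rois[lay$target_net == j], col_of), use.names = FALSE)
  })

  # V x n_net loading matrix: seed voxels carry their seed's network
  # weights; each network's target sphere carries loading 1
  L <- matrix(0, Vall, n_net)
  for (s in seeds) {
    rows <- pp[pp$seed == s, ]
    for (r in seq_len(nrow(rows))) {
      L[seed_cols[[s]], rows$network[r]] <- rows$weight[r]
    }
  }
  # each network's target sphere is an anticorrelated hub whose loading
  # balances the network's seed loadings, so the planted signal sums to
  # zero over the brain and survives global-signal regression untouched
  for (j in seq_len(n_net)) {
    L[target_cols[[j]], j] <- -sum(L[, j]) / length(target_cols[[j]])
  }

  # covariates: 2:1 women:men, gender-specific NEO-like neuroticism
  n_w <- round(2 / 3 * cfg$n_subjects)
  gender <- c(rep("F", n_w), rep("M", cfg$n_subjects - n_w))
  neuro <- round(ifelse(
    gender == "F", rnorm(cfg$n_subjects, 144.44, 17.72),
    rnorm(cfg$n_subjects, 127.38, 21.57)
  ))
  neuro_c <- center_within(neuro, gender)
  covariates <- tibble::tibble(
    subject_id = sprintf("sub-%02d", seq_len(cfg$n_subjects)),
    gender = gender,
    neuroticism = neuro
  )

  tt <- seq_len(T_)
  subjects <- vector("list", cfg$n_subjects)
  gains_tab <- list()
  net_tcs <- list()
  for (i in seq_len(cfg$n_subjects)) {
    sess <- list()
    motion <- list()
    for (session in c("standard", "criticism")) {
      is_crit <- session == "criticism"
      # nuisance structure first: drift (linear + quadratic), shared
      # global fluctuation, motion-correlated component, WM/CSF-specific
      # signals; the network series are then drawn orthogonal to all of
      # it (and to the drift shapes) within the pass-band
      lin <- seq(-1, 1, length.out = T_)
      quad <- lin^2 - mean(lin^2)
      drift <- cfg$drift_amp * (rnorm(1) * lin + rnorm(1) * quad)
      glob <- cfg$global_amp * band_limited_series(T_, cfg$tr_s, 0.005, 0.025)
      mot <- vapply(
        seq_len(6L), function(m) cumsum(rnorm(T_, 0, 0.02)), numeric(T_)
      )
      mot_comp <- cfg$motion_amp * rowMeans(scale(mot))
      wm_sig <- band_limited_series(T_, cfg$tr_s, 0.005, 0.028)
      csf_sig <- band_limited_series(T_, cfg$tr_s, 0.005, 0.028)
      nuis <- cbind(lin, quad, mot, glob, wm_sig, csf_sig)
      nuis <- cbind(nuis, apply(nuis, 2L, temporal_derivative))
      S <- network_series(T_, cfg$tr_s, n_net, cfg$network_band, nuis)
      g <- cfg$base_gain +
        (cfg$session_effect + cfg$covariate_slope * neuro_c[i]) * is_crit
      Y <- S %*% (t(L) * g)
      Y[, brain_cols] <- Y[, brain_cols] + drift + glob + mot_comp
      Y[, wm_cols] <- Y[, wm_cols] + drift + mot_comp + wm_sig
      Y[, csf_cols] <- Y[, csf_cols] + drift + mot_comp + csf_sig
      if (cfg$noise_sd > 0) {
        Y <- Y + matrix(rnorm(T_ * Vall, 0, cfg$noise_sd), T_, Vall)
      }
      sess[[session]] <- Y
      motion[[session]] <- mot
      net_tcs[[paste(i, session)]] <- S
      gains_tab[[paste(i, session)]] <- tibble::tibble(
        subject_id = covariates$subject_id[i],
        session = session,
        network = seq_len(n_net),
        gain = g
      )
    }
    subjects[[i]] <- list(
      subject_id = covariates$subject_id[i],
      sessions = sess,
      motion = motion
    )
  }

  truth <- list(
    covariates = dplyr::mutate(covariates, neuro_centered = neuro_c),
    gains = dplyr::bind_rows(gains_tab),
    network_time_courses = net_tcs,
    seed_centers_mm = stats::setNames(
      asplit(lay$seed_center_mat, 1), seeds
    ),
    target_centers_mm = stats::setNames(
      asplit(lay$target_center_mat, 1),
      paste0("target_net", lay$target_net, "_", seq_along(lay$target_net))
    ),
    partition = pp,
    session_effect = cfg$session_effect,
    covariate_slope = cfg$covariate_slope,
    loading = L
  )

  structure(
    list(
      config = cfg,
      grid = grid,
      subjects = subjects,
      covariates = covariates,
      voxel_index = voxel_index,
      brain_cols = brain_cols,
      wm_cols = wm_cols,
      csf_cols = csf_cols,
      seed_cols = seed_cols,
      target_cols = target_cols,
      seed_rois = seed_rois,
      truth = truth
    ),
    class = "seedfc_cohort"
  )
}

center_within <- function(x, group) {
  x - stats::ave(x, group)
}

#' @export
print.seedfc_cohort <- function(x, ...) {
  cat(
    "<seedfc_cohort> ", x$config$n_subjects, " subjects x 2 sessions, ",
    x$config$n_volumes, " volumes @ TR ", x$config$tr_s, " s, grid ",
    paste(x$config$grid_shape, collapse = "x"), ", ",
    length(x$seed_cols), " seeds\n",
    sep = ""
  )
  invisible(x)
}

#' Reassemble a session matrix into a 4D volume
#'
#' @param cohort a `seedfc_cohort`.
#' @param subject subject index or id.
#' @param session `"standard"` or `"criticism"`.
#' @return 4D array on the cohort grid (out-of-mask voxels 0).
#' @export
cohort_volume <- function(cohort, subject, session) {
  if (is.character(subject)) {
    subject <- match(subject, cohort$covariates$subject_id)
  }
  Y <- cohort$subjects[[subject]]$sessions[[session]]
  lin <- index_to_linear(cohort$grid, cohort$voxel_index)
  T_ <- nrow(Y)
  vol <- array(0, c(cohort$grid$shape, T_))
  frame <- array(0, cohort$grid$shape)
  for (t in seq_len(T_)) {
    frame[lin] <- Y[t, ]
    vol[, , , t] <- frame
  }
  vol
}

#' Write a cohort to disk
#'
#' Emits one BIDS-like tree: per subject/session 4D NIfTI volumes and
#' whitespace-delimited T x 6 motion tables, 3D NIfTI masks (brain, WM,
#' CSF and one mask per seed), a covariate TSV
#' (`subject_id`, `gender`, `neuroticism`) and a JSON truth manifest of
#' every planted parameter.
#'
#' @param cohort a `seedfc_cohort`.
#' @param dir output directory (created).
#' @param gzip write `.nii.gz` (default) or plain `.nii`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, gzip = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  grid <- cohort$grid
  mask_vol <- function(cols) {
    v <- array(0L, grid$shape)
    lin <- index_to_linear(grid, cohort$voxel_index[cols, , drop = FALSE])
    v[lin] <- 1L
    v
  }
  write_volume(mask_vol(cohort$brain_cols), grid, file.path(dir, paste0("mask_brain", ext)))
  write_volume(mask_vol(cohort$wm_cols), grid, file.path(dir, paste0("mask_wm", ext)))
  write_volume(mask_vol(cohort$csf_cols), grid, file.path(dir, paste0("mask_csf", ext)))
  for (s in names(cohort$seed_cols)) {
    write_volume(
      mask_vol(cohort$seed_cols[[s]]), grid,
      file.path(dir, paste0("seed_", s, ext))
    )
  }
  for (i in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[i]]
    for (session in names(sub$sessions)) {
      base <- paste0(sub$subject_id, "_", session)
      write_volume(
        cohort_volume(cohort, i, session), grid,
        file.path(dir, paste0(base, ext)), tr_s = cohort$config$tr_s
      )
      write.table(
        sub$motion[[session]], file.path(dir, paste0(base, "_motion.txt")),
        row.names = FALSE, col.names = FALSE
      )
    }
  }
  write.table(
    cohort$covariates, file.path(dir, "covariates.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  manifest <- list(
    config = cohort$config[setdiff(names(cohort$config), "planted_partition")],
    partition = cohort$truth$partition,
    covariates = cohort$truth$covariates,
    gains = cohort$truth$gains,
    seed_centers_mm = cohort$truth$seed_centers_mm,
    target_centers_mm = cohort$truth$target_centers_mm
  )
  jsonlite::write_json(
    manifest, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
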