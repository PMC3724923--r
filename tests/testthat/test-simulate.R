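test_that("cohort generation is bit-reproducible for a fixed seed", {
  cfg <- tiny_cohort_config(n_subjects = 3, rng_seed = 12)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$subjects[[2]]$sessions$criticism,
    b$subjects[[2]]$sessions$criticism)
  expect_identical(a$subjects[[3]]$motion, b$subjects[[3]]$motion)
  expect_identical(a$covariates, b$covariates)
  # and a different seed gives different data
  c_ <- generate_cohort(tiny_cohort_config(n_subjects = 3, rng_seed = 13))
  expect_false(identical(a$subjects[[1]]$sessions$standard,
    c_$subjects[[1]]$sessions$standard))
})

test_that("written cohorts are byte-identical across repeated runs", {
  cfg <- tiny_cohort_config(n_subjects = 2, rng_seed = 5)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(generate_cohort(cfg), d1, gzip = FALSE)
  write_cohort(generate_cohort(cfg), d2, gzip = FALSE)
  f1 <- list.files(d1, pattern = "\\.nii$")
  expect_gt(length(f1), 0)
  for (f in f1) {
    expect_identical(
      unname(tools::md5sum(file.path(d1, f))),
      unname(tools::md5sum(file.path(d2, f))),
      info = f
    )
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- rnorm(3)
  set.seed(99)
  invisible(generate_cohort(tiny_cohort_config(n_subjects = 2)))
  expect_identical(rnorm(3), before)
})

test_that("planted loadings sum to zero over the brain (global-signal immunity)", {
  co <- generate_cohort(cohort_config(n_subjects = 2, rng_seed = 2))
  L <- co$truth$loading
  expect_lt(max(abs(colSums(L[co$brain_cols, , drop = FALSE]))), 1e-9)
  # WM/CSF compartments carry no network loading
  expect_true(all(L[c(co$wm_cols, co$csf_cols), ] == 0))
})

test_that("network time courses are unit-sd, in-band and nuisance-orthogonal", {
  co <- generate_cohort(cohort_config(n_subjects = 2, rng_seed = 3))
  S <- co$truth$network_time_courses[["1 criticism"]]
  expect_equal(apply(S, 2, sd), rep(1, 4), tolerance = 1e-10)
  expect_lt(max(abs(crossprod(S) - diag(diag(crossprod(S))))), 1e-8)
  # the analysis band-pass is transparent to them
  expect_lt(max(abs(bandpass(S, co$config$tr_s) - scale(S, scale = FALSE))), 1e-8)
  # and so is the session's motion regression
  mot <- co$subjects[[1]]$motion$criticism
  expect_lt(max(abs(crossprod(mot, S))), 1e-8)
})

test_that("neuroticism scores are gender-shifted at the configured effect size", {
  # calibration property across cohorts, not per cohort
  diffs <- vapply(1:20, function(r) {
    co <- generate_cohort(tiny_cohort_config(n_subjects = 12, rng_seed = 400 + r))
    cov <- co$covariates
    mean(cov$neuroticism[cov$gender == "F"]) -
      mean(cov$neuroticism[cov$gender == "M"])
  }, numeric(1))
  # planted means 144.4 (F) vs 127.4 (M): pooled difference detectable
  expect_gt(mean(diffs), 8)
  expect_lt(abs(mean(diffs) - 17.06), 3 * sd(diffs) / sqrt(length(diffs)))
  # centred scores have exact zero mean within gender
  co <- generate_cohort(tiny_cohort_config(n_subjects = 12, rng_seed = 1))
  tr <- co$truth$covariates
  expect_equal(as.numeric(tapply(tr$neuro_centered, tr$gender, mean)),
    c(0, 0), tolerance = 1e-9)
})

test_that("per-subject covariate slope is recoverable by an OLS oracle on the truth manifest", {
  cfg <- tiny_cohort_config(n_subjects = 12, rng_seed = 6)
  co <- generate_cohort(cfg)
  L <- co$truth$loading
  # recovered per-subject contrast values at planted voxels
  theta <- vapply(seq_len(12), function(i) {
    sub <- co$subjects[[i]]
    cl <- lapply(c("standard", "criticism"), function(ss) {
      preprocess_session(
        sub$sessions[[ss]], sub$motion[[ss]],
        wm_cols = co$wm_cols, csf_cols = co$csf_cols,
        brain_cols = co$brain_cols, tr_s = cfg$tr_s
      )
    })
    cm <- subject_contrasts(cl[[1]], cl[[2]], co$seed_cols)[, "seedA"]
    sum(cm * L[, 1]) / sum(L[, 1]^2)
  }, numeric(1))
  nu <- co$truth$covariates$neuro_centered
  fit <- summary(lm(theta ~ nu))
  est <- coef(fit)
  expect_lt(abs(est["nu", "Estimate"] - cfg$covariate_slope), 3 * est["nu", "Std. Error"])
})

test_that("invalid configurations fail with informative errors", {
  expect_error(
    cohort_config(grid_shape = c(10, 10, 10)),
    "no room for seed sphere"
  )
  bad_pp <- default_partition()
  bad_pp$weight[1] <- 0.7
  expect_error(
    cohort_config(planted_partition = bad_pp),
    "sum to 1 per seed"
  )
  expect_error(
    cohort_config(session_effect = c(1, 1)),
    "one entry per network"
  )
  expect_error(
    cohort_config(target_radii = list(6, 6)),
    "one element per network"
  )
  expect_error(cohort_config(n_volumes = 10), "n_volumes")
})
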