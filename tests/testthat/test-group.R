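test_that("second-level design centres neuroticism within gender", {
  cov <- tibble::tibble(
    subject_id = sprintf("s%d", 1:4),
    gender = c("F", "F", "M", "M"),
    neuroticism = c(140, 150, 120, 130)
  )
  des <- build_design(cov)
  expect_equal(unname(des$X[, "neuro"]), c(-5, 5, -5, 5))
  # per-gender means of the centred column are exactly zero
  expect_equal(as.numeric(tapply(des$X[, "neuro"], cov$gender, mean)), c(0, 0))
  expect_equal(des$df, 4 - 3)

  # mean-session contrast is unaffected by shifting all scores
  cov2 <- dplyr::mutate(cov, neuroticism = neuroticism + 37)
  expect_equal(build_design(cov2)$X, des$X)

  expect_error(
    build_design(dplyr::mutate(cov, neuroticism = 140)),
    "rank deficient"
  )
  expect_warning(
    des1 <- build_design(cov[cov$gender == "F", ][rep(1:2, 3), ]),
    "single-gender"
  )
  expect_false("gender" %in% colnames(des1$X))
})

test_that("voxelwise t maps match the closed-form one-sample t", {
  des <- list(X = matrix(1, 5, 1), df = 4)
  out <- second_level_glm(matrix(1:5, ncol = 1), des, 1)
  expect_equal(out$t, 4.2426, tolerance = 1e-4)   # mean/(sd/sqrt(n))
  expect_equal(out$df, 4)

  sym <- matrix(c(-2, -1, 0, 1, 2), ncol = 1)
  expect_equal(second_level_glm(sym, des, 1)$t, 0)

  # zero residual variance is flagged NA, finite voxels keep t
  maps <- cbind(rep(3, 5), 1:5)
  out2 <- second_level_glm(maps, des, 1)
  expect_true(is.na(out2$t[1]))
  expect_false(is.na(out2$t[2]))
})

test_that("t-to-z conversion matches printed peak-table pairs at df = 45", {
  expect_equal(t_to_z(5.45, 45), 4.74, tolerance = 0.05)
  expect_equal(t_to_z(6.30, 45), 5.29, tolerance = 0.05)
  expect_equal(t_to_z(0, 17), 0)
  expect_equal(t_to_z(1.96, 1e6), 1.96, tolerance = 1e-3)
  # strictly monotone and odd, finite in extreme tails
  ts <- seq(-8, 8, by = 0.25)
  zs <- t_to_z(ts, 45)
  expect_true(all(diff(zs) > 0))
  expect_equal(zs, -rev(zs), tolerance = 1e-10)
  expect_true(is.finite(t_to_z(60, 10)))
})

test_that("the 13-seed Bonferroni flag uses a strict 0.05/13 threshold", {
  expect_true(bonferroni_seeds(0.002))
  expect_false(bonferroni_seeds(0.004))
  expect_false(bonferroni_seeds(0.05, n_seeds = 1))   # strict <
  expect_true(bonferroni_seeds(0.049, n_seeds = 1))
  expect_error(bonferroni_seeds(1.4), "fwe_p")
})

test_that("26-connectivity clustering merges corner-touching voxels and applies the extent rule", {
  grid <- make_grid(c(12, 12, 10), 2)
  # two voxels touching only at a corner: one component under 26-connectivity
  idx <- rbind(c(2, 2, 2), c(3, 3, 3), c(8, 8, 8))
  memb <- seedfc:::connected_components_26(idx, grid)
  expect_equal(memb[1], memb[2])
  expect_false(memb[1] == memb[3])

  # permutation FWE: a 15-voxel component is excluded when k_min = 20
  set.seed(2)
  n <- 12
  V <- prod(grid$shape)
  voxel_index <- as.matrix(expand.grid(i = 0:11, j = 0:11, k = 0:9))
  maps <- matrix(rnorm(n * V, sd = 0.1), n)
  blob <- which(voxel_index[, 1] %in% 2:6 & voxel_index[, 2] == 5 &
    voxel_index[, 3] %in% 3:5)   # 15 voxels
  maps[, blob] <- maps[, blob] + 3
  cov <- tibble::tibble(
    subject_id = sprintf("s%d", 1:n),
    gender = rep(c("F", "M"), each = 6),
    neuroticism = c(131:136, 120:125)
  )
  des <- build_design(cov)
  sm <- permutation_cluster_fwe(
    maps, des, des$contrasts$session_mean, n_perm = 120, rng_seed = 7,
    voxel_index = voxel_index, grid = grid, k_min = 20
  )
  expect_equal(nrow(sm$clusters), 0L)
  sm2 <- permutation_cluster_fwe(
    maps, des, des$contrasts$session_mean, n_perm = 120, rng_seed = 7,
    voxel_index = voxel_index, grid = grid, k_min = 10
  )
  expect_equal(sm2$clusters$k, 15L)
})

test_that("permutation FWE detects a strong planted blob and respects its preconditions", {
  set.seed(4)
  grid <- make_grid(c(12, 12, 10), 2)
  V <- prod(grid$shape)
  voxel_index <- as.matrix(expand.grid(i = 0:11, j = 0:11, k = 0:9))
  n <- 12
  maps <- matrix(rnorm(n * V), n)
  blob <- which(voxel_index[, 1] %in% 3:7 & voxel_index[, 2] %in% 4:8 &
    voxel_index[, 3] %in% 3:4)   # 50 voxels
  maps[, blob] <- maps[, blob] + 4  # effect >> noise
  cov <- tibble::tibble(
    subject_id = sprintf("s%d", 1:n),
    gender = rep(c("F", "M"), 6),
    neuroticism = round(seq(110, 160, length.out = n))
  )
  des <- build_design(cov)
  sm <- permutation_cluster_fwe(
    maps, des, des$contrasts$session_mean, n_perm = 199, rng_seed = 11,
    voxel_index = voxel_index, grid = grid
  )
  expect_gte(nrow(sm$clusters), 1L)
  expect_lt(sm$clusters$fwe_p[1], 0.05)
  expect_setequal(sm$clusters$voxels[[1]], blob)

  expect_error(
    permutation_cluster_fwe(maps, des, des$contrasts$session_mean,
      n_perm = 50, voxel_index = voxel_index, grid = grid),
    "n_perm >= 100"
  )
  expect_error(
    permutation_cluster_fwe(maps[1:5, ], list(X = matrix(1, 5, 1), df = 4),
      1, n_perm = 100, voxel_index = voxel_index, grid = grid),
    "attainable minimum FWE p"
  )
})

test_that("peak reporting keeps at most three maxima at least 8 mm apart", {
  grid <- make_grid(c(15, 15, 9), 2)
  voxel_index <- as.matrix(expand.grid(i = 0:14, j = 0:14, k = 0:8))
  t <- rep(0, nrow(voxel_index))
  lin <- function(i, j, k) which(voxel_index[, 1] == i &
    voxel_index[, 2] == j & voxel_index[, 3] == k)
  # two local maxima 6 mm apart -> only the stronger is reported
  # (background values distinct so no plateau voxel ties as a maximum)
  for (i in 4:10) t[lin(i, 7, 4)] <- 3 - 0.1 * abs(i - 5)
  t[lin(5, 7, 4)] <- 6
  t[lin(8, 7, 4)] <- 5
  pk <- seedfc:::cluster_peaks(
    t, which(t > 0), voxel_index, grid, max_peaks = 3, min_sep_mm = 8
  )
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$t, 6)

  # 10 mm apart -> both reported, strongest first
  t[lin(8, 7, 4)] <- 0
  t[lin(10, 7, 4)] <- 5
  pk2 <- seedfc:::cluster_peaks(
    t, which(t > 0), voxel_index, grid, max_peaks = 3, min_sep_mm = 8
  )
  expect_equal(pk2$t, c(6, 5))
})
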