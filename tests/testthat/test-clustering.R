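test_that("profile matrix rows are voxelwise subject means", {
  m <- rbind(c(1, 2, 3), c(3, 2, 1), c(2, 2, 2))
  D <- build_profile_matrix(list(a = m, b = m[1:2, ]))
  expect_equal(D["a", ], c(2, 2, 2))
  expect_equal(D["b", ], c(2, 2, 2))

  # +v / -v cancel
  v <- rnorm(5)
  expect_equal(
    unname(build_profile_matrix(list(s = rbind(v, -v)))[1, ]), rep(0, 5)
  )

  expect_error(build_profile_matrix(list(a = m, b = NULL)), "missing contrast map")
  expect_error(build_profile_matrix(list(a = m, b = m[, 1:2])), "different voxel sets")
})

test_that("eigen spectrum matches a dense decomposition oracle and the trace identity", {
  set.seed(31)
  D <- matrix(rnorm(5 * 50), 5)
  ev <- eigen_spectrum(D)
  # oracle: singular values of the centred, scaled voxel-by-seed matrix
  Dc <- t(scale(t(D), scale = FALSE))
  sv <- svd(t(Dc) / sqrt(ncol(D) - 1))$d^2
  expect_equal(ev, sort(sv, decreasing = TRUE), tolerance = 1e-10)
  expect_equal(sum(ev), sum(apply(D, 1, var)), tolerance = 1e-10)

  # duplicated rows limit the rank
  D4 <- rbind(D[1, ], D[1, ], D[2, ], D[3, ])
  expect_lte(sum(eigen_spectrum(D4) > 1e-10), 3)

  expect_warning(ev0 <- eigen_spectrum(matrix(2, 4, 30)), "constant")
  expect_equal(ev0, rep(0, 4))
})

test_that("profile log-likelihood model order finds the planted split", {
  # 13 eigenvalues: three large, ten small
  expect_equal(estimate_k_profile_loglik(c(10, 10, 10, rep(0.1, 10))), 3L)
  # independent explicit-likelihood oracle on a noisy spectrum
  set.seed(8)
  ev <- sort(c(rnorm(4, 50, 2), rnorm(9, 5, 2)), decreasing = TRUE)
  oracle <- function(ev) {
    p <- length(ev)
    ll <- sapply(1:(p - 1), function(q) {
      g1 <- ev[1:q]; g2 <- ev[(q + 1):p]
      s2 <- (sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)) / p
      -p / 2 * log(2 * pi * s2) -
        (sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)) / (2 * s2)
    })
    which.max(ll)
  }
  expect_equal(estimate_k_profile_loglik(ev), oracle(ev))
  expect_equal(estimate_k_profile_loglik(ev), 4L)

  expect_warning(k <- estimate_k_profile_loglik(rep(3, 6)), "equal")
  expect_equal(k, 1L)
})

test_that("scree rule takes the largest successive gap with smallest-q ties", {
  expect_equal(estimate_k_scree(c(10, 10, 10, 0.1, 0.05, 0.01)), 3L)
  # geometric decay: the first gap is always the largest
  expect_equal(estimate_k_scree(10 * 0.5^(0:7)), 1L)
  # exact tie breaks to the smallest q
  expect_equal(estimate_k_scree(c(6, 4, 2, 0)), 1L)
})

test_that("fuzzy c-means separates far groups and obeys its invariants", {
  set.seed(41)
  g1 <- matrix(rnorm(4 * 10, 0, 0.1), 4)
  g2 <- matrix(rnorm(3 * 10, 10, 0.1), 3)
  D <- rbind(g1, g2)
  rownames(D) <- paste0("s", 1:7)
  fit <- fcm(D, 2, rng_seed = 3)
  # own-cluster memberships >= 0.95 and centroids near group means
  own <- apply(fit$U, 2, max)
  expect_true(all(own >= 0.95))
  cl1 <- which.max(fit$U[, 1])
  expect_equal(
    sort(fit$centroids[, 1]),
    sort(c(mean(g1[, 1]), mean(g2[, 1]))),
    tolerance = 0.05
  )
  # memberships column-normalised, objective non-increasing
  expect_equal(unname(colSums(fit$U)), rep(1, 7), tolerance = 1e-9)
  expect_true(all(diff(fit$objective_trace) <= 1e-8))

  # c = 1 degenerates to all-ones
  expect_equal(unname(fcm(D, 1)$U[1, ]), rep(1, 7))

  # coincident rows take membership 1 by the limit rule
  D0 <- rbind(c(0, 0), c(0, 0), c(10, 10))
  f0 <- fcm(D0, 2, rng_seed = 1)
  expect_equal(max(f0$U[, 1]), 1)
  expect_equal(max(f0$U[, 3]), 1)

  expect_error(fcm(D, 9), "c < n")
})

test_that("fcm objective is non-increasing on random problems", {
  set.seed(55)
  for (rep in 1:5) {
    D <- matrix(rnorm(10 * 20), 10)
    fit <- fcm(D, 3, rng_seed = rep, n_init = 3)
    expect_true(all(diff(fit$objective_trace) <= 1e-8))
    expect_equal(colSums(fit$U), rep(1, 10), tolerance = 1e-9)
  }
})

test_that("fcm agrees with an independent reference implementation", {
  set.seed(61)
  D <- rbind(
    matrix(rnorm(5 * 8, 0, 0.5), 5),
    matrix(rnorm(4 * 8, 6, 0.5), 4)
  )
  fit <- fcm(D, 2, rng_seed = 2)
  ref <- e1071::cmeans(D, centers = 2, m = 2, iter.max = 200)
  # same crisp partition up to relabelling
  expect_equal(
    adjusted_rand(apply(fit$U, 2, which.max), ref$cluster), 1
  )
  # same converged objective: evaluate J_m = sum u^m d^2 on the
  # reference fit's memberships and centroids with our own formula
  d2 <- outer(
    rowSums(ref$centers^2), rowSums(D^2), "+"
  ) - 2 * ref$centers %*% t(D)
  j_ref <- sum(t(ref$membership)^2 * pmax(d2, 0))
  expect_equal(fit$objective, j_ref, tolerance = 1e-3)
})

test_that("cluster assignment flags dual memberships by the top-two gap", {
  U <- cbind(
    c(0.5, 0.5, 0, 0),
    c(0.9, 0.05, 0.03, 0.02),
    c(0.45, 0.31, 0.14, 0.10)
  )
  colnames(U) <- c("a", "b", "c")
  asg <- assign_clusters(U, dual_gap = 0.15)
  expect_equal(unname(asg$dual), c(TRUE, FALSE, TRUE))  # 0.45-0.31 = 0.14 < 0.15
  expect_equal(unname(asg$cluster), c(1L, 1L, 1L))
  expect_equal(unname(asg$second_cluster[1]), 2L)
})

test_that("seed similarity graph is a Pearson correlation structure", {
  set.seed(71)
  D <- matrix(rnorm(4 * 30), 4)
  rownames(D) <- paste0("s", 1:4)
  g <- seed_similarity_graph(D)
  # direct covariance / sd-product oracle
  oracle <- function(a, b) cov(a, b) / (sd(a) * sd(b))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(g$cor[i, j], oracle(D[i, ], D[j, ]), tolerance = 1e-10)
  }
  expect_equal(diag(g$cor), rep(1, 4), ignore_attr = TRUE)
  expect_equal(g$cor, t(g$cor))
  expect_equal(nrow(g$edges), 6L)

  D2 <- rbind(a = D[1, ], b = D[1, ], c = -D[1, ])
  g2 <- seed_similarity_graph(D2)
  expect_equal(g2$cor["a", "b"], 1)
  expect_equal(g2$cor["a", "c"], -1)

  D3 <- rbind(a = D[1, ], b = rep(2, 30))
  expect_true(is.na(seed_similarity_graph(D3)$cor["a", "b"]))
})

test_that("adjusted Rand index is label-permutation invariant", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjusted_rand(a, a), 1)
  expect_equal(adjusted_rand(a, c(3, 3, 1, 1, 2, 2)), 1)
  expect_lt(adjusted_rand(a, c(1, 2, 3, 1, 2, 3)), 0.5)
})

test_that("clustering the neuroticism-slope maps reproduces the session-contrast solution", {
  dc <- default_run_cached()
  co <- dc$cohort; run <- dc$run
  nu <- co$truth$covariates$neuro_centered
  sxx <- sum(nu^2)
  slope_maps <- lapply(run$contrasts, function(M) drop(crossprod(M, nu)) / sxx)
  D_slope <- build_profile_matrix(slope_maps)
  ev <- eigen_spectrum(D_slope)
  expect_equal(estimate_k_profile_loglik(ev), 4L)
  expect_equal(estimate_k_scree(ev), 4L)
  part_contrast <- assign_clusters(fcm(run$D, 4, rng_seed = 5))
  part_slope <- assign_clusters(fcm(D_slope, 4, rng_seed = 5))
  expect_equal(
    adjusted_rand(part_contrast$cluster, part_slope$cluster), 1
  )
})
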