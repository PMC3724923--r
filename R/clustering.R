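#' Clustering seed regions by their connectivity profiles
#'
#' The group-average contrast maps of the seeds are stacked into a matrix
#' `D` (rows = seeds, columns = in-mask voxels).  The number of
#' components is estimated from the eigenvalues of the seed-by-seed
#' covariance of `D` by two rules — the largest scree gap and the maximum
#' profile log-likelihood — and fuzzy c-means groups the seeds, with
#' graded memberships in `[0, 1]` and a dual-membership flag for seeds
#' loading on two clusters.  Pairwise Pearson correlations between seed
#' profiles give the weighted seed-similarity graph.
#'
#' @name network_clustering
NULL

#' Build the seed-profile matrix D
#'
#' @param contrast_maps named list (one element per seed) of
#'   n_subjects x V matrices of per-subject contrast values on a shared
#'   voxel set, or of length-V vectors already averaged.
#' @return `n_seeds x V` matrix; row s is the voxelwise mean over
#'   subjects of seed s's contrast map.
#' @export
build_profile_matrix <- function(contrast_maps) {
  stopifnot(length(contrast_maps) >= 1L, !is.null(names(contrast_maps)))
  rows <- lapply(names(contrast_maps), function(s) {
    m <- contrast_maps[[s]]
    if (is.null(m)) stop("missing contrast map for seed '", s, "'")
    if (is.matrix(m)) {
      if (anyNA(m)) stop("contrast map for seed '", s, "' has missing values")
      colMeans(m)
    } else {
      if (anyNA(m)) stop("contrast map for seed '", s, "' has missing values")
      as.numeric(m)
    }
  })
  V <- unique(lengths(rows))
  if (length(V) != 1L) stop("contrast maps are on different voxel sets")
  D <- do.call(rbind, rows)
  rownames(D) <- names(contrast_maps)
  D
}

#' Eigenvalue spectrum of the seed-profile covariance
#'
#' Eigenvalues of the seed-by-seed covariance of `D` over voxels (voxels
#' as observations, seeds as variables), sorted descending.  The trace
#' identity `sum(lambda) = sum of per-seed variances` holds by
#' construction.
#'
#' @param D seed-profile matrix from [build_profile_matrix()].
#' @return numeric vector of `n_seeds` eigenvalues, descending.
#' @export
eigen_spectrum <- function(D) {
  stopifnot(nrow(D) >= 2L)
  C <- stats::cov(t(D))
  if (all(abs(C) < 1e-300)) {
    warning("constant profile matrix: all-zero spectrum")
    return(rep(0, nrow(D)))
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  sort(pmax(ev, 0), decreasing = TRUE)
}

#' Model order by maximum profile log-likelihood
#'
#' For each split `q` the ordered eigenvalues are modelled as two
#' Gaussian groups (first `q`, remaining `p - q`) with separate means and
#' a pooled maximum-likelihood variance; the returned `q` maximises the
#' summed log-likelihood over `q = 1 .. p-1`.
#'
#' @param eigenvalues descending eigenvalue vector (length >= 3).
#' @return integer component count.
#' @export
estimate_k_profile_loglik <- function(eigenvalues) {
  ev <- as.numeric(eigenvalues)
  p <- length(ev)
  stopifnot(p >= 3L)
  if (max(ev) - min(ev) < 1e-12 * max(abs(ev), 1)) {
    warning("all eigenvalues equal: returning 1")
    return(1L)
  }
  ll <- vapply(seq_len(p - 1L), function(q) {
    g1 <- ev[seq_len(q)]
    g2 <- ev[(q + 1L):p]
    s2 <- (sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)) / p
    if (s2 <= 0) return(Inf)  # perfect two-group fit
    sum(stats::dnorm(g1, mean(g1), sqrt(s2), log = TRUE)) +
      sum(stats::dnorm(g2, mean(g2), sqrt(s2), log = TRUE))
  }, numeric(1))
  which.max(ll)
}

#' Model order by the scree gap
#'
#' Cattell's elbow operationalised as the split with the largest
#' successive eigenvalue drop `lambda_q - lambda_{q+1}`; ties break to
#' the smallest `q`.
#'
#' @param eigenvalues descending eigenvalue vector (length >= 3).
#' @return integer component count.
#' @export
estimate_k_scree <- function(eigenvalues) {
  ev <- as.numeric(eigenvalues)
  stopifnot(length(ev) >= 3L)
  which.max(-diff(ev))
}

#' Fuzzy c-means clustering of seed profiles
#'
#' Standard alternating FCM: memberships
#' `u_ij = 1 / sum_k (d_ij / d_kj)^(2/(m-1))`, centroids the
#' `u^m`-weighted row means, iterated until the objective
#' `J_m = sum u^m d^2` changes by less than `tol`.  Because FCM is
#' sensitive to initialisation, `n_init` seeded random restarts are run
#' and the lowest-objective fit kept.  A seed exactly coincident with a
#' centroid receives membership 1 for that cluster (limit rule).
#'
#' @param D seed-profile matrix (rows clustered).
#' @param c number of clusters, `2 <= c < nrow(D)` (`c = 1` returns the
#'   trivial all-ones membership).
#' @param m fuzzifier, > 1 (default 2).
#' @param tol objective-change convergence tolerance.
#' @param max_iter iteration cap per restart.
#' @param n_init random restarts.
#' @param rng_seed seed for the restarts.
#' @return a `seedfc_fcm`: list with `U` (c x n_seeds memberships,
#'   columns sum to 1), `centroids` (c x V), `objective` (best final
#'   value), `objective_trace` (per iteration of the best restart),
#'   `iterations`, `c`, `m`.
#' @export
fcm <- function(D, c, m = 2, tol = 1e-6, max_iter = 500, n_init = 20,
                rng_seed = 1) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(m > 1, c >= 1, c < n || c == 1)
  if (c == 1L) {
    U <- matrix(1, 1L, n, dimnames = list(NULL, rownames(D)))
    return(structure(
      list(
        U = U, centroids = matrix(colMeans(D), 1L),
        objective = sum(sweep(D, 2L, colMeans(D))^2),
        objective_trace = numeric(0), iterations = 0L, c = 1L, m = m
      ),
      class = "seedfc_fcm"
    ))
  }
  best <- NULL
  with_seed(rng_seed, {
    for (init in seq_len(n_init)) {
      U <- matrix(runif(c * n), c, n)
      U <- sweep(U, 2L, colSums(U), "/")
      fit <- fcm_once(D, U, c, m, tol, max_iter)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
  })
  colnames(best$U) <- rownames(D)
  structure(c(best, list(c = c, m = m)), class = "seedfc_fcm")
}

fcm_once <- function(D, U, c, m, tol, max_iter) {
  n <- nrow(D)
  row_sq <- rowSums(D^2)
  trace <- numeric(0)
  obj_prev <- Inf
  for (iter in seq_len(max_iter)) {
    W <- U^m
    centroids <- (W %*% D) / rowSums(W)
    d2 <- outer(rowSums(centroids^2), row_sq, "+") - 2 * centroids %*% t(D)
    d2 <- pmax(d2, 0)
    obj <- sum(W * d2)
    trace <- c(trace, obj)
    # membership update with the coincident-point limit rule
    zero <- d2 < .Machine$double.eps
    inv <- d2^(-1 / (m - 1))
    U <- sweep(inv, 2L, colSums(inv), "/")
    hit <- colSums(zero) > 0L
    if (any(hit)) {
      U[, hit] <- zero[, hit] / rep(colSums(zero)[hit], each = c)
    }
    if (abs(obj_prev - obj) < tol) break
    obj_prev <- obj
  }
  list(
    U = U, centroids = centroids, objective = obj,
    objective_trace = trace, iterations = iter
  )
}

#' @export
print.seedfc_fcm <- function(x, ...) {
  cat(
    "<seedfc_fcm> c = ", x$c, ", m = ", x$m, ", objective = ",
    signif(x$objective, 6), " after ", x$iterations, " iterations\n",
    sep = ""
  )
  invisible(x)
}

#' Crisp (and dual) cluster assignment from memberships
#'
#' Each seed goes to its argmax cluster; it is additionally assigned to
#' the runner-up when the top-two membership gap is below `dual_gap`
#' (mixed seeds loading on two clusters).
#'
#' @param fit a `seedfc_fcm` (or a bare membership matrix U).
#' @param dual_gap dual-membership gap threshold (default 0.15).
#' @return tibble with `seed`, `cluster` (argmax), `membership`,
#'   `second_cluster`, `second_membership`, `dual` (logical).
#' @export
assign_clusters <- function(fit, dual_gap = 0.15) {
  U <- if (inherits(fit, "seedfc_fcm")) fit$U else as.matrix(fit)
  seeds <- colnames(U)
  if (is.null(seeds)) seeds <- paste0("seed_", seq_len(ncol(U)))
  res <- lapply(seq_len(ncol(U)), function(j) {
    ord <- order(U[, j], decreasing = TRUE)
    top <- ord[1]
    second <- if (nrow(U) >= 2L) ord[2] else NA_integer_
    gap <- if (is.na(second)) Inf else U[top, j] - U[second, j]
    tibble::tibble(
      seed = seeds[j],
      cluster = unname(top),
      membership = unname(U[top, j]),
      second_cluster = unname(second),
      second_membership = unname(if (is.na(second)) NA_real_ else U[second, j]),
      dual = unname(gap < dual_gap)
    )
  })
  dplyr::bind_rows(res)
}

#' Seed-similarity correlation graph
#'
#' Pearson correlations between seed profile rows; the weighted edge
#' list (edge weight = correlation) is importable by graph tools.
#' A constant row has no defined correlations and is reported `NA`.
#'
#' @param D seed-profile matrix.
#' @return list with `cor` (n_seeds x n_seeds, diagonal 1, symmetric)
#'   and `edges` (tibble `source`, `target`, `weight`, each pair once).
#' @export
seed_similarity_graph <- function(D) {
  D <- as.matrix(D)
  sds <- apply(D, 1L, sd)
  C <- suppressWarnings(stats::cor(t(D)))
  C[sds < 1e-300, ] <- NA_real_
  C[, sds < 1e-300] <- NA_real_
  diag(C) <- 1
  nm <- rownames(D)
  if (is.null(nm)) nm <- paste0("seed_", seq_len(nrow(D)))
  dimnames(C) <- list(nm, nm)
  pairs <- which(upper.tri(C), arr.ind = TRUE)
  edges <- tibble::tibble(
    source = nm[pairs[, 1]],
    target = nm[pairs[, 2]],
    weight = C[pairs]
  )
  list(cor = C, edges = edges)
}

#' Adjusted Rand index between two partitions
#'
#' Label-permutation-invariant agreement between a recovered and a
#' planted partition; 1 means exact recovery up to relabelling.
#'
#' @param a,b integer/factor label vectors of equal length.
#' @return adjusted Rand index.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
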