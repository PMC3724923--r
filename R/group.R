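#' Second-level random-effects inference
#'
#' Per seed, the per-subject contrast maps enter a voxelwise OLS with
#' design `[intercept, gender, neuroticism]`: gender deviation-coded
#' (women -1/2, men +1/2, a factor of no interest) and neuroticism
#' centred separately within women and men, so the intercept is the
#' gender-balanced mean session effect and the neuroticism column tests
#' its modulation.  Family-wise error over voxels is controlled at
#' cluster level by permutation (sign flipping for the mean effect,
#' Freedman-Lane residual sign flipping for the covariate slope) with a
#' cluster-forming threshold of p < 0.001 (one-sided) and an extent rule
#' k > 20; a Bonferroni flag marks clusters surviving the 13-seed
#' correction 0.05/13 < 0.003.
#'
#' @name group_inference
NULL

#' Build the second-level design
#'
#' @param covariates tibble with `subject_id`, `gender` (`"F"`/`"M"`),
#'   `neuroticism`.
#' @return list with the design matrix `X` (columns `intercept`,
#'   `gender`, `neuro`), named contrast vectors (`session_mean`,
#'   `neuro_pos`, `neuro_neg`) and `df` = n - rank.
#' @export
build_design <- function(covariates) {
  stopifnot(all(c("subject_id", "gender", "neuroticism") %in% names(covariates)))
  n <- nrow(covariates)
  gender <- covariates$gender
  neuro_c <- center_within(covariates$neuroticism, gender)
  if (all(abs(neuro_c) < 1e-12)) {
    stop(
      "neuroticism is constant within gender: ",
      "the slope contrast is rank deficient"
    )
  }
  if (length(unique(gender)) < 2L) {
    warning("single-gender cohort: dropping the gender column")
    X <- cbind(intercept = rep(1, n), neuro = neuro_c)
    contrasts <- list(
      session_mean = c(1, 0), neuro_pos = c(0, 1), neuro_neg = c(0, -1)
    )
  } else {
    g <- ifelse(gender == "M", 0.5, -0.5)
    X <- cbind(intercept = rep(1, n), gender = g, neuro = neuro_c)
    contrasts <- list(
      session_mean = c(1, 0, 0), neuro_pos = c(0, 0, 1),
      neuro_neg = c(0, 0, -1)
    )
  }
  if (n < ncol(X) + 1L) stop("too few subjects for the second-level design")
  rk <- qr(X)$rank
  if (rk < ncol(X)) stop("second-level design is rank deficient")
  list(X = X, contrasts = contrasts, df = n - rk)
}

#' Voxelwise second-level t map
#'
#' OLS at every voxel; `t = c'beta / se(c'beta)` with
#' `df = n - rank(X)`.  Voxels with (numerically) zero residual variance
#' get `NA` and are excluded from clustering.
#'
#' @param maps n_subjects x V matrix of per-subject contrast values.
#' @param design a [build_design()] result (or any list with `X`, `df`).
#' @param contrast numeric contrast vector over design columns.
#' @return list with `t` (length V), `df`, `beta` (contrast estimate),
#'   `se`.
#' @export
second_level_glm <- function(maps, design, contrast) {
  maps <- as.matrix(maps)
  X <- design$X
  stopifnot(nrow(maps) == nrow(X), length(contrast) == ncol(X))
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, maps)            # p x V
  res <- maps - X %*% B
  df <- design$df
  sigma2 <- colSums(res^2) / df
  cb <- drop(crossprod(contrast, B))
  se <- sqrt(pmax(sigma2, 0) * drop(crossprod(contrast, XtXi %*% contrast)))
  t <- ifelse(se > sqrt(.Machine$double.eps), cb / se, NA_real_)
  list(t = t, df = df, beta = cb, se = se)
}

#' Convert t statistics to z scores
#'
#' Tail-matching transform: `z` has the same one-sided tail probability
#' under the standard normal as `t` under Student's t with `df` degrees
#' of freedom.  Computed on the log scale so extreme values do not
#' underflow; strictly monotone and odd in `t`.
#'
#' @param t numeric vector of t values.
#' @param df degrees of freedom (>= 1).
#' @return numeric vector of z values.
#' @examples
#' t_to_z(5.45, 45)  # ~4.75
#' @export
t_to_z <- function(t, df) {
  stopifnot(df >= 1)
  sgn <- sign(t)
  lp <- pt(abs(t), df, lower.tail = FALSE, log.p = TRUE)
  sgn * qnorm(lp, lower.tail = FALSE, log.p = TRUE)
}

#' Bonferroni flag across seeds
#'
#' @param fwe_p cluster-level FWE p value(s).
#' @param n_seeds number of seed regions tested (default 13, giving the
#'   0.05/13 < 0.003 threshold).
#' @return logical: `TRUE` iff `fwe_p < 0.05 / n_seeds` (strict).
#' @export
bonferroni_seeds <- function(fwe_p, n_seeds = 13) {
  stopifnot(all(fwe_p >= 0 & fwe_p <= 1))
  fwe_p < 0.05 / n_seeds
}

# Connected components of a suprathreshold voxel set under 26-neighbour
# connectivity (faces, edges, corners).  `index` is an n x 3 0-based
# integer matrix; returns an integer component label per row.
connected_components_26 <- function(index, grid) {
  n <- nrow(index)
  if (n == 0L) return(integer(0))
  lin <- index_to_linear(grid, index)
  pos <- integer(prod(grid$shape))
  pos[lin] <- seq_len(n)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
    (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), , drop = FALSE]
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    nb <- index + matrix(offs[r, ], n, 3, byrow = TRUE)
    ok <- in_grid(grid, nb)
    if (!any(ok)) next
    nb_pos <- pos[index_to_linear(grid, nb[ok, , drop = FALSE])]
    hit <- nb_pos > 0L
    if (any(hit)) {
      edges[[length(edges) + 1L]] <- cbind(which(ok)[hit], nb_pos[hit])
    }
  }
  if (length(edges) == 0L) return(seq_len(n))
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::components(g)$membership
}

# Maximum suprathreshold cluster extent of a t map (one-sided, t > thr),
# for the permutation null distribution.
max_cluster_extent <- function(t, thr, voxel_index, grid) {
  sup <- which(!is.na(t) & t > thr)
  if (length(sup) == 0L) return(0L)
  memb <- connected_components_26(voxel_index[sup, , drop = FALSE], grid)
  max(tabulate(memb))
}

#' Permutation cluster-extent FWE inference
#'
#' Clusters are connected components (26-neighbour) of voxels exceeding
#' the one-sided cluster-forming threshold `qt(1 - voxel_p, df)`; only
#' clusters with extent `k > k_min` are reported.  The FWE p value of a
#' cluster is the fraction of permutation null maximum cluster extents at
#' least as large as its own (with the observed map counted once).  The
#' null is built by sign flipping the subject maps when the tested
#' contrast is the intercept, and by Freedman-Lane sign flipping of
#' reduced-model residuals for covariate contrasts.
#'
#' @param maps n_subjects x V matrix of per-subject contrast values.
#' @param design a [build_design()] result.
#' @param contrast contrast vector (tested one-sided, in its direction).
#' @param voxel_p cluster-forming voxel-level p (default 0.001).
#' @param k_min extent threshold; clusters must exceed it (default 20).
#' @param n_perm number of permutations (>= 100).
#' @param rng_seed seed for the sign-flip draws.
#' @param voxel_index V x 3 0-based voxel indices of the map columns.
#' @param grid a [make_grid()] object.
#' @return a `seedfc_statmap`: list with `t`, `z`, `df`, `threshold`,
#'   `clusters` (tibble: `cluster_id`, `k`, `fwe_p`, `bonferroni`,
#'   `voxels` list-column), `null_max_extent`, plus the call parameters.
#' @export
permutation_cluster_fwe <- function(maps, design, contrast,
                                    voxel_p = 0.001, k_min = 20,
                                    n_perm = 1000, rng_seed = 1,
                                    voxel_index, grid) {
  stopifnot(n_perm >= 100)
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (n < 31 && n_perm >= 2^n) {
    stop(
      "too few subjects for ", n_perm, " distinct sign flips; ",
      "attainable minimum FWE p is ", signif(1 / 2^n, 3)
    )
  }
  obs <- second_level_glm(maps, design, contrast)
  thr <- qt(1 - voxel_p, obs$df)
  sup <- which(!is.na(obs$t) & obs$t > thr)
  clusters <- tibble::tibble(
    cluster_id = integer(), k = integer(), fwe_p = numeric(),
    bonferroni = logical(), voxels = list()
  )
  if (length(sup) > 0L) {
    memb <- connected_components_26(voxel_index[sup, , drop = FALSE], grid)
    sizes <- tabulate(memb)
    keep <- which(sizes > k_min)
    clusters <- tibble::tibble(
      cluster_id = seq_along(keep),
      k = sizes[keep],
      fwe_p = NA_real_,
      bonferroni = NA,
      voxels = lapply(keep, function(cl) sup[memb == cl])
    )
  }

  # Freedman-Lane: sign-flip the residuals of the reduced model (without
  # the tested column) and add back its fit; for the intercept contrast
  # the reduced projection leaves the maps themselves to be flipped.
  X <- design$X
  tested <- which(contrast != 0)
  if (length(tested) != 1L) stop("contrast must test a single design column")
  Xr <- X[, -tested, drop = FALSE]
  fit_r <- if (ncol(Xr) > 0L) {
    qr_r <- qr(Xr)
    qr.fitted(qr_r, maps)
  } else {
    matrix(0, n, ncol(maps))
  }
  res_r <- maps - fit_r

  null_max <- with_seed(rng_seed, {
    vapply(seq_len(n_perm), function(p) {
      flips <- sample(c(-1, 1), n, replace = TRUE)
      perm_maps <- fit_r + flips * res_r
      tp <- second_level_glm(perm_maps, design, contrast)$t
      max_cluster_extent(tp, thr, voxel_index, grid)
    }, numeric(1))
  })

  if (nrow(clusters) > 0L) {
    clusters$fwe_p <- vapply(
      clusters$k,
      function(k) (1 + sum(null_max >= k)) / (n_perm + 1),
      numeric(1)
    )
    clusters$bonferroni <- bonferroni_seeds(clusters$fwe_p)
    ord <- order(
      vapply(clusters$voxels, function(v) max(obs$t[v]), numeric(1)),
      decreasing = TRUE
    )
    clusters <- clusters[ord, ]
    clusters$cluster_id <- seq_len(nrow(clusters))
  }

  structure(
    list(
      t = obs$t, z = t_to_z(obs$t, obs$df), beta = obs$beta, df = obs$df,
      threshold = thr, clusters = clusters, null_max_extent = null_max,
      voxel_p = voxel_p, k_min = k_min, n_perm = n_perm,
      voxel_index = voxel_index, grid = grid
    ),
    class = "seedfc_statmap"
  )
}

#' @export
print.seedfc_statmap <- function(x, ...) {
  cat(
    "<seedfc_statmap> df = ", x$df, ", cluster-forming t > ",
    signif(x$threshold, 4), ", k > ", x$k_min, ": ",
    nrow(x$clusters), " cluster(s)\n",
    sep = ""
  )
  invisible(x)
}

# Local maxima of t within one cluster: voxels >= all their 26
# neighbours inside the cluster, thinned to `max_peaks` peaks pairwise
# >= min_sep_mm apart, strongest first.
cluster_peaks <- function(t, voxels, voxel_index, grid,
                          max_peaks = 3L, min_sep_mm = 8) {
  idx <- voxel_index[voxels, , drop = FALSE]
  tv <- t[voxels]
  n <- length(voxels)
  lin <- index_to_linear(grid, idx)
  val <- rep(-Inf, prod(grid$shape))
  val[lin] <- tv
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  is_max <- rep(TRUE, n)
  for (r in seq_len(nrow(offs))) {
    nb <- idx + matrix(offs[r, ], n, 3, byrow = TRUE)
    ok <- in_grid(grid, nb)
    nbv <- rep(-Inf, n)
    nbv[ok] <- val[index_to_linear(grid, nb[ok, , drop = FALSE])]
    is_max <- is_max & tv >= nbv
  }
  cand <- order(tv, decreasing = TRUE)
  cand <- cand[is_max[cand]]
  mm <- index_to_mm(grid, idx)
  picked <- integer(0)
  for (c_ in cand) {
    if (length(picked) == max_peaks) break
    if (length(picked) == 0L) {
      picked <- c_
      next
    }
    d <- sqrt(rowSums((
      mm[picked, , drop = FALSE] -
        matrix(mm[c_, ], length(picked), 3, byrow = TRUE)
    )^2))
    if (all(d >= min_sep_mm)) picked <- c(picked, c_)
  }
  tibble::tibble(
    peak = seq_along(picked),
    t = tv[picked],
    x_mm = mm[picked, 1], y_mm = mm[picked, 2], z_mm = mm[picked, 3]
  )
}

#' Cluster table for a stat map
#'
#' One row per reported peak (up to 3 local maxima per cluster, pairwise
#' >= 8 mm apart), blocks sorted by peak t descending — the familiar
#' peak-activation table layout with extent, t, z, mm coordinates,
#' cluster-level FWE p and the across-seed Bonferroni flag.
#'
#' @param statmap a `seedfc_statmap`.
#' @param seed_name optional seed label column.
#' @param max_peaks,min_sep_mm peak reporting rules.
#' @return tibble with columns `seed`, `cluster_id`, `k`, `peak`, `t`,
#'   `z`, `x_mm`, `y_mm`, `z_mm`, `fwe_p`, `bonferroni`.
#' @export
cluster_table <- function(statmap, seed_name = NA_character_,
                          max_peaks = 3L, min_sep_mm = 8) {
  cl <- statmap$clusters
  if (nrow(cl) == 0L) {
    return(tibble::tibble(
      seed = character(), cluster_id = integer(), k = integer(),
      peak = integer(), t = numeric(), z = numeric(),
      x_mm = numeric(), y_mm = numeric(), z_mm = numeric(),
      fwe_p = numeric(), bonferroni = logical()
    ))
  }
  rows <- purrr::pmap(cl, function(cluster_id, k, fwe_p, bonferroni, voxels) {
    pk <- cluster_peaks(
      statmap$t, voxels, statmap$voxel_index, statmap$grid,
      max_peaks = max_peaks, min_sep_mm = min_sep_mm
    )
    dplyr::mutate(
      pk,
      seed = seed_name, cluster_id = cluster_id, k = k,
      z = t_to_z(.data$t, statmap$df), fwe_p = fwe_p,
      bonferroni = bonferroni,
      .before = 1
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::select(
    out, "seed", "cluster_id", "k", "peak", "t", "z",
    "x_mm", "y_mm", "z_mm", "fwe_p", "bonferroni"
  )
}
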