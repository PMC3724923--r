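#' Seed eigenvariate extraction and first-level connectivity GLMs
#'
#' Each seed region is represented by the first eigenvariate of its voxel
#' time series — the first principal temporal component of the
#' column-demeaned T x n matrix — standardised to unit variance with the
#' sign pinned so that its mean covariance with the seed's voxels is
#' positive.  That time course enters a per-voxel GLM
#' `voxel ~ intercept + seed`, whose seed coefficient map is the
#' connectivity map; the criticism-minus-standard difference of the two
#' session maps is the subject's contrast map.
#'
#' @name seed_connectivity
NULL

#' First eigenvariate of an ROI's time series
#'
#' @param roi_series T x n matrix of voxel time courses (n >= 1, T > 3).
#' @return list with `values` (length-T, unit variance, sign-aligned) and
#'   `var_explained` (fraction of total variance carried).
#' @export
extract_eigenvariate <- function(roi_series) {
  X <- as.matrix(roi_series)
  if (nrow(X) <= 3L) stop("eigenvariate needs more than 3 time points")
  X <- sweep(X, 2L, colMeans(X))
  if (all(abs(X) < .Machine$double.eps * 1e3)) {
    stop("all-zero (or constant) ROI time series: no eigenvariate")
  }
  # first left singular vector via the smaller-side eigenproblem
  if (ncol(X) <= nrow(X)) {
    e <- eigen(crossprod(X), symmetric = TRUE)
    u <- X %*% e$vectors[, 1]
    lambda1 <- e$values[1]
  } else {
    e <- eigen(tcrossprod(X), symmetric = TRUE)
    u <- e$vectors[, 1]
    lambda1 <- e$values[1]
  }
  if (sum(crossprod(X, u)) < 0) u <- -u
  list(
    values = drop(u) / sd(u),
    var_explained = lambda1 / sum(X^2)
  )
}

#' Voxelwise seed-regression coefficients
#'
#' Per-voxel OLS of `Y` on `[intercept, seed_tc]`; because the seed time
#' course is standardised to unit variance upstream, the returned betas
#' are in BOLD units per seed standard deviation and are invariant to any
#' rescaling of the raw seed signal.
#'
#' @param Y T x V matrix of (cleaned) voxel time courses.
#' @param seed_tc length-T seed time course (standardised to unit
#'   variance when `standardize = TRUE`, the default).
#' @param standardize standardise `seed_tc` before fitting.
#' @return length-V vector of seed coefficients.
#' @export
first_level_beta <- function(Y, seed_tc, standardize = TRUE) {
  Y <- as.matrix(Y)
  s <- as.numeric(seed_tc)
  if (length(s) != nrow(Y)) stop("seed time course length does not match data")
  v <- var(s)
  if (v < .Machine$double.eps * 1e3) stop("zero-variance seed regressor")
  if (standardize) s <- (s - mean(s)) / sqrt(v)
  sc <- s - mean(s)
  drop(crossprod(Y, sc)) / sum(sc^2)
}

#' Between-session connectivity contrast
#'
#' @param beta_criticism,beta_standard length-V beta maps on the same
#'   voxel set (criticism and standard sessions of one subject/seed).
#' @return length-V contrast map `beta_criticism - beta_standard`.
#' @export
make_contrast <- function(beta_criticism, beta_standard) {
  if (length(beta_criticism) != length(beta_standard)) {
    stop("beta maps are on different voxel sets")
  }
  if (anyNA(beta_criticism) || anyNA(beta_standard)) {
    stop("beta maps contain missing values")
  }
  beta_criticism - beta_standard
}

#' Per-subject seed connectivity contrasts
#'
#' Convenience wrapper: for each seed, extract the session eigenvariates
#' from the cleaned data, fit the first-level GLMs and difference the
#' betas.
#'
#' @param clean_std,clean_crit T x V cleaned matrices for the standard and
#'   criticism sessions (same column/voxel order).
#' @param seed_cols named list mapping seed name -> column indices of the
#'   seed's voxels.
#' @return V x n_seeds matrix of contrast values (columns named by seed).
#' @export
subject_contrasts <- function(clean_std, clean_crit, seed_cols) {
  stopifnot(ncol(clean_std) == ncol(clean_crit))
  out <- vapply(seed_cols, function(cols) {
    tc_s <- extract_eigenvariate(clean_std[, cols, drop = FALSE])$values
    tc_c <- extract_eigenvariate(clean_crit[, cols, drop = FALSE])$values
    make_contrast(
      first_level_beta(clean_crit, tc_c),
      first_level_beta(clean_std, tc_s)
    )
  }, numeric(ncol(clean_std)))
  colnames(out) <- names(seed_cols)
  out
}
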