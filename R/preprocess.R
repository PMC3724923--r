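#' Temporal preprocessing of BOLD sessions
#'
#' Session-level cleaning follows the usual resting-state recipe, in this
#' fixed order: (1) ordinary-least-squares regression of nuisance series
#' (six rigid-body motion parameters, the global signal, white-matter and
#' CSF signals) together with their first temporal derivatives and an
#' intercept; (2) band-pass filtering that detrends and retains
#' 0.008-0.08 Hz.  An optional Gaussian spatial smoothing operator is
#' provided for volumes already resampled to a common grid.
#'
#' @name rs_preprocess
NULL

#' Backward-difference temporal derivative
#'
#' Element `t` is `x[t] - x[t-1]` with a leading zero, so the output keeps
#' length `T`.
#'
#' @param x numeric series of length >= 2.
#' @return numeric series, same length.
#' @examples
#' temporal_derivative(c(1, 3, 6))  # 0 2 3
#' @export
temporal_derivative <- function(x) {
  if (length(x) < 2L) stop("temporal_derivative() needs a series of length >= 2")
  c(0, diff(x))
}

#' Assemble the nuisance design matrix
#'
#' Columns: intercept, the nuisance series, and their backward-difference
#' derivatives.  Exact duplicate columns are dropped (keeping the first);
#' any remaining rank deficiency is an error naming the collinear columns.
#'
#' @param nuisance list with elements `motion` (T x 6 matrix),
#'   `global_signal`, `wm_signal`, `csf_signal` (length-T series).  Any
#'   element may be omitted.
#' @return numeric design matrix with named columns.
#' @export
nuisance_design <- function(nuisance) {
  cols <- list()
  if (!is.null(nuisance$motion)) {
    m <- as.matrix(nuisance$motion)
    stopifnot(ncol(m) == 6L)
    for (i in seq_len(6L)) cols[[paste0("motion", i)]] <- m[, i]
  }
  for (nm in c("global_signal", "wm_signal", "csf_signal")) {
    if (!is.null(nuisance[[nm]])) cols[[nm]] <- as.numeric(nuisance[[nm]])
  }
  if (length(cols) == 0L) stop("empty nuisance set")
  tlen <- unique(vapply(cols, length, integer(1)))
  if (length(tlen) != 1L) stop("nuisance series have unequal lengths")
  if (anyNA(unlist(cols))) stop("nuisance series contain missing values")
  derivs <- lapply(cols, temporal_derivative)
  names(derivs) <- paste0("d_", names(cols))
  X <- cbind(intercept = rep(1, tlen), do.call(cbind, cols), do.call(cbind, derivs))
  # drop exact duplicates (e.g. a constant series duplicating the intercept)
  dup <- duplicated(t(X))
  X <- X[, !dup, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop(
      "nuisance design is rank deficient after de-duplication; ",
      "collinear columns: ", paste(bad, collapse = ", ")
    )
  }
  X
}

#' Regress nuisance series out of voxel time courses
#'
#' Per-voxel OLS against [nuisance_design()]; returns residuals, which are
#' orthogonal to every retained design column.
#'
#' @param Y T x V matrix of voxel time series.
#' @param nuisance nuisance set, see [nuisance_design()]; alternatively a
#'   ready design matrix.
#' @return T x V residual matrix.
#' @export
regress_nuisance <- function(Y, nuisance) {
  Y <- as.matrix(Y)
  X <- if (is.matrix(nuisance)) nuisance else nuisance_design(nuisance)
  if (nrow(X) != nrow(Y)) stop("design and data have different numbers of volumes")
  Y - X %*% solve(crossprod(X), crossprod(X, Y))
}

#' Extract global / tissue nuisance signals
#'
#' The global signal is the mean time course over the brain mask; the
#' white-matter and CSF signals are the first eigenvariates of their
#' masks' voxel time series (see [extract_eigenvariate()]).
#'
#' @param Y T x V matrix over the brain mask (columns align with
#'   `brain_cols`).
#' @param brain_cols,wm_cols,csf_cols column indices of each compartment.
#' @return list with `global_signal`, `wm_signal`, `csf_signal`.
#' @export
nuisance_signals <- function(Y, brain_cols, wm_cols, csf_cols) {
  list(
    global_signal = rowMeans(Y[, brain_cols, drop = FALSE]),
    wm_signal = extract_eigenvariate(Y[, wm_cols, drop = FALSE])$values,
    csf_signal = extract_eigenvariate(Y[, csf_cols, drop = FALSE])$values
  )
}

#' Band-pass filter BOLD time courses
#'
#' Linear detrend followed by an ideal discrete-Fourier band-pass: every
#' frequency bin outside `[low_hz, high_hz]` (including DC) is zeroed, so
#' in-band sinusoids pass essentially unchanged and out-of-band components
#' are fully rejected.  Output columns have mean ~0.
#'
#' @param Y T x V matrix (or length-T vector).
#' @param tr_s repetition time, seconds.
#' @param low_hz,high_hz band edges in Hz; `high_hz` must stay below the
#'   Nyquist frequency `1/(2 tr_s)`.
#' @return filtered matrix, same shape.
#' @export
bandpass <- function(Y, tr_s, low_hz = 0.008, high_hz = 0.08) {
  vec <- is.null(dim(Y))
  Y <- as.matrix(Y)
  T_ <- nrow(Y)
  if (T_ < 4L) stop("bandpass() needs at least 4 volumes")
  nyq <- 1 / (2 * tr_s)
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz < nyq)) {
    stop(
      "invalid band [", low_hz, ", ", high_hz,
      "] Hz for Nyquist ", signif(nyq, 4), " Hz"
    )
  }
  # closed-form linear detrend, then orthogonal projection onto the
  # in-band Fourier subspace (identical to zeroing out-of-band DFT bins)
  tc <- seq_len(T_) - (T_ + 1) / 2
  Y <- sweep(Y, 2L, colMeans(Y))
  Y <- Y - tc %*% (crossprod(tc, Y) / sum(tc^2))
  B <- band_basis(T_, tr_s, low_hz, high_hz)
  out <- B %*% crossprod(B, Y)
  if (vec) drop(out) else out
}

#' Gaussian spatial smoothing
#'
#' Separable 3D Gaussian convolution per volume with
#' `sigma = fwhm / (2 sqrt(2 log 2))` per axis in mm; the kernel is
#' sampled at voxel centres, truncated at 4 sigma and normalised to sum 1
#' (so a constant image is unchanged away from the edges).
#'
#' @param vol 3D array or 4D array (smoothed volume by volume).
#' @param fwhm_mm full width at half maximum, mm (0 = identity).
#' @param voxel_mm voxel size, mm (scalar or length 3).
#' @return array of the same shape.
#' @export
gaussian_smooth <- function(vol, fwhm_mm = 6, voxel_mm = 2) {
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) return(vol)
  voxel_mm <- rep_len(voxel_mm, 3L)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  kernels <- lapply(voxel_mm, function(h) {
    r <- max(1L, ceiling(4 * sigma / h))
    k <- exp(-((-r:r) * h)^2 / (2 * sigma^2))
    k / sum(k)
  })
  smooth3 <- function(a) {
    for (ax in 1:3) {
      a <- apply_along(a, ax, kernels[[ax]])
    }
    a
  }
  if (length(dim(vol)) == 3L) {
    smooth3(vol)
  } else {
    out <- vol
    for (t in seq_len(dim(vol)[4])) out[, , , t] <- smooth3(vol[, , , t])
    out
  }
}

# 1D convolution of a 3D array along axis `ax` with kernel `k`
# (zero-padded edges; kernel normalised by the caller).
apply_along <- function(a, ax, k) {
  d <- dim(a)
  perm <- c(ax, setdiff(1:3, ax))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[ax])
  r <- (length(k) - 1L) / 2L
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (off in -r:r) {
    w <- k[off + r + 1L]
    src <- (1 + max(0, off)):(n + min(0, off))
    dst <- src - off
    out[dst, ] <- out[dst, ] + w * m[src, ]
  }
  aperm(array(out, d[perm]), order(perm))
}

#' Preprocess one session over a brain mask
#'
#' Runs the full temporal pipeline for one subject/session: optionally
#' truncates to the first `n_keep` volumes, extracts the nuisance signals,
#' regresses the nuisance design out, then band-pass filters.
#'
#' @param Y T x V matrix over the brain mask.
#' @param motion T x 6 motion parameter matrix (rows truncated with `Y`).
#' @param wm_cols,csf_cols columns of `Y` belonging to the white-matter /
#'   CSF compartments (excluded from connectivity but used as nuisance
#'   sources); pass integer(0) to skip either signal.
#' @param brain_cols columns over which the global signal (mask mean) is
#'   taken; defaults to every column not in `wm_cols`/`csf_cols`.
#' @param tr_s repetition time, seconds.
#' @param low_hz,high_hz band-pass edges.
#' @param n_keep if non-`NULL`, keep only the first `n_keep` volumes
#'   before any processing (the standard session convention when one
#'   session was acquired longer).
#' @return T x V matrix of cleaned time courses.
#' @export
preprocess_session <- function(Y, motion, wm_cols, csf_cols, tr_s,
                               brain_cols = NULL,
                               low_hz = 0.008, high_hz = 0.08,
                               n_keep = NULL) {
  Y <- as.matrix(Y)
  motion <- as.matrix(motion)
  if (!is.null(n_keep)) {
    if (nrow(Y) < n_keep) stop("session has fewer than n_keep volumes")
    Y <- Y[seq_len(n_keep), , drop = FALSE]
    motion <- motion[seq_len(n_keep), , drop = FALSE]
  }
  if (nrow(motion) != nrow(Y)) stop("motion table length does not match session")
  if (is.null(brain_cols)) {
    brain_cols <- setdiff(seq_len(ncol(Y)), c(wm_cols, csf_cols))
  }
  nuis <- list(motion = motion)
  nuis$global_signal <- rowMeans(Y[, brain_cols, drop = FALSE])
  if (length(wm_cols)) {
    nuis$wm_signal <- extract_eigenvariate(Y[, wm_cols, drop = FALSE])$values
  }
  if (length(csf_cols)) {
    nuis$csf_signal <- extract_eigenvariate(Y[, csf_cols, drop = FALSE])$values
  }
  bandpass(regress_nuisance(Y, nuis), tr_s, low_hz, high_hz)
}
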