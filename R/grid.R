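#' Define a sampling grid
#'
#' A grid couples an integer array shape with a NIfTI-style affine mapping
#' 0-based voxel indices to RAS+ millimetre coordinates:
#' `mm = affine %*% c(i, j, k, 1)`.  All ROI construction and peak
#' reporting use this one convention.
#'
#' @param shape integer(3), voxels per axis.
#' @param voxel_mm voxel edge length in mm (isotropic) or length-3 vector.
#' @param origin_mm mm coordinate of voxel (0, 0, 0).  The default centres
#'   the grid on the origin so that, for odd extents, the middle voxel
#'   centre sits exactly at (0, 0, 0).
#' @return an object of class `seedfc_grid` with elements `shape`,
#'   `voxel_mm` and `affine` (4 x 4).
#' @examples
#' g <- make_grid(c(25, 25, 25), voxel_mm = 2)
#' index_to_mm(g, c(12, 12, 12))  # centre voxel -> (0, 0, 0)
#' @export
make_grid <- function(shape, voxel_mm = 2, origin_mm = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  stopifnot(all(voxel_mm > 0))
  if (is.null(origin_mm)) {
    origin_mm <- -(shape - 1) / 2 * voxel_mm
  }
  affine <- diag(4)
  affine[1:3, 1:3] <- diag(voxel_mm, 3L)
  affine[1:3, 4] <- origin_mm
  structure(
    list(shape = shape, voxel_mm = voxel_mm, affine = affine),
    class = "seedfc_grid"
  )
}

#' @export
print.seedfc_grid <- function(x, ...) {
  cat(
    "<seedfc_grid> ", paste(x$shape, collapse = " x "),
    " voxels @ ", paste(signif(x$voxel_mm, 3), collapse = " x "), " mm\n",
    sep = ""
  )
  invisible(x)
}

#' Convert between voxel indices and mm coordinates
#'
#' @param grid a [make_grid()] object.
#' @param index n x 3 matrix (or length-3 vector) of 0-based voxel indices.
#' @param mm n x 3 matrix (or length-3 vector) of mm coordinates.
#' @return `index_to_mm()` returns an n x 3 mm matrix; `mm_to_index()`
#'   returns the n x 3 matrix of nearest 0-based voxel indices.
#' @export
index_to_mm <- function(grid, index) {
  index <- rbind_coords(index)
  t(grid$affine[1:3, 1:3] %*% t(index) + grid$affine[1:3, 4])
}

#' @rdname index_to_mm
#' @export
mm_to_index <- function(grid, mm) {
  mm <- rbind_coords(mm)
  idx <- t(solve(grid$affine[1:3, 1:3]) %*% (t(mm) - grid$affine[1:3, 4]))
  round(idx)
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  stopifnot(ncol(x) == 3L)
  x
}

voxel_volume_mm3 <- function(grid) prod(grid$voxel_mm)

in_grid <- function(grid, index) {
  index <- rbind_coords(index)
  apply(index >= 0, 1L, all) &
    index[, 1] < grid$shape[1] &
    index[, 2] < grid$shape[2] &
    index[, 3] < grid$shape[3]
}

# 0-based n x 3 index matrix -> 1-based linear index into an array of
# dimension grid$shape
index_to_linear <- function(grid, index) {
  index <- rbind_coords(index)
  1L + index[, 1] +
    grid$shape[1] * (index[, 2] + grid$shape[2] * index[, 3])
}

linear_to_index <- function(grid, lin) {
  lin0 <- as.integer(lin) - 1L
  i <- lin0 %% grid$shape[1]
  rest <- lin0 %/% grid$shape[1]
  j <- rest %% grid$shape[2]
  k <- rest %/% grid$shape[2]
  cbind(i, j, k)
}
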