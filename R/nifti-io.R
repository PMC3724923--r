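#' Read and write volumes as NIfTI-1
#'
#' Thin wrappers over RNifti that keep the package's one coordinate
#' convention: the stored sform maps 0-based voxel indices to RAS+ mm.
#'
#' @param vol 3D or 4D numeric array.
#' @param grid a [make_grid()] object describing the spatial axes.
#' @param path `.nii` or `.nii.gz` path.
#' @param tr_s repetition time in seconds, written into pixdim[4] for 4D
#'   volumes.
#' @return `write_volume()` returns `path` invisibly; `read_volume()`
#'   returns `list(data, grid, tr_s)`.
#' @export
write_volume <- function(vol, grid, path, tr_s = NULL) {
  stopifnot(identical(as.integer(dim(vol)[1:3]), grid$shape))
  img <- RNifti::asNifti(vol)
  pd8 <- c(1, grid$voxel_mm, if (is.null(tr_s)) 1 else tr_s, 1, 1, 1)
  img <- RNifti::asNifti(img, reference = list(pixdim = pd8))
  RNifti::qform(img) <- structure(grid$affine, code = 2L)
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), dimnames = NULL)
  dm <- dim(img)
  pd <- attr(img, "pixdim")
  grid <- make_grid(dm[1:3], voxel_mm = abs(diag(aff)[1:3]))
  grid$affine <- rbind(cbind(aff[1:3, 1:3], aff[1:3, 4]), c(0, 0, 0, 1))
  list(
    data = as.array(img),
    grid = grid,
    tr_s = if (length(dm) >= 4L && length(pd) >= 4L) pd[4] else NULL
  )
}
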