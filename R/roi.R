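#' Seed and tissue regions of interest
#'
#' An ROI is a named set of voxels in a common grid.  Spherical seeds are
#' built around a mm centre with an inclusive voxel-centre rule; label
#' seeds (e.g. bilateral amygdala or hippocampus drawn from an atlas
#' labelling) take every voxel carrying a given integer label.
#'
#' @name roi
NULL

new_roi <- function(name, voxel_indices, grid, center_mm = NULL) {
  voxel_indices <- rbind_coords(voxel_indices)
  storage.mode(voxel_indices) <- "integer"
  structure(
    list(
      name = name,
      voxel_indices = voxel_indices,
      center_mm = center_mm,
      volume_mm3 = nrow(voxel_indices) * voxel_volume_mm3(grid),
      grid = grid
    ),
    class = "seedfc_roi"
  )
}

#' @export
print.seedfc_roi <- function(x, ...) {
  cat(
    "<seedfc_roi> '", x$name, "': ", nrow(x$voxel_indices), " voxels, ",
    signif(x$volume_mm3, 6), " mm^3\n",
    sep = ""
  )
  invisible(x)
}

#' @export
as.data.frame.seedfc_roi <- function(x, ...) {
  mm <- index_to_mm(x$grid, x$voxel_indices)
  data.frame(
    name = x$name,
    i = x$voxel_indices[, 1], j = x$voxel_indices[, 2],
    k = x$voxel_indices[, 3],
    x_mm = mm[, 1], y_mm = mm[, 2], z_mm = mm[, 3]
  )
}

#' Build a spherical seed ROI
#'
#' Includes exactly the voxels whose centres lie at Euclidean distance
#' `<= radius_mm` from `center_mm` (inclusive boundary).  With the
#' conventional 6 mm radius on a 2 mm isotropic grid and the centre on a
#' voxel centre this gives the canonical 123-voxel (984 mm^3) seed.
#'
#' @param center_mm length-3 mm coordinate of the sphere centre.
#' @param radius_mm sphere radius in mm (>= 0).
#' @param grid a [make_grid()] object.
#' @param name ROI name.
#' @return a `seedfc_roi`.
#' @examples
#' g <- make_grid(c(25, 25, 25), voxel_mm = 2)
#' nrow(build_sphere_roi(c(0, 0, 0), 6, g)$voxel_indices)  # 123
#' @export
build_sphere_roi <- function(center_mm, radius_mm, grid, name = "seed") {
  stopifnot(radius_mm >= 0, length(center_mm) == 3L)
  c_idx <- drop(
    solve(grid$affine[1:3, 1:3]) %*% (center_mm - grid$affine[1:3, 4])
  )
  if (any(c_idx < -0.5) || any(c_idx > grid$shape - 0.5)) {
    stop("sphere centre for '", name, "' lies outside the grid")
  }
  # candidate bounding box in index space (possibly out of bounds; we
  # count clipped voxels to report a hard error rather than truncating)
  r_idx <- radius_mm / grid$voxel_mm
  lo <- floor(c_idx - r_idx)
  hi <- ceiling(c_idx + r_idx)
  cand <- as.matrix(expand.grid(
    i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]
  ))
  centers <- t(grid$affine[1:3, 1:3] %*% t(cand) + grid$affine[1:3, 4])
  d2 <- rowSums((centers - matrix(center_mm, nrow(cand), 3, byrow = TRUE))^2)
  inside_sphere <- d2 <= radius_mm^2 + 1e-9
  cand <- cand[inside_sphere, , drop = FALSE]
  ok <- in_grid(grid, cand)
  if (any(!ok)) {
    stop(
      "sphere '", name, "' extends outside the grid: ",
      sum(!ok), " voxel(s) clipped"
    )
  }
  new_roi(name, cand, grid, center_mm = as.numeric(center_mm))
}

#' Build an ROI from an integer label volume
#'
#' @param label_volume 3D integer array matching `grid$shape`.
#' @param label_id integer label to extract.
#' @param grid a [make_grid()] object.
#' @param name ROI name.
#' @return a `seedfc_roi` containing every voxel carrying `label_id`.
#' @export
roi_from_label_mask <- function(label_volume, label_id, grid,
                                name = paste0("label_", label_id)) {
  stopifnot(identical(dim(label_volume), NULL) == FALSE)
  if (!identical(as.integer(dim(label_volume)), grid$shape)) {
    stop("label volume dimensions do not match the grid")
  }
  lin <- which(label_volume == label_id)
  if (length(lin) == 0L) {
    stop("label ", label_id, " is absent from the label volume")
  }
  new_roi(name, linear_to_index(grid, lin), grid)
}

#' Read a seed configuration table
#'
#' The table is TSV with columns `name`, `x`, `y`, `z`, `radius` (mm) for
#' spherical seeds, and `label_id` for label-mask seeds (sphere columns
#' `NA` for those rows).  The packaged default
#' (`system.file("extdata", "seeds_13.tsv", package = "seedfc")`) holds
#' the nine self-reflection sphere seeds plus bilateral amygdala and
#' hippocampus label seeds.
#'
#' @param path TSV path.
#' @return a tibble, one row per seed.
#' @export
read_seed_table <- function(path = default_seed_table()) {
  tab <- tibble::as_tibble(read.delim(path, sep = "\t"))
  stopifnot(all(c("name", "x", "y", "z", "radius", "label_id") %in% names(tab)))
  tab
}

#' @rdname read_seed_table
#' @export
default_seed_table <- function() {
  system.file("extdata", "seeds_13.tsv", package = "seedfc", mustWork = TRUE)
}

#' Build every seed ROI from a seed table
#'
#' @param seed_table tibble from [read_seed_table()].
#' @param grid a [make_grid()] object.
#' @param label_volume integer 3D array for rows with a `label_id`; may be
#'   `NULL` when the table contains spheres only.
#' @param check_disjoint `"warn"` (default) reports overlapping seed ROIs
#'   with a warning, `"error"` refuses them, `"none"` skips the check.
#'   Published seed coordinate sets can overlap at a 6 mm radius (e.g.
#'   neighbouring inferior-frontal and insular centres), which leaves the
#'   analysis valid but makes their profiles partially shared.
#' @return named list of `seedfc_roi`.
#' @export
build_seed_rois <- function(seed_table, grid, label_volume = NULL,
                            check_disjoint = c("warn", "error", "none")) {
  check_disjoint <- match.arg(check_disjoint)
  rois <- purrr::pmap(seed_table, function(name, x, y, z, radius, label_id, ...) {
    if (!is.na(label_id)) {
      if (is.null(label_volume)) {
        stop("seed '", name, "' needs a label volume (label_id ", label_id, ")")
      }
      roi_from_label_mask(label_volume, label_id, grid, name = name)
    } else {
      build_sphere_roi(c(x, y, z), radius, grid, name = name)
    }
  })
  names(rois) <- seed_table$name
  if (check_disjoint != "none") {
    lin <- lapply(rois, function(r) index_to_linear(grid, r$voxel_indices))
    all_lin <- unlist(lin)
    if (anyDuplicated(all_lin)) {
      dup <- all_lin[duplicated(all_lin)][1]
      offenders <- names(rois)[vapply(lin, function(l) dup %in% l, logical(1))]
      msg <- paste0("seed ROIs overlap: ", paste(offenders, collapse = ", "))
      if (check_disjoint == "error") stop(msg) else warning(msg)
    }
  }
  rois
}

#' Write an ROI as a NIfTI binary mask
#'
#' @param roi a `seedfc_roi`.
#' @param path output `.nii`/`.nii.gz` path.
#' @export
write_roi_mask <- function(roi, path) {
  vol <- array(0L, roi$grid$shape)
  vol[index_to_linear(roi$grid, roi$voxel_indices)] <- 1L
  write_volume(vol, roi$grid, path)
  invisible(path)
}
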