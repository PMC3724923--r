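# Shared fixtures, built in code at test time.

# 2 mm isotropic grid with the centre voxel exactly at the origin
centered_grid <- function(n = 25) make_grid(rep(n, 3L), voxel_mm = 2)

# brute-force lattice enumeration oracle for sphere voxel counts:
# all integer offsets with squared norm <= (radius/spacing)^2
sphere_count_oracle <- function(radius_mm, spacing_mm) {
  r <- ceiling(radius_mm / spacing_mm)
  offs <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  sum(rowSums(offs^2) * spacing_mm^2 <= radius_mm^2 + 1e-9)
}

# small planted-free covariate/cluster profile for fast cohorts:
# two seeds in one network on a small grid (full 13-seed cohorts need
# the default 24 x 28 x 24 grid)
tiny_partition <- function() {
  tibble::tibble(
    seed = c("seedA", "seedB"), network = c(1L, 1L), weight = c(1, 1)
  )
}

tiny_cohort_config <- function(n_subjects = 12, rng_seed = 1, ...) {
  cohort_config(
    n_subjects = n_subjects,
    grid_shape = c(16, 16, 16),
    planted_partition = tiny_partition(),
    session_effect = 0.5,
    covariate_slope = 0.01,
    target_radii = list(6),
    rng_seed = rng_seed,
    ...
  )
}

# one default-condition cohort + pipeline run, computed once per test
# session (several tests inspect different aspects of the same run)
.seedfc_cache <- new.env(parent = emptyenv())

default_run_cached <- function() {
  if (is.null(.seedfc_cache$run)) {
    .seedfc_cache$cohort <- generate_cohort(cohort_config(rng_seed = 1))
    .seedfc_cache$run <- suppressMessages(run_pipeline(
      .seedfc_cache$cohort, run_config(run_inference = FALSE, rng_seed = 1)
    ))
  }
  list(cohort = .seedfc_cache$cohort, run = .seedfc_cache$run)
}

# argmax network per pure seed of the default partition (mixed seeds
# have no single planted label)
planted_labels <- function(partition = default_partition()) {
  seeds <- unique(partition$seed)
  lab <- vapply(seeds, function(s) {
    rows <- partition[partition$seed == s, ]
    rows$network[which.max(rows$weight)]
  }, integer(1))
  mixed <- names(which(
    table(partition$seed)[seeds] > 1
  ))
  list(labels = lab, mixed = mixed, pure = setdiff(seeds, mixed))
}
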