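#' Tidy and glance methods
#'
#' broom-style accessors: `tidy()` returns one observation per row,
#' `glance()` a one-row model summary.
#'
#' @name tidiers
NULL

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname tidiers
#' @param x a `seedfc_fcm` fit.
#' @param ... unused.
#' @return `tidy.seedfc_fcm()`: tibble with `seed`, `cluster`,
#'   `membership` (long membership matrix, memberships per seed summing
#'   to 1).
#' @export
tidy.seedfc_fcm <- function(x, ...) {
  U <- x$U
  tibble::tibble(
    seed = rep(colnames(U), each = nrow(U)),
    cluster = rep(seq_len(nrow(U)), ncol(U)),
    membership = as.numeric(U)
  )
}

#' @rdname tidiers
#' @export
glance.seedfc_fcm <- function(x, ...) {
  tibble::tibble(
    c = x$c, m = x$m, objective = x$objective,
    iterations = x$iterations, n_seeds = ncol(x$U)
  )
}

#' @rdname tidiers
#' @return `tidy.seedfc_statmap()`: the cluster/peak table, see
#'   [cluster_table()].
#' @export
tidy.seedfc_statmap <- function(x, ...) {
  cluster_table(x, ...)
}

#' @rdname tidiers
#' @export
glance.seedfc_statmap <- function(x, ...) {
  tibble::tibble(
    df = x$df, threshold = x$threshold, k_min = x$k_min,
    n_perm = x$n_perm, n_clusters = nrow(x$clusters),
    min_fwe_p = if (nrow(x$clusters)) min(x$clusters$fwe_p) else NA_real_
  )
}

#' @rdname tidiers
#' @return `tidy.seedfc_run()`: per-seed assignment tibble with
#'   memberships and dual flags.
#' @export
tidy.seedfc_run <- function(x, ...) {
  x$assignments
}

#' @rdname tidiers
#' @export
glance.seedfc_run <- function(x, ...) {
  tibble::tibble(
    n_seeds = nrow(x$D), n_voxels = ncol(x$D),
    k_profile = x$k_profile, k_scree = x$k_scree,
    fcm_c = x$fcm$c, fcm_objective = x$fcm$objective,
    n_dual = sum(x$assignments$dual)
  )
}
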