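#' Plots for clustering results
#'
#' ggplot2 views of the main result types: the membership bar chart
#' (seeds on the x axis, stacked membership degrees in [0, 1]), the
#' eigenvalue scree plot with the selected component counts, and the
#' seed-similarity graph as a tile heat map.
#'
#' @name plots
NULL

#' @rdname plots
#' @param object a `seedfc_fcm` fit.
#' @param ... unused.
#' @export
autoplot.seedfc_fcm <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = .data$seed, y = .data$membership,
      fill = factor(.data$cluster)
    )
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "membership degree", fill = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plots
#' @param spectrum descending eigenvalue vector from [eigen_spectrum()].
#' @export
plot_scree <- function(spectrum) {
  d <- tibble::tibble(
    component = seq_along(spectrum), eigenvalue = spectrum
  )
  kp <- estimate_k_profile_loglik(spectrum)
  ks <- estimate_k_scree(spectrum)
  ggplot2::ggplot(d, ggplot2::aes(.data$component, .data$eigenvalue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = kp + 0.5, linetype = 2) +
    ggplot2::labs(
      subtitle = sprintf("profile log-likelihood: %d, scree gap: %d", kp, ks),
      x = "component", y = "eigenvalue"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @param graph a [seed_similarity_graph()] result.
#' @export
plot_seed_graph <- function(graph) {
  C <- graph$cor
  d <- tibble::as_tibble(as.data.frame.table(C, responseName = "r"))
  names(d)[1:2] <- c("from", "to")
  ggplot2::ggplot(d, ggplot2::aes(.data$from, .data$to, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "correlation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
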