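# ggplot2 graphics for the main result types.

#' Trace plots of the sampler's hyperparameter chains
#'
#' @param object An `mrs_posterior` with recorded chains.
#' @param ... Unused.
#' @return A ggplot: per-sweep traces of `h2`, `p` and the nonzero count.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.mrs_posterior <- function(object, ...) {
  if (!nrow(object$chains)) {
    stop_validation("no chains recorded (closed-form fit?)")
  }
  long <- tidyr::pivot_longer(object$chains, c("p", "h2", "m_c"),
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sweep, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$parameter), scales = "free_y",
                        ncol = 1) +
    ggplot2::labs(x = "post-burn-in sweep", y = NULL,
                  title = "Hyperparameter chains")
}

#' @rdname autoplot.mrs_posterior
#' @export
plot_chains <- function(object, ...) autoplot.mrs_posterior(object, ...)

#' Cluster-size distribution plot
#'
#' @param object A `cluster_set`.
#' @param ... Unused.
#' @return A ggplot histogram of probes-per-cluster (log10 x-axis).
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.cluster_set <- function(object, ...) {
  sizes <- tibble(size = cluster_sizes(object))
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "probes per cluster", y = "clusters",
                  title = attr(object, "label"))
}

#' @rdname autoplot.cluster_set
#' @export
plot_cluster_sizes <- function(object, ...) autoplot.cluster_set(object, ...)

#' Score distributions by phenotype class
#'
#' @param scores Score tibble.
#' @param pheno Phenotype tibble.
#' @return A ggplot of score densities per class.
#' @export
plot_score_separation <- function(scores, pheno) {
  dat <- dplyr::inner_join(scores, validate_phenotypes(pheno),
                           by = "sample_id")
  dat$class <- factor(dat$y, levels = c(0, 1), labels = c("control", "case"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$score, fill = .data$class)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "methylation score", y = "density", fill = NULL)
}
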