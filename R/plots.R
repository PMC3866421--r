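#' Plot prototype representations in principal-component space
#'
#' Scatter of the 2-D PCA projection of the category-prototype cortical
#' representations, coloured by global-level category and faceted by
#' labelling condition — the visual form of the warping result.
#'
#' @param result An `experiment_result` from [run_warping_experiment()], or
#'   its `projections` data frame.
#' @param seed Which replicate seed to show (default: the first).
#' @return A ggplot object.
#' @export
plot_warping <- function(result, seed = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_config("plotting requires the ggplot2 package")
  proj <- if (inherits(result, "experiment_result")) result$projections else result
  seed <- seed %||% proj$seed[[1]]
  d <- proj[proj$seed == seed, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                  colour = .data$global_category)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$basic_category),
                       size = 2.4, vjust = -0.8, show.legend = FALSE) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "PC 1", y = "PC 2", colour = "global category",
                  title = "Cortical prototype representations") +
    ggplot2::theme_minimal()
}

#' Plot familiarization times by background condition
#'
#' Bar chart of mean presentations-to-criterion with per-seed points
#' overlaid, in the canonical condition order (no background, unlabeled
#' background, labelled background).
#'
#' @param result An `experiment_result` from
#'   [run_familiarization_experiment()].
#' @return A ggplot object.
#' @export
plot_familiarization <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_config("plotting requires the ggplot2 package")
  d <- result$per_seed
  d$condition <- factor(d$condition, levels = c(
    "no_background", "unlabeled_background", "labeled_background"))
  means <- stats::aggregate(presentations ~ condition, d, mean)
  ggplot2::ggplot(means, ggplot2::aes(x = .data$condition,
                                      y = .data$presentations)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_jitter(data = d, width = 0.1, height = 0, size = 1.5) +
    ggplot2::labs(x = NULL, y = "presentations to criterion",
                  title = "Familiarization time by background experience") +
    ggplot2::theme_minimal()
}
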