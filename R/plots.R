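#' Plot a TPR-FDP curve
#'
#' @param object a [tpr_fdp_curve()].
#' @param ... unused.
#' @return a ggplot: FDP on the x axis, TPR on the y axis, with the operating
#'   point at the marked FDR level.
#' @method autoplot tpr_fdp_curve
#' @export
autoplot.tpr_fdp_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fdp, y = .data$tpr)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "false discovery proportion", y = "true positive rate")
  if (is.finite(object$mark$tpr)) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(fdp = object$mark$fdp, tpr = object$mark$tpr),
      size = 3
    )
  }
  p
}

#' Per-sample intensity distributions of an assay
#'
#' @param object a [feature_assay()].
#' @param ... unused.
#' @return a ggplot of per-sample boxplots of the observed intensities.
#' @method autoplot feature_assay
#' @export
autoplot.feature_assay <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$sample_id, y = .data$intensity)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::labs(x = NULL, y = if (object$log2) "log2 intensity" else "intensity") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' P-value histogram of a result table
#'
#' @param results result tibble (see [test_contrasts()]).
#' @param bins number of histogram bins.
#' @return a ggplot, faceted by contrast.
#' @export
plot_pvalue_histogram <- function(results, bins = 20) {
  results |>
    dplyr::filter(.data$status %in% c("ok", "reduced")) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$pvalue)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, length.out = bins + 1),
                            closed = "right", boundary = 0) +
    ggplot2::facet_wrap(~ contrast) +
    ggplot2::labs(x = "p-value", y = "proteins")
}

#' log2 fold-change distributions by truth class
#'
#' @param results result tibble.
#' @param truth truth tibble from [simulate_spikein()].
#' @return a ggplot of per-class logFC boxplots with the true values marked.
#' @export
plot_logfc_error <- function(results, truth) {
  tab <- join_truth(results, truth) |>
    dplyr::filter(.data$status %in% c("ok", "reduced"), !is.na(.data$logFC)) |>
    dplyr::mutate(class = ifelse(.data$is_da, "spike-in", "background"))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$class, y = .data$logFC)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~ contrast) +
    ggplot2::labs(x = NULL, y = "estimated log2 fold change")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
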