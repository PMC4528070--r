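#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an AFROC curve
#'
#' Family-wise false-positive rate against true-positive rate over the
#' threshold sweep; the dashed line marks the FPR = 0.05 restriction used by
#' [afroc_auc()].
#'
#' @param object an [afroc_curve()].
#' @param fpr_max FPR guide line position.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.afroc_curve <- function(object, fpr_max = 0.05, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::geom_vline(xintercept = fpr_max, linetype = "dashed") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "family-wise FPR", y = "TPR (fraction of true fixels)",
                  title = "AFROC curve") +
    ggplot2::theme_minimal()
}

#' Heat map of a parameter sweep
#'
#' AUC of the restricted AFROC as a tile map over two swept parameters
#' (default E x H), faceted by any others that vary.
#'
#' @param sweep a [parameter_sweep()] tibble.
#' @param x,y names of the parameters on the axes.
#' @return a ggplot.
#' @export
plot_sweep_heatmap <- function(sweep, x = "E", y = "H") {
  others <- setdiff(c("snr", "fwhm", "E", "H", "C"), c(x, y))
  vary <- others[vapply(others, function(v) length(unique(sweep[[v]])) > 1,
                        logical(1))]
  p <- ggplot2::ggplot(sweep, ggplot2::aes(x = factor(.data[[x]]),
                                           y = factor(.data[[y]]),
                                           fill = .data$auc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = x, y = y, fill = "AUC") +
    ggplot2::theme_minimal()
  if (length(vary)) {
    p <- p + ggplot2::facet_wrap(vary, labeller = ggplot2::label_both)
  }
  p
}

#' Plot the permutation null distribution of a CFE fit
#'
#' Histogram of the maximal enhanced statistic across permutations, with the
#' observed maximum marked.
#'
#' @param object a `cfe_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cfe_fit <- function(object, ...) {
  df <- tibble::tibble(max_enhanced = object$null_max)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$max_enhanced)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$null_max[1], colour = "red") +
    ggplot2::labs(x = "max enhanced statistic (per permutation)",
                  y = "count",
                  title = "Permutation null of the maximal CFE statistic") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
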