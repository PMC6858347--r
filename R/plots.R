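#' Volcano plot of a differential-expression table
#'
#' @param object A `de_table` from [run_de()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot de_table
#' @export
autoplot.de_table <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, -log10(.data$p),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(
      title = paste0(attr(object, "alt_id"), " (", attr(object, "role"),
                     " genes)"),
      x = "log2 fold change (altered - unaltered)",
      y = expression(-log[10] ~ p)
    ) +
    ggplot2::theme_minimal()
}

#' WFTM ranking barplot of a mediation fit
#'
#' @param object A `mediation_fit` from [run_mediation()].
#' @param ... Unused.
#' @return A ggplot object; the Rank-1 candidate driver is highlighted.
#' @method autoplot mediation_fit
#' @export
autoplot.mediation_fit <- function(object, ...) {
  df <- object$ranking
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$cis_gene,
                                                  .data$wftm),
                                   .data$wftm, fill = .data$is_rank1)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick"),
                               guide = "none") +
    ggplot2::labs(title = paste0("Cis-gene mediation ranking: ",
                                 object$alt_id),
                  x = NULL, y = "weighted fraction of trans mediation") +
    ggplot2::theme_minimal()
}

#' Heatmaps of Sobel-test performance over the simulation grid
#'
#' @param object A `perf_grid` from [simulate_grid()].
#' @param metric One of `"auc"`, `"sensitivity"`, `"specificity"`.
#' @param ... Unused.
#' @return A ggplot tile plot of the metric over (correlation, sample size).
#' @method autoplot perf_grid
#' @export
autoplot.perf_grid <- function(object, metric = c("auc", "sensitivity",
                                                  "specificity"), ...) {
  metric <- match.arg(metric)
  df <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(factor(round(.data$r, 2)),
                                   factor(.data$n),
                                   fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f",
                                                    .data[[metric]]))) +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "white",
                                 high = "steelblue") +
    ggplot2::labs(x = "corr(X, Y)", y = "sample size", fill = metric) +
    ggplot2::theme_minimal()
}

#' Bootstrap inclusion fraction against WFTM or entropy
#'
#' @param object A `bootstrap_report` from [bootstrap_rank1()].
#' @param covariate `"wftm"` or `"entropy"`.
#' @param ... Unused.
#' @return A ggplot scatter with a least-squares line.
#' @method autoplot bootstrap_report
#' @export
autoplot.bootstrap_report <- function(object,
                                      covariate = c("wftm", "entropy"),
                                      ...) {
  covariate <- match.arg(covariate)
  df <- object$scores
  ggplot2::ggplot(df, ggplot2::aes(.data[[covariate]],
                                   .data$inclusion_fraction)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = covariate, y = "Rank-1 inclusion fraction") +
    ggplot2::theme_minimal()
}
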