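#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot detection scores across IoU thresholds
#'
#' Precision, recall and F1 as a function of the IoU threshold — the
#' standard way to read instance-segmentation quality at a glance.
#'
#' @param object A [detection_scores()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.detection_scores <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_threshold,
                            cols = c("precision", "recall", "f1"),
                            names_to = "metric", values_to = "score")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$score,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "IoU threshold", y = "score", colour = NULL,
                  subtitle = sprintf("average F1 %.3f, mean Jaccard %.3f",
                                     object$avg_f1, object$mean_jaccard)) +
    ggplot2::theme_minimal()
}

#' Plot measurement agreement
#'
#' Either the concordance scatter against the identity line, or the
#' Bland-Altman plot (differences against means with bias and 95% limits
#' of agreement).
#'
#' @param object An [agreement_stats()] result.
#' @param type `"concordance"` or `"bland_altman"`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.agreement_stats <- function(object,
                                     type = c("concordance", "bland_altman"),
                                     ...) {
  type <- match.arg(type)
  df <- tibble::tibble(target = object$x, prediction = object$y)
  if (type == "concordance") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$target,
                                     y = .data$prediction)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::labs(
        x = sprintf("%s (target)", object$measure),
        y = sprintf("%s (prediction)", object$measure),
        subtitle = sprintf("CCC %.4f (95%% CI %.4f-%.4f)", object$ccc,
                           object$ccc_ci95[1], object$ccc_ci95[2])) +
      ggplot2::theme_minimal()
  } else {
    df$mean <- (df$target + df$prediction) / 2
    df$diff <- df$prediction - df$target
    ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
      ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
      ggplot2::geom_hline(yintercept = object$loa, linetype = "dashed",
                          colour = "grey40") +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::labs(x = sprintf("mean %s", object$measure),
                    y = "prediction - target",
                    subtitle = sprintf("bias %.4g, LoA [%.4g, %.4g]",
                                       object$bias, object$loa[1],
                                       object$loa[2])) +
      ggplot2::theme_minimal()
  }
}

#' Histogram of per-fibre g-ratios
#'
#' @param morphometry A [measure_fibres()] tibble.
#' @param bins Number of histogram bins.
#' @return A ggplot comparing myelin and axon g-ratio distributions.
#' @export
plot_gratio_distribution <- function(morphometry, bins = 20) {
  df <- tidyr::pivot_longer(
    morphometry[, c("fibre_id", "g_myelin", "g_axon")],
    cols = c("g_myelin", "g_axon"), names_to = "metric",
    values_to = "g")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$g, fill = .data$metric)) +
    ggplot2::geom_histogram(bins = bins, position = "identity",
                            alpha = 0.55) +
    ggplot2::labs(x = "g-ratio", y = "fibres", fill = NULL) +
    ggplot2::theme_minimal()
}
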