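#' Plot NAP investment against growth temperature
#'
#' Scatter of per-species NAP investment versus optimal growth temperature
#' with the least-squares line and its confidence band.
#'
#' @param data Tibble with `ogt` and `nap_percent` columns.
#' @param log_y Log10 y axis.
#' @return A ggplot object.
#' @export
plot_investment_ogt <- function(data, log_y = FALSE) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$ogt, y = .data$nap_percent)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                         color = "grey30", fill = "grey80") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Optimal growth temperature (°C)",
                  y = "NAP investment (% of proteome)") +
    ggplot2::theme_classic()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @describeIn plot_investment_ogt Presence/absence heatmap of NAP families.
#' @param object A result object.
#' @param ... Unused.
#' @export
autoplot.nap_presence <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"genome",
                              names_to = "family", values_to = "present")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$family, y = .data$genome,
                                     fill = .data$present)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey20", `FALSE` = "grey90")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "present") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_investment_ogt Co-occurrence counts of NAP families.
#' @export
autoplot.nap_cooccurrence <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$family_a, y = .data$family_b,
                                       fill = .data$n_genomes)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_genomes), color = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = "genomes") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_investment_ogt Volcano plot of nucleoid enrichment.
#' @export
autoplot.nap_enrichment <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$log2fc,
                               y = -log10(.data$q_value))) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::labs(x = "log2 fold change (nucleoid - top)",
                  y = "-log10 q-value") +
    ggplot2::theme_classic()
}

#' @describeIn plot_investment_ogt Distribution of screen correlations with
#'   the NAP aggregate marked.
#' @export
autoplot.nap_screen <- function(object, ...) {
  nap_class <- attr(object, "nap_class")
  nap_rho <- object$rho[object$class == nap_class]
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$rho)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "grey30") +
    ggplot2::geom_vline(xintercept = nap_rho, color = "red") +
    ggplot2::labs(x = "Spearman rho vs growth temperature", y = "features") +
    ggplot2::theme_classic()
}

#' @describeIn plot_investment_ogt ESD test statistics against critical
#'   values.
#' @export
autoplot.nap_esd <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$R, fill = .data$outlier),
                      width = 0.6) +
    ggplot2::geom_step(ggplot2::aes(y = .data$lambda), direction = "mid",
                       color = "red") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey20", `FALSE` = "grey70")) +
    ggplot2::labs(x = "outlier index i", y = "R_i (bars), lambda_i (line)") +
    ggplot2::theme_classic()
}

#' @describeIn plot_investment_ogt OLS fit with confidence and prediction
#'   bands.
#' @export
autoplot.nap_ols <- function(object, ...) {
  df <- object$fit$model
  xs <- seq(min(df$x), max(df$x), length.out = 80)
  ci <- predict(object$fit, data.frame(x = xs), interval = "confidence")
  pi <- suppressWarnings(predict(object$fit, data.frame(x = xs),
                                 interval = "prediction"))
  band <- tibble(x = xs, fit = ci[, 1], ci_lo = ci[, 2], ci_hi = ci[, 3],
                 pi_lo = pi[, 2], pi_hi = pi[, 3])
  ggplot2::ggplot(band, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$pi_lo, ymax = .data$pi_hi),
                         fill = "grey90") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         fill = "grey75") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit)) +
    ggplot2::geom_point(data = df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(x = "growth temperature (°C)",
                  y = "NAP investment (%)") +
    ggplot2::theme_classic()
}
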