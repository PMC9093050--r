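#' Plot a Welch PSD estimate
#'
#' Log-power spectra, one line per channel, over the 1-42 Hz analysis range.
#'
#' @param object a `psd_estimate`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.psd_estimate <- function(object, ...) {
  df <- tibble::tibble(
    channel = rep(object$labels, times = length(object$freqs)),
    freq = rep(object$freqs, each = length(object$labels)),
    psd = as.vector(object$psd))
  df <- dplyr::filter(df, .data$freq >= 1, .data$freq <= 42)
  ggplot2::ggplot(df, ggplot2::aes(.data$freq, .data$psd, group = .data$channel)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = expression(PSD ~ (mu * V^2 / Hz)))
}

#' Plot a connectivity matrix as a heatmap
#'
#' @param object a `connectivity_matrix`.
#' @param ... unused.
#' @export
autoplot.connectivity_matrix <- function(object, ...) {
  df <- tibble::tibble(
    from = factor(rep(object$labels, times = length(object$labels)), levels = object$labels),
    to = factor(rep(object$labels, each = length(object$labels)), levels = rev(object$labels)),
    plv = as.vector(object$values))
  ggplot2::ggplot(df, ggplot2::aes(.data$from, .data$to, fill = .data$plv)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "PLV") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot per-class microstate features
#'
#' Bar panels of GEV, duration, occurrence, coverage, interval and mean GFP.
#'
#' @param object a `microstate_features` result.
#' @param ... unused.
#' @export
autoplot.microstate_features <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_class, -"class", names_to = "feature")
  ggplot2::ggplot(df, ggplot2::aes(.data$class, .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = "Microstate class", y = NULL)
}

#' Null distribution of a permutation test
#'
#' Histogram of the permuted statistics with the observed value marked.
#'
#' @param object a `perm_result`.
#' @param ... unused.
#' @export
autoplot.perm_result <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(stat = object$null), ggplot2::aes(.data$stat)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = object$statistic, linetype = 2) +
    ggplot2::labs(x = object$stat, y = "count",
                  subtitle = sprintf("p = %.4g (%d permutations)",
                                     object$p, object$n_perm))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
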