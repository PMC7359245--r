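#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Phase-plane plot of a population scan
#'
#' Scatter of sites in the (MET, JSD) plane coloured by cytosine type, under
#' the binary-entropy envelope that bounds the divergence, with the
#' classification thresholds drawn.
#'
#' @param sites Classified site-statistics tibble.
#' @param thresholds The [phase_thresholds()] used for the guide lines.
#' @param alpha Point transparency.
#' @return A ggplot object.
#' @export
plot_phase_plane <- function(sites, thresholds = phase_thresholds(),
                             alpha = 0.4) {
  .check_sites(sites, c("met", "jsd", "ctype"))
  envelope <- tibble::tibble(met = seq(0, 1, length.out = 401))
  envelope$jsd <- binary_entropy(envelope$met)
  ggplot2::ggplot(sites, ggplot2::aes(x = .data$met, y = .data$jsd)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$ctype), alpha = alpha,
                        size = 0.8) +
    ggplot2::geom_line(data = envelope, linetype = "dashed",
                       colour = "grey40") +
    ggplot2::geom_vline(xintercept = c(thresholds$met_low,
                                       thresholds$met_high),
                        linetype = "dotted", colour = "grey50") +
    ggplot2::annotate("segment", x = thresholds$met_low,
                      xend = thresholds$met_high,
                      y = thresholds$jsd_metastable,
                      yend = thresholds$jsd_metastable,
                      linetype = "dotted", colour = "grey50") +
    ggplot2::labs(x = "MET (weighted methylation level)",
                  y = "JSD (bit)", colour = "C type") +
    ggplot2::theme_minimal()
}

#' @describeIn metagene_profile Plot the profile: flank bins at their
#'   genomic offsets, body bins on a rescaled axis.
#' @param object A `meta_profile` object.
#' @param ... Unused.
#' @method autoplot meta_profile
#' @export
autoplot.meta_profile <- function(object, ...) {
  fw <- attr(object, "flank_width")
  fb <- attr(object, "flank_bin")
  bb <- attr(object, "body_bins")
  df <- tibble::as_tibble(object)
  df$x <- ifelse(df$segment == "upstream", -fw + df$bin * fb + fb / 2,
          ifelse(df$segment == "body", (df$bin + 0.5) / bb * fw,
                 fw + df$bin * fb + fb / 2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = c(0, fw), linetype = "dotted") +
    ggplot2::scale_x_continuous(
      breaks = c(-fw, 0, fw, 2 * fw),
      labels = c(paste0("-", fw / 1000, " kb"), "start", "end",
                 paste0("+", fw / 1000, " kb"))
    ) +
    ggplot2::labs(x = NULL, y = attr(object, "signal"),
                  title = sprintf("Metagene profile over %d features",
                                  attr(object, "n_features"))) +
    ggplot2::theme_minimal()
}

#' @describeIn csd_lsd_test Plot the null distribution with the observed
#'   statistic marked.
#' @param object A `perm_test` object.
#' @param ... Unused.
#' @method autoplot perm_test
#' @export
autoplot.perm_test <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = object$statistic, y = "null draws",
                  subtitle = sprintf("p = %.4g (add-one %.4g)",
                                     object$p_value, object$p_smoothed)) +
    ggplot2::theme_minimal()
}

#' Plot a binned chromosome track
#'
#' @param binned A `binned_signal` tibble from [bin_signal()] or
#'   [msg_fraction_track()].
#' @return A ggplot object, one facet per chromosome.
#' @export
plot_binned_signal <- function(binned) {
  .check_sites(binned, c("chrom", "start", "value"))
  ggplot2::ggplot(tibble::as_tibble(binned),
                  ggplot2::aes(x = (.data$start + .data$end) / 2,
                               y = .data$value)) +
    ggplot2::geom_step(na.rm = TRUE) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)",
                  y = attr(binned, "statistic") %||% "value") +
    ggplot2::theme_minimal()
}
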