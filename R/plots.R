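#' Plot a mixture meta-model fit
#'
#' Shows the projected QTL positions (rug), each QTL's implied normal
#' density (thin lines) and the fitted mixture components (means with 95%
#' intervals).
#'
#' @param object A `metaqtl_fit` from [fit_mixture()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metaqtl_fit
#' @export
autoplot.metaqtl_fit <- function(object, ...) {
  comp <- tidy(object)
  obs <- tibble(position_cM = object$positions, sigma = object$sigmas)
  ggplot2::ggplot() +
    ggplot2::geom_rug(data = obs, ggplot2::aes(x = .data$position_cM)) +
    ggplot2::geom_errorbarh(
      data = comp,
      ggplot2::aes(xmin = .data$ci_lo_cM, xmax = .data$ci_hi_cM,
                   y = .data$component),
      height = 0.2) +
    ggplot2::geom_point(
      data = comp,
      ggplot2::aes(x = .data$mu_cM, y = .data$component,
                   size = .data$weight)) +
    ggplot2::scale_y_continuous(breaks = comp$component) +
    ggplot2::labs(x = "position (cM)", y = "meta-QTL component",
                  size = "weight",
                  title = sprintf("Mixture meta-model, K = %d", object$K)) +
    ggplot2::theme_minimal()
}

#' Plot cluster and hotspot calls along chromosomes
#'
#' Draws each call as a horizontal interval on its chromosome, colored by
#' call type (cluster vs hotspot trait).
#'
#' @param clusters Cluster calls from [detect_clusters()] (may have 0 rows).
#' @param hotspots Hotspot calls from [detect_hotspots()] (may have 0 rows).
#' @return A ggplot object.
#' @export
plot_calls <- function(clusters, hotspots) {
  calls <- bind_rows(
    clusters %>% mutate(type = "cluster"),
    hotspots %>% mutate(type = .data$trait)
  )
  if (nrow(calls) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "No calls") + ggplot2::theme_minimal())
  }
  calls$chromosome <- factor(
    calls$chromosome,
    levels = rev(unique(calls$chromosome[order(chrom_number(calls$chromosome))])))
  ggplot2::ggplot(calls) +
    ggplot2::geom_linerange(
      ggplot2::aes(y = .data$chromosome, xmin = .data$start_cM,
                   xmax = .data$end_cM, color = .data$type),
      linewidth = 3,
      position = ggplot2::position_dodge2(width = 0.7)) +
    ggplot2::labs(x = "position (cM)", y = NULL, color = "call",
                  title = "QTL clusters and hotspots") +
    ggplot2::theme_minimal()
}
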