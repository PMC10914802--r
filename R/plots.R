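#' Plot a G' scan track
#'
#' G' along the genome, faceted by chromosome, with significant SNPs
#' highlighted and called QTL intervals shaded.
#'
#' @param object A `gprime_scan` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @importFrom ggplot2 autoplot
#' @method autoplot gprime_scan
autoplot.gprime_scan <- function(object, ...) {
  snps <- object$snps
  gg <- ggplot2::ggplot(snps, ggplot2::aes(x = .data$pos / 1e6, y = .data$gprime)) +
    ggplot2::geom_line(colour = "grey40", linewidth = 0.3) +
    ggplot2::geom_point(
      data = dplyr::filter(snps, .data$sig),
      colour = "firebrick", size = 0.6
    ) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(
      x = "position (Mbp)", y = "G'",
      title = "Tricube-smoothed G' scan",
      subtitle = sprintf(
        "%s-corrected alpha = %g; %d QTL interval(s)",
        object$cfg$correction, object$cfg$alpha, nrow(object$intervals)
      )
    ) +
    ggplot2::theme_minimal()
  if (nrow(object$intervals) > 0) {
    gg <- gg + ggplot2::geom_rect(
      data = object$intervals,
      ggplot2::aes(
        xmin = .data$start_bp / 1e6, xmax = .data$end_bp / 1e6,
        ymin = -Inf, ymax = Inf
      ),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.1
    )
  }
  gg
}

#' @rdname autoplot.gprime_scan
#' @param scan A `gprime_scan` object.
#' @export
plot_gprime <- function(scan) autoplot(scan)

#' Boxplot of DRYM by bulk
#'
#' The classic bulk-separation figure: per-experiment DRYM of the clones
#' assigned to each bulk.
#'
#' @param drym_table Output of [compute_drym()].
#' @param assignment A `bulk_assignment` from [select_bulks()].
#' @return A ggplot.
#' @export
plot_drym_bulks <- function(drym_table, assignment) {
  dat <- drym_table %>%
    dplyr::mutate(bulk = dplyr::case_when(
      .data$genotype_id %in% assignment$tolerant_ids ~ "tolerant",
      .data$genotype_id %in% assignment$sensitive_ids ~ "sensitive",
      .default = NA_character_
    )) %>%
    dplyr::filter(!is.na(.data$bulk))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bulk, y = .data$drym, fill = .data$bulk)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "DRYM", title = "Bulk separation by DRYM") +
    ggplot2::theme_minimal()
}

#' Rolling-window allele-frequency track
#'
#' @param windows Output of [rolling_windows()].
#' @return A ggplot.
#' @export
plot_windows <- function(windows) {
  ggplot2::ggplot(
    dplyr::filter(windows, .data$n_snps > 0),
    ggplot2::aes(x = (.data$window_start + .data$window_end) / 2e6, y = .data$mean)
  ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(
      x = "position (Mbp)", y = "window mean allele frequency",
      title = "Rolling-window allele frequency"
    ) +
    ggplot2::theme_minimal()
}
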