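#' Volcano plot of a differential-expression result
#'
#' Signed log2 fold change against -log10 p, with the joint significance
#' rule's thresholds drawn and significant features highlighted.
#'
#' @param object A `de_result` from [differential_expression()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.de_result <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(log2_ratio = log2(.data$ratio),
           neg_log10_p = -log10(pmax(.data$p, .Machine$double.xmin)))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2_ratio, .data$neg_log10_p,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 expression ratio", y = "-log10 p",
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Growth curves on a log OD scale
#'
#' @param curve Growth tibble (`time_h`, `od`, `replicate`, optional
#'   `strain`/`medium`).
#' @param od_window Optional OD window to shade (e.g. `c(0.1, 0.3)`).
#' @return A ggplot with log10 OD600 against time, one line per replicate.
#' @export
plot_growth_curves <- function(curve, od_window = NULL) {
  curve <- as_tibble(curve)
  if (!"strain" %in% names(curve)) curve$strain <- "strain"
  p <- ggplot2::ggplot(curve,
                       ggplot2::aes(.data$time_h, .data$od,
                                    group = interaction(.data$strain,
                                                        .data$replicate),
                                    colour = .data$strain)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "OD600") +
    ggplot2::theme_minimal()
  if (!is.null(od_window)) {
    p <- p + ggplot2::geom_hline(yintercept = od_window, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' Aligned diauxic-shift overlay
#'
#' Replicates aligned at their own first-phase end (time zero), the overlay
#' used to compare strains that enter the shift at different times.
#'
#' @param object A `diauxic_alignment` from [detect_first_phase_end()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.diauxic_alignment <- function(object, ...) {
  ggplot2::ggplot(object$aligned,
                  ggplot2::aes(.data$relative_time, .data$od,
                               group = interaction(.data$strain,
                                                   .data$replicate),
                               colour = .data$strain)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time relative to end of first growth phase (h)",
                  y = "OD600") +
    ggplot2::theme_minimal()
}

#' Metabolite time-course with error bars
#'
#' @param object A `timecourse` from [excretion_timecourse()].
#' @param ... Unused.
#' @return A ggplot of mean RRF +/- sd against time, faceted by compound.
#' @export
autoplot.timecourse <- function(object, ...) {
  ggplot2::ggplot(object$series,
                  ggplot2::aes(.data$time_h, .data$mean_rrf,
                               colour = .data$strain)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_rrf - .data$sd_rrf,
      ymax = .data$mean_rrf + .data$sd_rrf)) +
    ggplot2::facet_wrap(~compound, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "relative response factor") +
    ggplot2::theme_minimal()
}

#' Experiment dendrogram
#'
#' @param object An `experiment_clustering` from [cluster_experiments()].
#' @param ... Unused.
#' @return A ggplot dendrogram (segments computed from the merge tree).
#' @export
autoplot.experiment_clustering <- function(object, ...) {
  hc <- object$hclust
  n <- length(hc$labels)
  xpos <- numeric(n)                      # leaf x by plotting order
  xpos[hc$order] <- seq_len(n)
  node_x <- numeric(nrow(hc$merge))
  node_h <- hc$height
  segs <- vector("list", nrow(hc$merge))
  at <- function(i) if (i < 0) c(xpos[-i], 0) else c(node_x[i], node_h[i])
  for (k in seq_len(nrow(hc$merge))) {
    l <- at(hc$merge[k, 1]); r <- at(hc$merge[k, 2])
    node_x[k] <- mean(c(l[1], r[1]))
    segs[[k]] <- tibble(
      x = c(l[1], r[1], l[1]), xend = c(l[1], r[1], r[1]),
      y = c(l[2], r[2], node_h[k]), yend = c(node_h[k], node_h[k], node_h[k]))
  }
  labels <- tibble(x = xpos, label = hc$labels)
  ggplot2::ggplot(bind_rows(segs)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = labels,
                       ggplot2::aes(.data$x, -0.02 * max(node_h),
                                    label = .data$label),
                       angle = 90, hjust = 1, size = 3) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.35, 0.05))) +
    ggplot2::labs(x = NULL, y = "1 - Pearson correlation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}
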