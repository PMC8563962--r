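#' Plot an AUC track with its segmentation
#'
#' Shows the per-site AUC values along the genome, coloured by the decoded
#' segment state, with DMRs highlighted as horizontal bars at their mean
#' AUC. One facet per chromosome.
#'
#' @param object A `rocker_fit` from [detect_dmrs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rocker_fit
#' @export
autoplot.rocker_fit <- function(object, ...) {
  sites <- object$auc
  seg <- object$segments
  sites$state <- "neutral"
  for (i in seq_len(nrow(seg))) {
    sites$state[seg$start_index[i]:seg$end_index[i]] <- seg$state[i]
  }
  pal <- c(hypo = "#2166ac", neutral = "grey60", hyper = "#b2182b")
  p <- ggplot2::ggplot(sites, ggplot2::aes(.data$pos, .data$auc)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$state), size = 0.4) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = pal) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "AUC", colour = "state") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (nrow(object$dmrs) > 0) {
    p <- p + ggplot2::geom_segment(
      data = object$dmrs,
      ggplot2::aes(
        x = .data$start, xend = .data$end,
        y = .data$mean_auc, yend = .data$mean_auc
      ),
      linewidth = 1.5, colour = "black"
    )
  }
  p
}

#' Plot per-sample support fractions by DMR class
#'
#' Boxplots of the per-sample fraction of supporting events for each DMR
#' class, one panel layout familiar from burden summaries.
#'
#' @param psfse_tbl Output of [psfse()] or [pcfse()].
#' @return A ggplot object.
#' @export
plot_psfse <- function(psfse_tbl) {
  ggplot2::ggplot(psfse_tbl, ggplot2::aes(.data$state, .data$psfse)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, size = 0.7, alpha = 0.6) +
    ggplot2::labs(x = "DMR class", y = "fraction of supported DMRs") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Heatmap of sample scores across a DMR catalog
#'
#' @param object A `rocker_scores` tibble from [score_samples()].
#' @param cap Absolute score value at which the colour scale saturates.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rocker_scores
#' @export
autoplot.rocker_scores <- function(object, cap = 10, ...) {
  dat <- mutate(object,
    score_c = pmax(pmin(.data$score, cap), -cap),
    dmr = factor(.data$dmr_id)
  )
  ggplot2::ggplot(dat, ggplot2::aes(.data$sample, .data$dmr, fill = .data$score_c)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "white", high = "#b2182b", midpoint = 0
    ) +
    ggplot2::facet_grid(state ~ ., scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "sample", y = "DMR", fill = "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5),
      axis.text.y = ggplot2::element_blank()
    )
}
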