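#' Plot SeRP enrichment profiles
#'
#' Draws the smoothed IP/total enrichment along each ORF, one facet per
#' transcript, with the neutral enrichment of 1 as a dashed reference. When
#' onset calls are supplied, detected onsets are marked with a vertical
#' line.
#'
#' @param object An [enrichment_profile()] tibble.
#' @param calls Optional `onset_calls` tibble from [call_onset()].
#' @param transcripts Optional character vector restricting the plot to
#'   those transcripts.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_profile
#' @export
autoplot.enrichment_profile <- function(object, calls = NULL,
                                        transcripts = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(transcripts)) {
    df <- dplyr::filter(df, .data$transcript_id %in% transcripts)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$codon,
                                        y = .data$enrichment)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::facet_wrap(~transcript_id, scales = "free_x") +
    ggplot2::labs(x = "Codon", y = "IP / total enrichment") +
    ggplot2::theme_minimal()
  if (!is.null(calls)) {
    onsets <- dplyr::filter(as_tibble(calls), .data$detected)
    if (!is.null(transcripts)) {
      onsets <- dplyr::filter(onsets, .data$transcript_id %in% transcripts)
    }
    if (nrow(onsets)) {
      p <- p + ggplot2::geom_vline(
        data = onsets,
        ggplot2::aes(xintercept = .data$onset_codon),
        colour = "#b2182b", linetype = "dotted")
    }
  }
  p
}

#' Plot a yield-vs-subunit-number curve
#'
#' Yield on a log scale against the number of subunits, coloured by
#' topology; the exponential decay of sequential assembly appears as a
#' straight line when the orphan hazard is zero.
#'
#' @param object A `yield_curve` from [yield_vs_n()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot yield_curve
#' @export
autoplot.yield_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$n, y = .data$yield,
                               colour = .data$topology)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Number of subunits", y = "Expected yield",
                  colour = "Topology") +
    ggplot2::theme_minimal()
}

#' Plot RIP-qPCR fold enrichments behind a set of calls
#'
#' Per-biological-replicate fold enrichments by treatment for every
#' bait-target pair, with the decision threshold as a dashed line.
#'
#' @param object A `qpcr_calls` result from [qpcr_calls()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qpcr_calls
#' @export
autoplot.qpcr_calls <- function(object, ...) {
  folds <- attr(object, "folds")
  if (is.null(folds)) abort("This qpcr_calls object carries no fold data.")
  thr <- object$threshold[1]
  ggplot2::ggplot(folds, ggplot2::aes(x = .data$treatment, y = .data$fold)) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.8,
                         colour = "#2166ac") +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "#b2182b", linewidth = 0.3) +
    ggplot2::facet_wrap(~bait + target_mrna) +
    ggplot2::labs(x = NULL, y = "Fold enrichment over no-bait") +
    ggplot2::theme_minimal()
}
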