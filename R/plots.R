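# ggplot2 views of the main result types.

#' @describeIn wavelet_coherence Time-frequency raster of a coherence
#'   result with the cone of influence overlaid.
#' @param object A `cmc_coherence` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.cmc_coherence <- function(object, ...) {
  n <- ncol(object$coherence)
  df <- tidyr::expand_grid(freq = object$freqs,
                           time = (seq_len(n) - 1) / object$fs)
  df$coherence <- as.vector(object$coherence)
  coi <- tibble::tibble(time = (seq_len(n) - 1) / object$fs,
                        freq = pmin(object$coi, max(object$freqs)))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$freq,
                                   fill = .data$coherence)) +
    ggplot2::geom_raster() +
    ggplot2::geom_line(data = coi, ggplot2::aes(.data$time, .data$freq),
                       inherit.aes = FALSE, linetype = 2,
                       colour = "white") +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)",
                  fill = "coherence")
}

#' Scatter of the 2-D embedding coloured by group
#'
#' @param stage1 A `cmc_stage1` object (with a non-null embedding).
#' @return A ggplot.
#' @export
plot_embedding <- function(stage1) {
  emb <- stage1$embedding
  if (is.null(emb)) stop("stage-1 result has no embedding")
  emb$group <- factor(emb$group, levels = c(0, 1),
                      labels = c("stroke", "healthy"))
  ggplot2::ggplot(emb, ggplot2::aes(.data$dim1, .data$dim2,
                                    colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "dimension 1", y = "dimension 2", colour = NULL)
}

#' Beeswarm-style Shapley plot for a regression fit
#'
#' @param fit A `cmc_regfit`.
#' @param split `"train"` or `"test"`.
#' @param top_n Number of features shown (by mean absolute attribution).
#' @return A ggplot.
#' @export
plot_shap_beeswarm <- function(fit, split = "train", top_n = 10) {
  sr <- shap_rank(fit, split)
  keep <- head(sr$ranking$feature, top_n)
  df <- sr$beeswarm[sr$beeswarm$feature %in% keep, ]
  df$feature <- factor(df$feature, levels = rev(keep))
  ggplot2::ggplot(df, ggplot2::aes(.data$shap, .data$feature,
                                   colour = .data$value)) +
    ggplot2::geom_jitter(height = 0.2, width = 0, size = 1.5) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::scale_colour_gradient2(low = "#2166ac", mid = "grey80",
                                    high = "#b2182b") +
    ggplot2::labs(x = "Shapley attribution", y = NULL,
                  colour = "feature\nvalue (z)")
}

#' Predicted-versus-observed scatter for regression fits
#'
#' @param stage2 A `cmc_stage2` object (or a single `cmc_regfit`).
#' @return A ggplot faceted by fit.
#' @export
plot_predictions <- function(stage2) {
  fits <- if (inherits(stage2, "cmc_regfit")) {
    stats::setNames(list(stage2), paste(stage2$target, stage2$family,
                                        sep = "_"))
  } else stage2$fits
  df <- purrr::imap_dfr(fits, function(f, key)
    dplyr::mutate(f$predictions, fit = key))
  df$group <- factor(df$group, levels = c(0, 1),
                     labels = c("stroke", "healthy"))
  ggplot2::ggplot(df, ggplot2::aes(.data$observed, .data$predicted,
                                   colour = .data$group,
                                   shape = .data$split)) +
    ggplot2::geom_abline(linetype = 3) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~fit, scales = "free") +
    ggplot2::labs(colour = NULL, shape = NULL)
}
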