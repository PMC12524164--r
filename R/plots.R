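#' Plot a zone map
#'
#' Raster plot of the five-region zone map with the field's usual
#' colouring (portal blue, periportal purple, zone 2 green, central
#' vein brown, pericentral yellow).
#'
#' @param zone_map Zone map from [build_zone_map()].
#' @param downsample Keep every k-th pixel for display (default chosen
#'   so the long side is about 400 px).
#' @return A ggplot object.
#' @export
plot_zone_map <- function(zone_map, downsample = NULL) {
  if (is.null(downsample)) {
    downsample <- max(1L, floor(max(dim(zone_map)) / 400))
  }
  z <- zone_map[seq(1, nrow(zone_map), by = downsample),
                seq(1, ncol(zone_map), by = downsample)]
  df <- tidyr::expand_grid(row = seq_len(nrow(z)), col = seq_len(ncol(z)))
  df$zone <- factor(zone_name(as.vector(z)), levels = names(ZONE_CODES))
  cols <- c(background = "grey90", lumen = "white", portal = "#3B6FB6",
            periportal = "#8C6BB1", zone2 = "#41AB5D",
            pericentral = "#FFD92F", central_vein = "#8C510A")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$zone)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = cols, drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "region")
}

#' Plot score distributions by fibrosis stage
#'
#' Box plots of a continuous score over the ordinal stages, the usual
#' way a digital-pathology score is shown against histology.
#'
#' @param data Tibble with the score and stage columns.
#' @param score,stage Column names (strings).
#' @return A ggplot object.
#' @export
plot_score_by_stage <- function(data, score, stage = "stage") {
  df <- tibble::tibble(
    stage = factor(paste0("F", data[[stage]])),
    value = data[[score]]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "white", outlier.size = 0.8) +
    ggplot2::labs(x = "fibrosis stage", y = score) +
    ggplot2::theme_classic()
}

#' Plot a Spearman correlation heatmap
#'
#' @param corr Long tibble from [spearman_matrix()].
#' @param sig_level Cells with `p_adj` below this are starred
#'   (default 0.05).
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(corr, sig_level = 0.05) {
  corr$star <- ifelse(!is.na(corr$p_adj) & corr$p_adj < sig_level, "*", "")
  ggplot2::ggplot(corr, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$star), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#542788", mid = "white",
                                  high = "#E66101", limits = c(-1, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "rho")
}

#' Plot random-forest variable importance
#'
#' @param importance Tibble from [rf_importance()].
#' @param top_n Show the `top_n` highest-ranked features (default 15).
#' @return A ggplot object.
#' @export
plot_importance <- function(importance, top_n = 15) {
  df <- utils::head(dplyr::arrange(importance, .data$rank), top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mse_increase,
                                   y = .data$feature)) +
    ggplot2::geom_col(fill = "#3B6FB6") +
    ggplot2::labs(x = "increase in OOB MSE (%)", y = NULL) +
    ggplot2::theme_classic()
}
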