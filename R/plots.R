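#' Plot an anomaly map as axial slices
#'
#' Voxel-wise anomaly scores tiled per axial (z) slice; invalid voxels
#' (tumour-excluded or degenerate) are blank.
#'
#' @param object An `fca_anomaly`.
#' @param slices Optional integer vector of 0-based z indices (defaults to
#'   all slices containing valid voxels).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fca_anomaly <- function(object, slices = NULL, ...) {
  ijk <- index_to_ijk(object$grid, object$mask$members)
  df <- tibble::tibble(i = ijk[, "i"], j = ijk[, "j"], k = ijk[, "k"],
                       score = object$score)
  if (!is.null(slices)) df <- df[df$k %in% slices, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~k, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "grey95",
                                  high = "#2166ac", midpoint = 0,
                                  na.value = "black") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Anomaly map: %s [%s]", object$subject,
                                  object$session_label),
                  fill = "score") +
    ggplot2::theme_minimal()
}

#' Plot a fitted quadratic trajectory trend
#'
#' @param object An `fca_trend`.
#' @param ... Unused.
#' @return A ggplot object showing the pooled points and the fitted curve.
#' @export
autoplot.fca_trend <- function(object, ...) {
  co <- object$coefficients
  grid <- tibble::tibble(session = seq(min(object$data$session),
                                       max(object$data$session), length.out = 100))
  grid$value <- co["a"] + co["b"] * grid$session + co["c"] * grid$session^2
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$session, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.05, height = 0, alpha = 0.5) +
    ggplot2::geom_line(data = grid, colour = "#2166ac", linewidth = 1) +
    ggplot2::labs(x = "session (0 = pre-surgery)",
                  y = "baseline-subtracted median anomaly",
                  title = sprintf("Quadratic trend (r2 = %s, RMSE = %.3g)",
                                  ifelse(is.na(object$r_squared), "NA",
                                         sprintf("%.2f", object$r_squared)),
                                  object$rmse)) +
    ggplot2::theme_minimal()
}

#' Plot a bi-hemispheric symmetry correlation matrix
#'
#' @param correlations Output of [symmetry_correlation()].
#' @param compartment `"cerebrum"` or `"cerebellum"`.
#' @return A ggplot tile plot of r-squared values.
#' @export
plot_symmetry_matrix <- function(correlations, compartment = "cerebrum") {
  df <- correlations[correlations$compartment == compartment, ]
  df$network_ipsi <- factor(df$network_ipsi, levels = network_names)
  df$network_contra <- factor(df$network_contra, levels = network_names)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$network_contra,
                                   y = .data$network_ipsi,
                                   fill = .data$r2)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r2)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "grey95", high = "#2166ac",
                                 limits = c(0, 1), na.value = "grey80") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "contralateral network", y = "ipsilateral network",
                  title = sprintf("Bi-hemispheric r2 (%s)", compartment)) +
    ggplot2::theme_minimal()
}

#' Plot lesion-map / anomaly overlap correlation curves
#'
#' @param overlap Output of [lesion_anomaly_overlap()].
#' @return A ggplot of the per-hemisphere correlation across anomaly
#'   thresholds.
#' @export
plot_overlap_curves <- function(overlap) {
  ggplot2::ggplot(overlap$curves,
                  ggplot2::aes(x = .data$threshold, y = .data$r,
                               colour = .data$side, group = .data$side)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "anomaly threshold (score < -t)",
                  y = "lesion-map / anomaly overlap correlation",
                  colour = "hemisphere vs tumour") +
    ggplot2::theme_minimal()
}
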