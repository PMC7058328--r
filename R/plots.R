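# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a scale-of-effect profile
#'
#' Univariate fit quality (Nagelkerke R-squared) against buffer scale,
#' with the scale of effect highlighted.
#'
#' @param object a `scale_profile` from [scale_profile_scan()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.scale_profile <- function(object, ...) {
  soe <- scale_of_effect(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$scale, y = .data$rn2)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$sign), size = 2) +
    ggplot2::geom_vline(xintercept = soe, linetype = "dashed") +
    ggplot2::labs(
      x = "buffer scale (m)", y = expression(R[N]^2),
      title = paste0(object$variable[1], ": scale of effect ", soe, " m"),
      colour = "effect sign"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a predicted-occupancy curve
#'
#' @param object a `psi_curve` from [prediction_curve()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.psi_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$psi)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = object$variable[1], y = "predicted occupancy probability"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic landscape
#'
#' Land-cover raster with patch outlines and the river polyline.
#'
#' @param object an `occ_landscape` from [generate_landscape()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.occ_landscape <- function(object, ...) {
  r <- object$land_cover
  ctr <- cell_centers(r)
  df <- tibble::tibble(
    x = ctr[, 1], y = ctr[, 2],
    class = factor(
      object$class_table$class[match(as.vector(r$values), object$class_table$code)]
    )
  )
  outlines <- purrr::imap(object$patches$polygon, function(poly, i) {
    ring <- close_ring(poly)
    tibble::tibble(patch_id = object$patches$patch_id[i], x = ring[, 1], y = ring[, 2])
  }) |> dplyr::bind_rows()
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$class)) +
    ggplot2::geom_path(
      data = outlines,
      ggplot2::aes(group = .data$patch_id),
      colour = "black", linewidth = 0.3
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "land cover") +
    ggplot2::theme_minimal()
  if (!is.null(object$river)) {
    riv <- tibble::tibble(x = object$river[, 1], y = object$river[, 2])
    gg <- gg + ggplot2::geom_path(data = riv, colour = "steelblue", linewidth = 0.6)
  }
  gg
}
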