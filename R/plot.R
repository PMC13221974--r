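#' Plot a sampled surface field
#'
#' Equirectangular map of the sphere with the chosen channel as fill; ray
#' misses (if any) are overplotted as points.
#'
#' @param object A `lira_surface`.
#' @param channel `"shape"` (radius, Angstrom) or `"esp"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.lira_surface <- function(object, channel = c("shape", "esp"), ...) {
  channel <- match.arg(channel)
  value <- if (channel == "shape") object$radius else object$esp
  df <- tibble::tibble(theta = object$theta, phi = object$phi, value = value,
                       miss = object$miss)
  lab <- if (channel == "shape") "radius (Å)" else "ESP (kcal/mol/e)"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$phi, y = .data$theta)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::labs(
      x = expression(phi ~ "(rad)"), y = expression(theta ~ "(rad)"),
      title = sprintf("Star-shaped surface '%s'", attr(object, "molecule_id"))
    ) +
    ggplot2::theme_minimal()
  if (any(df$miss)) {
    p <- p + ggplot2::geom_point(data = df[df$miss, ], size = 0.3,
                                 colour = "red")
  }
  p
}

#' Plot a rotation-invariant fingerprint spectrum
#'
#' @param object A `lira_rif`.
#' @param ... Unused.
#' @return A ggplot object: per-degree amplitude versus degree.
#' @export
autoplot.lira_rif <- function(object, ...) {
  unit <- if (attr(object, "channel") == "shape") "Å" else "kcal/mol/e"
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$l, y = .data$amplitude)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "degree l", y = sprintf("A_l (%s)", unit),
                  title = sprintf("RIF spectrum (%s channel, total %.3f)",
                                  attr(object, "channel"), attr(object, "total"))) +
    ggplot2::theme_minimal()
}

#' Plot a hit list
#'
#' Per-channel DRIF of each hit against its rank, with the combined score.
#'
#' @param object A `lira_hits`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lira_hits <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("rank", "drif_shape", "drif_esp", "score")],
    -"rank", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "rank", y = "distance / score",
                  title = sprintf("Screening hits for '%s'",
                                  attr(object, "query_id"))) +
    ggplot2::theme_minimal()
}

#' @export
plot.lira_surface <- function(x, ...) print(autoplot.lira_surface(x, ...))
#' @export
plot.lira_rif <- function(x, ...) print(autoplot.lira_rif(x, ...))
#' @export
plot.lira_hits <- function(x, ...) print(autoplot.lira_hits(x, ...))
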