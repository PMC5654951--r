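#' Plot a density profile
#'
#' Line plot of per-residue coverage height, optionally shading hotspot
#' intervals.
#'
#' @param object A `density_profile`.
#' @param hotspots Optional `hotspot_table` from [segment_hotspots()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.density_profile <- function(object, hotspots = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$position,
                                            y = .data$height)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::labs(
      x = "residue position",
      y = "peptides covering residue",
      title = paste0(
        attr(object, "protein_id"), " (HLA ", attr(object, "class_selector"),
        " profile)"
      )
    ) +
    ggplot2::theme_minimal()
  if (!is.null(hotspots) && nrow(hotspots) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = as.data.frame(hotspots),
      ggplot2::aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "firebrick",
      inherit.aes = FALSE
    )
  }
  p
}

#' Plot a peptide length distribution
#'
#' @param db A `peptidome_db`.
#' @param class_selectors Selectors to overlay (default class I and II).
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(db, class_selectors = c("I", "II")) {
  dat <- purrr::map(class_selectors, function(cs) {
    d <- length_distribution(db, cs)
    d$class_selector <- cs
    tibble::as_tibble(d)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$length, y = .data$n,
                                    fill = .data$class_selector)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "peptide length (residues)", y = "unique peptides",
                  fill = "HLA class") +
    ggplot2::theme_minimal()
}

#' Plot a recovery curve
#'
#' @param object A `recovery_curve` from [rank_by_feature()].
#' @param max_rank Truncate the x-axis (default: full curve).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_curve <- function(object, max_rank = NULL, ...) {
  dat <- if (is.null(max_rank)) object else object[object$rank <= max_rank, ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rank, y = .data$recovered)) +
    ggplot2::geom_step(colour = "firebrick") +
    ggplot2::labs(
      x = "rank", y = "immunogenic peptides recovered",
      title = paste0("ranked by ", attr(object, "feature"),
                     " (", attr(object, "direction"), ")")
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
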