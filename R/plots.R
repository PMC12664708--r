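#' Plotting helpers
#'
#' ggplot2 visualisations for mazes, shank-angle waveforms with detected
#' events, session trajectories with heel strikes, and association
#' tables.
#'
#' @name plots
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a maze: walls, entry/exit, and optionally the solution path
#'
#' @param object a `vrgait_maze`.
#' @param show_path draw the unique solution path (default `TRUE`).
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.vrgait_maze <- function(object, show_path = TRUE, ...) {
  b <- object$block_size
  # walls = grid edges between adjacent cells that are not open passages
  open <- paste(pmin(object$edges[, 1], object$edges[, 2]),
                pmax(object$edges[, 1], object$edges[, 2]))
  walls <- list()
  for (r in seq_len(object$rows)) {
    for (c in seq_len(object$cols)) {
      id <- cell_id(r, c, object$cols)
      if (c < object$cols) {
        nb <- cell_id(r, c + 1L, object$cols)
        if (!(paste(min(id, nb), max(id, nb)) %in% open)) {
          walls[[length(walls) + 1]] <- c(c * b, (r - 1) * b, c * b, r * b)
        }
      }
      if (r < object$rows) {
        nb <- cell_id(r + 1L, c, object$cols)
        if (!(paste(min(id, nb), max(id, nb)) %in% open)) {
          walls[[length(walls) + 1]] <- c((c - 1) * b, r * b, c * b, r * b)
        }
      }
    }
  }
  wd <- as.data.frame(do.call(rbind, walls))
  names(wd) <- c("x", "y", "xend", "yend")
  ends <- tibble::tibble(
    x = (c(object$entry[2], object$exit[2]) - 0.5) * b,
    y = (c(object$entry[1], object$exit[1]) - 0.5) * b,
    what = c("entry", "exit")
  )
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = tibble::tibble(x = 0), inherit.aes = FALSE,
      xmin = 0, xmax = object$cols * b, ymin = 0, ymax = object$rows * b,
      fill = NA, colour = "grey20"
    ) +
    ggplot2::geom_segment(
      data = wd,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey20"
    ) +
    ggplot2::geom_point(
      data = ends,
      ggplot2::aes(.data$x, .data$y, shape = .data$what), size = 3
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", shape = NULL) +
    ggplot2::theme_minimal()
  if (show_path) {
    path <- solution_path(object)
    p <- p + ggplot2::geom_path(
      data = path, ggplot2::aes(.data$x, .data$y),
      colour = "steelblue", linewidth = 1
    )
  }
  p
}

#' Plot a shank-angle waveform with detected events
#'
#' @param waveform output of [shank_angle()].
#' @param events optional event tibble from [detect_events()].
#' @return a ggplot.
#' @export
plot_shank_angle <- function(waveform, events = NULL) {
  p <- ggplot2::ggplot(waveform, ggplot2::aes(.data$t, .data$alpha)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::labs(x = "time (s)", y = expression(alpha ~ "(deg)")) +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    ev <- dplyr::mutate(events, alpha = waveform$alpha[.data$sample_index])
    p <- p + ggplot2::geom_point(
      data = ev, ggplot2::aes(colour = .data$kind), size = 2
    )
  }
  p
}

#' Plot a session trajectory with heel-strike positions
#'
#' Navel path in the horizontal plane with left/right heel-strike
#' locations from an analysis.
#'
#' @param object a `vrgait_analysis`.
#' @param session the analysed `vrgait_session`.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.vrgait_analysis <- function(object, session, ...) {
  nav <- session$streams$navel
  hs <- dplyr::distinct(
    tibble::tibble(
      x = c(object$strides$x_initial, object$strides$x_terminal),
      y = c(object$strides$y_initial, object$strides$y_terminal),
      side = rep(object$strides$side, 2)
    )
  )
  ggplot2::ggplot() +
    ggplot2::geom_path(data = nav, ggplot2::aes(.data$px, .data$py),
                       colour = "grey60") +
    ggplot2::geom_point(data = hs,
                        ggplot2::aes(.data$x, .data$y, colour = .data$side)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = "heel strikes") +
    ggplot2::theme_minimal()
}

#' Heatmap of an association table
#'
#' Coefficient grid (outcomes x tests) per condition-by-visit stratum,
#' with significant cells outlined.
#'
#' @param assoc output of [build_association_table()].
#' @return a ggplot.
#' @export
plot_association_table <- function(assoc) {
  assoc$stratum <- paste(assoc$condition, assoc$visit)
  ggplot2::ggplot(assoc, ggplot2::aes(.data$test, .data$outcome,
                                      fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(
      data = assoc[assoc$significant, ],
      fill = NA, colour = "black", linewidth = 0.7
    ) +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
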