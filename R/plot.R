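# ggplot2 visualisations: annotated traces, transmission dynamics,
# compressed-graph renderings, group histograms, per-frame overlays.

#' Plot one cell's trace with EMA lines, baseline and detected events
#'
#' @param traces Trace container accepted by [detect_events()].
#' @param cell Column index of the cell to plot.
#' @inheritParams detect_events
#' @return A ggplot object: intensity, forward/backward EMA, baseline, and
#'   shaded detected events.
#' @export
plot_trace <- function(traces, cell = 1L, k = 0.97, threshold = 0) {
  m <- as_trace_matrix(traces)
  tr <- m[, cell]
  ef <- ema_forward(tr, k)
  eb <- ema_backward(tr, k)
  bl <- compute_baseline(tr, ef)
  ev <- detect_events(tr, k = k, threshold = threshold)
  lines <- tibble::tibble(
    frame = rep(seq_along(tr), 4L),
    value = c(tr, ef, eb, as.numeric(bl)),
    series = rep(c("intensity", "EMA forward", "EMA backward", "baseline"),
                 each = length(tr)))
  p <- ggplot2::ggplot(lines, ggplot2::aes(.data$frame, .data$value,
                                           colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "intensity",
                  title = paste("cell", cell)) +
    ggplot2::theme_minimal()
  if (nrow(ev)) {
    p <- p + ggplot2::geom_rect(
      data = ev, inherit.aes = FALSE, alpha = 0.15, fill = "red",
      ggplot2::aes(xmin = .data$start, xmax = .data$finish,
                   ymin = -Inf, ymax = Inf))
  }
  p
}

#' Transmission dynamics of a dynamic graph
#'
#' Per-frame number of simultaneously present directed edges.
#'
#' @param object A `dynamic_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dynamic_graph <- function(object, ...) {
  ept <- edges_per_frame(object)
  ggplot2::ggplot(tibble::tibble(frame = seq_along(ept), edges = ept),
                  ggplot2::aes(.data$frame, .data$edges)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "frame", y = "transmissions |E_t|",
                  title = "Dynamics of the number of transmissions") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.dynamic_graph
#' @export
plot_transmission_dynamics <- function(object, ...) {
  autoplot.dynamic_graph(object, ...)
}

#' Render a compressed transmission graph over region centers
#'
#' In `"two_colour"` mode each direction of a pair is drawn as its own
#' arrow, coloured by direction, line width scaled by the transmission
#' count. In `"contrast"` mode a single arrow is drawn in the prevailing
#' direction of each pair with opacity proportional to the absolute arc
#' label `|b_ij| = |c_ij - c_ji|`, and vertex size proportional to
#' in-degree.
#'
#' @param object A `compressed_graph`.
#' @param centers Region centers tibble from [region_centers()].
#' @param mode `"two_colour"` or `"contrast"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.compressed_graph <- function(object, centers,
                                      mode = c("two_colour", "contrast"),
                                      ...) {
  mode <- match.arg(mode)
  if (missing(centers) || is.null(centers)) {
    stop("`centers` are required to draw the graph.", call. = FALSE)
  }
  stopifnot(all(c("cell_id", "row", "col") %in% names(centers)))
  deg <- degree_centrality(object)
  nodes <- dplyr::left_join(centers, deg, by = "cell_id")
  e <- object$edges
  if (mode == "contrast") e <- dplyr::filter(e, .data$balance > 0)
  e <- e |>
    dplyr::left_join(centers, by = c(source = "cell_id")) |>
    dplyr::rename(x0 = "col", y0 = "row") |>
    dplyr::left_join(centers, by = c(target = "cell_id")) |>
    dplyr::rename(x1 = "col", y1 = "row")
  p <- ggplot2::ggplot() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (nrow(e)) {
    arr <- ggplot2::arrow(length = ggplot2::unit(0.12, "inches"))
    if (mode == "two_colour") {
      p <- p + ggplot2::geom_segment(
        data = e,
        ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                     yend = .data$y1,
                     colour = .data$source < .data$target,
                     linewidth = .data$count),
        arrow = arr, show.legend = FALSE) +
        ggplot2::scale_colour_manual(values = c("red", "darkgreen")) +
        ggplot2::scale_linewidth(range = c(0.3, 1.6))
    } else {
      p <- p + ggplot2::geom_segment(
        data = e,
        ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                     yend = .data$y1,
                     alpha = .data$balance),
        colour = "black", arrow = arr, show.legend = FALSE) +
        ggplot2::scale_alpha(range = c(0.2, 1))
    }
  }
  p + ggplot2::geom_point(
    data = nodes,
    ggplot2::aes(x = .data$col, y = .data$row,
                 size = if (mode == "contrast") .data$indegree else 3),
    colour = "grey30", show.legend = FALSE) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$col, y = .data$row, label = .data$cell_id),
      colour = "white", size = 2.5)
}

#' @rdname autoplot.compressed_graph
#' @export
plot_compressed <- function(object, centers,
                            mode = c("two_colour", "contrast"), ...) {
  autoplot.compressed_graph(object, centers, mode = mode, ...)
}

#' Plot group histograms of per-cell transmission counts
#'
#' One line per group over the transfer counts i = 1..max, height in cells
#' per hundred.
#'
#' @param histograms Output of [group_histogram()].
#' @return A ggplot object.
#' @export
plot_group_histogram <- function(histograms) {
  stopifnot(all(c("group", "i", "n_i") %in% names(histograms)))
  ggplot2::ggplot(histograms,
                  ggplot2::aes(.data$i, .data$n_i,
                               colour = factor(.data$group))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "transmissions per cell",
                  y = "cells per 100", colour = "group") +
    ggplot2::theme_minimal()
}

#' Per-cell transmission map on the label image
#'
#' Fills each region with its total transfer count, showing how uniformly
#' transmissions are distributed over the field.
#'
#' @param cg A `compressed_graph`.
#' @param labels Label image matching the graph's cells.
#' @return A ggplot object.
#' @export
plot_transmission_map <- function(cg, labels) {
  check_label_image(labels)
  transfers <- per_cell_transfers(cg)
  fill <- c(NA_real_, transfers$transfers)[as.vector(labels) + 1L]
  df <- tibble::tibble(
    row = rep(seq_len(nrow(labels)), times = ncol(labels)),
    col = rep(seq_len(ncol(labels)), each = nrow(labels)),
    transfers = fill)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$transfers)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "black") +
    ggplot2::labs(fill = "transfers") +
    ggplot2::theme_void()
}

#' Render dynamic-graph overlay frames to PNG files
#'
#' For each requested frame, fills every region with the deviation of its
#' trace from the baseline (the `"deviation"` substrate) or with its raw
#' intensity (`"intensity"`), then overlays an arrow from the center of the
#' source region to the center of the target region for every edge active
#' on that frame. One PNG per frame is written to `out_dir`; the files can
#' be assembled into a video by any external encoder.
#'
#' @param g A `dynamic_graph`.
#' @param traces Trace container the graph was built from.
#' @param labels Label image.
#' @param centers Region centers from [region_centers()]; required.
#' @param out_dir Output directory (created if needed).
#' @param frames Frames to render; default all frames with at least one
#'   active edge (or frame 1 if there are none).
#' @param substrate `"deviation"` or `"intensity"`.
#' @inheritParams detect_events
#' @param width,height Device size in pixels.
#' @return Invisibly, the written file paths.
#' @export
render_dynamic_frames <- function(g, traces, labels, centers, out_dir,
                                  frames = NULL,
                                  substrate = c("deviation", "intensity"),
                                  k = 0.97, width = 480, height = 480) {
  stopifnot(inherits(g, "dynamic_graph"))
  substrate <- match.arg(substrate)
  if (missing(centers) || is.null(centers)) {
    stop("`centers` are required to draw arrows.", call. = FALSE)
  }
  check_label_image(labels)
  m <- as_trace_matrix(traces)
  if (is.null(frames)) {
    active <- which(edges_per_frame(g) > 0L)
    frames <- if (length(active)) active else 1L
  }
  values <- if (substrate == "deviation") {
    m - vapply(seq_len(ncol(m)), function(i) {
      as.numeric(compute_baseline(m[, i], ema_forward(m[, i], k)))
    }, numeric(nrow(m)))
  } else m
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lab_vec <- as.vector(labels)
  base_df <- tibble::tibble(
    row = rep(seq_len(nrow(labels)), times = ncol(labels)),
    col = rep(seq_len(ncol(labels)), each = nrow(labels)))
  paths <- character(0)
  for (t in frames) {
    fill <- c(NA_real_, values[t, ])[lab_vec + 1L]
    df <- dplyr::mutate(base_df, value = fill)
    act <- dplyr::filter(g$edges, .data$first_frame <= t,
                         .data$last_frame >= t) |>
      dplyr::left_join(centers, by = c(source = "cell_id")) |>
      dplyr::rename(x0 = "col", y0 = "row") |>
      dplyr::left_join(centers, by = c(target = "cell_id")) |>
      dplyr::rename(x1 = "col", y1 = "row")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                          fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::scale_y_reverse() +
      ggplot2::coord_fixed() +
      ggplot2::scale_fill_viridis_c(na.value = "black") +
      ggplot2::labs(title = paste("frame", t), fill = "deviation") +
      ggplot2::theme_void()
    if (nrow(act)) {
      p <- p + ggplot2::geom_segment(
        data = act, inherit.aes = FALSE, colour = "white",
        arrow = ggplot2::arrow(length = ggplot2::unit(0.1, "inches")),
        ggplot2::aes(x = .data$x0, y = .data$y0,
                     xend = .data$x1, yend = .data$y1))
    }
    f <- file.path(out_dir, sprintf("frame_%06d.png", t))
    ggplot2::ggsave(f, p, width = width / 96, height = height / 96,
                    dpi = 96)
    paths <- c(paths, f)
  }
  invisible(paths)
}

#' Calibration error curve
#'
#' @param object An `ema_calibration` from [calibrate_k()].
#' @param ... Unused.
#' @return A ggplot of markup error against the EMA coefficient, with the
#'   minimising coefficient marked.
#' @export
autoplot.ema_calibration <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$k, .data$error)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_best, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "EMA coefficient k", y = "markup error (frames)") +
    ggplot2::theme_minimal()
}
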