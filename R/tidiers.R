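# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a dynamic graph into its edge table
#'
#' @param x A `dynamic_graph`.
#' @param ... Unused.
#' @return The edge tibble (`source`, `target`, `first_frame`,
#'   `last_frame`, `source_event`, `target_event`).
#' @export
tidy.dynamic_graph <- function(x, ...) x$edges

#' One-row summary of a dynamic graph
#'
#' @inheritParams tidy.dynamic_graph
#' @return The [graph_metrics()] row plus `n_cells` and `n_frames`.
#' @export
glance.dynamic_graph <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(n_cells = x$n_cells,
                                  n_frames = x$n_frames),
                   graph_metrics(x))
}

#' Tidy a compressed transmission graph into its edge table
#'
#' @param x A `compressed_graph`.
#' @param ... Unused.
#' @return Tibble with `source`, `target`, `count`, `balance`.
#' @export
tidy.compressed_graph <- function(x, ...) x$edges

#' One-row summary of a compressed transmission graph
#'
#' @inheritParams tidy.compressed_graph
#' @return Tibble with `n_cells`, `n_edges` (directed pairs),
#'   `n_transmissions` (NEC), `max_count`.
#' @export
glance.compressed_graph <- function(x, ...) {
  tibble::tibble(n_cells = x$n_cells, n_edges = nrow(x$edges),
                 n_transmissions = compressed_edge_count(x),
                 max_count = if (nrow(x$edges)) max(x$edges$count) else 0L)
}

#' Tidy an EMA calibration into its error curve
#'
#' @param x An `ema_calibration` from [calibrate_k()].
#' @param ... Unused.
#' @return Tibble with `k` and `error`.
#' @export
tidy.ema_calibration <- function(x, ...) x$curve

#' One-row summary of an EMA calibration
#'
#' @inheritParams tidy.ema_calibration
#' @return Tibble with `k_best`, `error_best`, `n_grid`.
#' @export
glance.ema_calibration <- function(x, ...) {
  tibble::tibble(k_best = x$k_best, error_best = x$error_best,
                 n_grid = nrow(x$curve))
}
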