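# Dynamic-graph metrics, time compression into the weighted transmission
# graph, and centralities.

#' Total edge count of a dynamic graph over all frames
#'
#' Counts every edge on every frame it is present, i.e. the sum over edges of
#' their overlap-interval lengths (frames are inclusive on both ends).
#'
#' @param g A `dynamic_graph`.
#' @return Non-negative integer.
#' @export
dynamic_edge_count <- function(g) {
  stopifnot(inherits(g, "dynamic_graph"))
  if (!nrow(g$edges)) return(0L)
  as.integer(sum(g$edges$last_frame - g$edges$first_frame + 1L))
}

#' Active cells of a dynamic graph
#'
#' A cell is active when it sent a transmission to a neighbour at least once,
#' received one, or shared a simultaneous significant event with a neighbour
#' (direction undecidable).
#'
#' @param g A `dynamic_graph`.
#' @param n Total number of cells; defaults to the graph's cell count.
#' @return A one-row tibble with `count` and `percent` (of `n`).
#' @export
active_cells <- function(g, n = g$n_cells) {
  stopifnot(inherits(g, "dynamic_graph"), n >= 1)
  cnt <- length(g$active_cells)
  tibble::tibble(count = cnt, percent = 100 * cnt / n)
}

# Per-frame number of simultaneously present edges, as an integer vector.
edges_per_frame <- function(g) {
  stopifnot(inherits(g, "dynamic_graph"))
  T <- g$n_frames
  if (T < 1L || !nrow(g$edges)) return(integer(T))
  delta <- integer(T + 1L)
  firsts <- g$edges$first_frame
  lasts <- g$edges$last_frame
  for (r in seq_along(firsts)) {
    delta[firsts[r]] <- delta[firsts[r]] + 1L
    delta[lasts[r] + 1L] <- delta[lasts[r] + 1L] - 1L
  }
  cumsum(delta[seq_len(T)])
}

#' Maximum number of transmissions on a single frame
#'
#' @inheritParams dynamic_edge_count
#' @return Non-negative integer: `max_t |E_t|`.
#' @export
max_transmissions_per_frame <- function(g) {
  ept <- edges_per_frame(g)
  if (!length(ept)) 0L else max(ept)
}

#' Mean number of periodic connections per cell
#'
#' Links that appear only once in the whole recording are discarded: only
#' ordered cell pairs with at least two distinct transmissions qualify. In
#' the default `"links"` mode every qualifying ordered pair contributes one
#' to the out-degree of its source and one to the in-degree of its target;
#' `"repetitions"` counts each repeated transmission instead. The summed
#' degrees are averaged over all `n` cells.
#'
#' @inheritParams active_cells
#' @param count_mode `"links"` (default) or `"repetitions"`.
#' @return A single non-negative number.
#' @export
mean_periodic_connections <- function(g, n = g$n_cells,
                                      count_mode = c("links", "repetitions")) {
  count_mode <- match.arg(count_mode)
  cg <- compress_graph(g)
  keep <- cg$counts >= 2L
  if (!any(keep)) return(0)
  contrib <- if (count_mode == "links") (cg$counts >= 2L) * 1 else
    cg$counts * (cg$counts >= 2L)
  sum(rowSums(contrib) + colSums(contrib)) / n
}

#' Compress a dynamic graph into the weighted transmission graph
#'
#' A transmission that persists over several consecutive frames is counted
#' once; transmissions in the two directions of a pair are counted
#' separately. Formally, for each ordered pair (i, j) the count `c_ij` is the
#' number of onsets of the edge i->j over time — frames where the edge is
#' present but was absent on the previous frame — computed on the union of
#' the pair's edge intervals. The arc-label matrix `b = c - t(c)` records the
#' net directional balance and drives the line-contrast rendering; the edge
#' set contains every ordered pair with `c_ij > 0`.
#'
#' @param g A `dynamic_graph`.
#' @return An object of class `compressed_graph`: list with `counts`
#'   (n x n integer matrix `c`), `b` (antisymmetric matrix `c - t(c)`),
#'   `edges` (tibble: `source`, `target`, `count`, `balance`), `n_cells`.
#' @export
compress_graph <- function(g) {
  stopifnot(inherits(g, "dynamic_graph"))
  n <- g$n_cells
  counts <- matrix(0L, n, n)
  e <- g$edges
  if (nrow(e)) {
    grp <- dplyr::group_by(e, .data$source, .data$target)
    tallies <- dplyr::summarise(
      grp,
      count = count_onsets(.data$first_frame, .data$last_frame),
      .groups = "drop")
    counts[cbind(tallies$source, tallies$target)] <- tallies$count
  }
  b <- counts - t(counts)
  idx <- which(counts > 0L, arr.ind = TRUE)
  edges <- tibble::tibble(
    source = as.integer(idx[, 1L]), target = as.integer(idx[, 2L]),
    count = counts[idx], balance = b[idx]) |>
    dplyr::arrange(.data$source, .data$target)
  structure(list(counts = counts, b = b, edges = edges, n_cells = n),
            class = "compressed_graph")
}

# Onset count of a set of frame intervals: number of maximal covered runs
# after union (present at t, absent at t - 1).
count_onsets <- function(first, last) {
  o <- order(first, last)
  first <- first[o]; last <- last[o]
  onsets <- 1L
  reach <- last[1L]
  for (r in seq_along(first)[-1L]) {
    if (first[r] > reach + 1L) onsets <- onsets + 1L
    reach <- max(reach, last[r])
  }
  onsets
}

#' @export
print.compressed_graph <- function(x, ...) {
  cat("Compressed transmission graph:", x$n_cells, "cells,",
      nrow(x$edges), "directed edges,",
      compressed_edge_count(x), "transmissions\n")
  invisible(x)
}

#' Total number of transmissions in a compressed graph
#'
#' Each transmission is counted once regardless of how many frames it
#' spanned. Low values flag cultures whose cells are dying or decoupled.
#'
#' @param cg A `compressed_graph`.
#' @return Non-negative integer `NEC`.
#' @export
compressed_edge_count <- function(cg) {
  stopifnot(inherits(cg, "compressed_graph"))
  as.integer(sum(cg$counts))
}

#' Per-cell transmission degrees of the compressed graph
#'
#' Out-degree is the number of transmissions a cell sent, in-degree the
#' number it received; both sum over repeated transmissions to the same
#' neighbour. Their grand totals each equal [compressed_edge_count()].
#'
#' @inheritParams compressed_edge_count
#' @return A tibble with columns `cell_id`, `outdegree`, `indegree`.
#' @export
degree_centrality <- function(cg) {
  stopifnot(inherits(cg, "compressed_graph"))
  tibble::tibble(cell_id = seq_len(cg$n_cells),
                 outdegree = as.integer(rowSums(cg$counts)),
                 indegree = as.integer(colSums(cg$counts)))
}

#' HITS hub and authority scores on the transmission graph
#'
#' Mutually recursive centralities on the transmission-count-weighted
#' directed graph: a cell's authority is the normalised sum of the hub
#' scores of the cells transmitting to it, and its hub score the normalised
#' sum of the authorities it transmits to. Computed by power iteration with
#' L2 normalisation; convergence when the largest per-cell change of both
#' score vectors falls below `tol`.
#'
#' @inheritParams compressed_edge_count
#' @param tol Convergence tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 1000).
#' @return A tibble with columns `cell_id`, `hub`, `authority`; both score
#'   vectors are unit-L2-norm and non-negative. With no edges all scores are
#'   zero (with a warning).
#' @export
hits_centrality <- function(cg, tol = 1e-8, max_iter = 1000) {
  stopifnot(inherits(cg, "compressed_graph"))
  n <- cg$n_cells
  C <- cg$counts
  if (all(C == 0L)) {
    warning("compressed graph has no edges; all HITS scores are zero.")
    return(tibble::tibble(cell_id = seq_len(n), hub = rep(0, n),
                          authority = rep(0, n)))
  }
  l2 <- function(v) { nv <- sqrt(sum(v^2)); if (nv > 0) v / nv else v }
  hub <- l2(rep(1, n))
  auth <- rep(0, n)
  for (it in seq_len(max_iter)) {
    auth_new <- l2(as.numeric(crossprod(C, hub)))   # t(C) %*% hub
    hub_new <- l2(as.numeric(C %*% auth_new))
    delta <- max(abs(auth_new - auth), abs(hub_new - hub))
    auth <- auth_new; hub <- hub_new
    if (delta < tol) break
  }
  tibble::tibble(cell_id = seq_len(n), hub = hub, authority = auth)
}

#' Summary metrics of a dynamic graph and its compression
#'
#' @inheritParams active_cells
#' @return A one-row tibble: `dynamic_edge_count`, `n_active`, `pct_active`,
#'   `max_transmissions_per_frame`, `mean_periodic_connections`,
#'   `compressed_edge_count`.
#' @export
graph_metrics <- function(g, n = g$n_cells) {
  act <- active_cells(g, n)
  tibble::tibble(
    dynamic_edge_count = dynamic_edge_count(g),
    n_active = act$count,
    pct_active = act$percent,
    max_transmissions_per_frame = max_transmissions_per_frame(g),
    mean_periodic_connections = mean_periodic_connections(g, n),
    compressed_edge_count = compressed_edge_count(compress_graph(g))
  )
}
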