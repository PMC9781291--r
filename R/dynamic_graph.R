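# Frame-resolved directed graph of calcium-signal propagation, built from
# staggered event overlap between spatially adjacent cells.

#' Classify the temporal overlap of two calcium events
#'
#' The staggered-overlap rule that sets edge direction: the event that starts
#' strictly earlier, overlaps the other, and finishes no later is the sender.
#' With events `a = [start_a, finish_a]` and `b = [start_b, finish_b]`:
#' `"forward"` (a sends to b) iff
#' `start_a < start_b <= finish_a <= finish_b`; `"backward"` is the mirror
#' image; `"simultaneous"` when the starts coincide and the intervals
#' intersect (no direction can be assigned); `"none"` for disjoint intervals
#' and for nested events (one interval strictly inside the other), where the
#' stagger needed to read a direction is absent.
#'
#' @param a,b Events: numeric `c(start, finish)` or one-row data frames with
#'   `start` and `finish` columns.
#' @return One of `"forward"`, `"backward"`, `"simultaneous"`, `"none"`.
#' @examples
#' classify_overlap(c(10, 20), c(15, 25))  # "forward"
#' classify_overlap(c(10, 20), c(30, 40))  # "none"
#' classify_overlap(c(10, 20), c(10, 18))  # "simultaneous"
#' @export
classify_overlap <- function(a, b) {
  a <- as_event_interval(a)
  b <- as_event_interval(b)
  classify_overlap_vec(a[1L], a[2L], b[1L], b[2L])
}

as_event_interval <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L, all(c("start", "finish") %in% names(x)))
    x <- c(x$start, x$finish)
  }
  stopifnot(is.numeric(x), length(x) == 2L, x[1L] <= x[2L])
  as.numeric(x)
}

# Vectorised core used by the graph builder.
classify_overlap_vec <- function(sa, fa, sb, fb) {
  out <- rep("none", length(sa))
  intersects <- sa <= fb & sb <= fa
  out[intersects & sa == sb] <- "simultaneous"
  out[intersects & sa < sb & fa <= fb] <- "forward"
  out[intersects & sb < sa & fb <= fa] <- "backward"
  out
}

#' Build the dynamic propagation graph from detected events
#'
#' For every pair of adjacent cells (`adjacency[i, j] == 1`) and every pair
#' of their significant events with a staggered overlap, a directed edge is
#' emitted from the earlier-starting cell, spanning the whole overlap
#' interval `[max(starts), min(finishes)]`. Simultaneous event pairs carry no
#' direction but mark both cells active. Nested event pairs emit nothing and
#' are reported in the `nested` diagnostic table so they can be audited.
#' Only adjacent pairs are ever compared: the method deliberately restricts
#' itself to short-range (contact-mediated) propagation.
#'
#' @param events Event table with columns `cell_id`, `start`, `finish`
#'   (the output of [detect_events()]); rows with `significant == FALSE`,
#'   if present, are dropped.
#' @param adjacency Symmetric binary n x n matrix from
#'   [compute_adjacency()].
#' @param n_frames Total frame count; defaults to the largest event finish.
#' @return An object of class `dynamic_graph`: list with `edges` (tibble:
#'   `source`, `target`, `first_frame`, `last_frame`, `source_event`,
#'   `target_event`), `simultaneous` (tibble of undirected co-activations),
#'   `nested` (diagnostics), `active_cells`, `n_cells`, `n_frames`. Edge
#'   ordering is deterministic (source, target, first frame).
#' @export
build_dynamic_graph <- function(events, adjacency, n_frames = NULL) {
  events <- tibble::as_tibble(events)
  stopifnot(all(c("cell_id", "start", "finish") %in% names(events)))
  if ("significant" %in% names(events)) {
    events <- dplyr::filter(events, .data$significant)
  }
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency)) {
    stop("`adjacency` must be a square matrix.", call. = FALSE)
  }
  n <- nrow(adjacency)
  if (nrow(events) && any(events$cell_id < 1L | events$cell_id > n)) {
    bad <- unique(events$cell_id[events$cell_id < 1L | events$cell_id > n])
    stop("event cell id(s) outside the adjacency dimension (n = ", n, "): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(n_frames)) {
    n_frames <- if (nrow(events)) max(events$finish) else 0L
  }
  # Event id = rank of the event within its cell, in start order.
  events <- events |>
    dplyr::arrange(.data$cell_id, .data$start) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::mutate(event_id = dplyr::row_number()) |>
    dplyr::ungroup()
  by_cell <- split(events, events$cell_id)

  pairs <- which(upper.tri(adjacency) & adjacency == 1, arr.ind = TRUE)
  dimnames(pairs) <- NULL
  edges <- list(); simult <- list(); nested <- list()
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    ei <- by_cell[[as.character(i)]]; ej <- by_cell[[as.character(j)]]
    if (is.null(ei) || is.null(ej) || !nrow(ei) || !nrow(ej)) next
    g <- tidyr::expand_grid(ai = seq_len(nrow(ei)), bj = seq_len(nrow(ej)))
    sa <- ei$start[g$ai]; fa <- ei$finish[g$ai]
    sb <- ej$start[g$bj]; fb <- ej$finish[g$bj]
    rel <- classify_overlap_vec(sa, fa, sb, fb)
    fw <- rel == "forward"; bw <- rel == "backward"; sm <- rel == "simultaneous"
    if (any(fw)) edges[[length(edges) + 1L]] <- tibble::tibble(
      source = i, target = j,
      first_frame = sb[fw], last_frame = fa[fw],
      source_event = ei$event_id[g$ai[fw]],
      target_event = ej$event_id[g$bj[fw]])
    if (any(bw)) edges[[length(edges) + 1L]] <- tibble::tibble(
      source = j, target = i,
      first_frame = sa[bw], last_frame = fb[bw],
      source_event = ej$event_id[g$bj[bw]],
      target_event = ei$event_id[g$ai[bw]])
    if (any(sm)) simult[[length(simult) + 1L]] <- tibble::tibble(
      cell_a = i, cell_b = j,
      event_a = ei$event_id[g$ai[sm]], event_b = ej$event_id[g$bj[sm]])
    nst <- rel == "none" & sa <= fb & sb <= fa  # intersecting but nested
    if (any(nst)) nested[[length(nested) + 1L]] <- tibble::tibble(
      cell_a = i, cell_b = j,
      event_a = ei$event_id[g$ai[nst]], event_b = ej$event_id[g$bj[nst]])
  }
  edges <- if (length(edges)) dplyr::bind_rows(edges) else empty_edge_table()
  edges <- dplyr::arrange(edges, .data$source, .data$target,
                          .data$first_frame, .data$target_event)
  simult <- if (length(simult)) dplyr::bind_rows(simult) else
    tibble::tibble(cell_a = integer(), cell_b = integer(),
                   event_a = integer(), event_b = integer())
  nested <- if (length(nested)) dplyr::bind_rows(nested) else
    tibble::tibble(cell_a = integer(), cell_b = integer(),
                   event_a = integer(), event_b = integer())
  structure(
    list(edges = edges, simultaneous = simult, nested = nested,
         active_cells = sort(unique(c(edges$source, edges$target,
                                      simult$cell_a, simult$cell_b))),
         n_cells = n, n_frames = as.integer(n_frames)),
    class = "dynamic_graph"
  )
}

empty_edge_table <- function() {
  tibble::tibble(source = integer(), target = integer(),
                 first_frame = integer(), last_frame = integer(),
                 source_event = integer(), target_event = integer())
}

#' @export
print.dynamic_graph <- function(x, ...) {
  cat("Dynamic propagation graph:", x$n_cells, "cells,", x$n_frames,
      "frames\n")
  cat("  directed edges:", nrow(x$edges),
      " simultaneous pairs:", nrow(x$simultaneous),
      " nested pairs (no edge):", nrow(x$nested), "\n")
  cat("  active cells:", length(x$active_cells), "\n")
  invisible(x)
}

#' Dense frame-by-frame representation of a dynamic graph
#'
#' Expands the sparse interval edge list into the n x n x T logical array
#' whose slice at frame t is the directed adjacency matrix of the graph on
#' that frame. Intended for export and as a cross-checking representation;
#' the edge list is the primary storage.
#'
#' @param g A `dynamic_graph`.
#' @param budget Maximum number of array elements permitted (memory guard).
#' @return Logical array of dimension `c(n, n, n_frames)`.
#' @export
to_dense <- function(g, budget = 1e8) {
  stopifnot(inherits(g, "dynamic_graph"))
  n <- g$n_cells; T <- g$n_frames
  if (as.double(n) * n * T > budget) {
    stop("dense array of ", n, " x ", n, " x ", T,
         " elements exceeds the budget (", format(budget),
         "); use the edge-list export instead.", call. = FALSE)
  }
  arr <- array(FALSE, dim = c(n, n, max(T, 0L)))
  e <- g$edges
  for (r in seq_len(nrow(e))) {
    arr[e$source[r], e$target[r], e$first_frame[r]:e$last_frame[r]] <- TRUE
  }
  arr
}

#' Recover an interval edge list from a dense dynamic-graph array
#'
#' Inverse of [to_dense()] up to event identities: each maximal run of
#' consecutive frames on which a directed pair is present becomes one edge
#' interval. `to_dense(dense_to_edges(a))` reproduces `a` exactly.
#'
#' @param arr Logical n x n x T array.
#' @return A `dynamic_graph` whose edges carry `NA` event ids.
#' @export
dense_to_edges <- function(arr) {
  stopifnot(is.array(arr), length(dim(arr)) == 3L,
            dim(arr)[1L] == dim(arr)[2L])
  n <- dim(arr)[1L]; T <- dim(arr)[3L]
  edges <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    runs <- runs_of(as.logical(arr[i, j, ]))
    if (nrow(runs)) edges[[length(edges) + 1L]] <- tibble::tibble(
      source = i, target = j, first_frame = runs$first,
      last_frame = runs$last, source_event = NA_integer_,
      target_event = NA_integer_)
  }
  edges <- if (length(edges)) dplyr::bind_rows(edges) else empty_edge_table()
  edges <- dplyr::arrange(edges, .data$source, .data$target,
                          .data$first_frame)
  structure(
    list(edges = edges,
         simultaneous = tibble::tibble(cell_a = integer(),
                                       cell_b = integer(),
                                       event_a = integer(),
                                       event_b = integer()),
         nested = tibble::tibble(cell_a = integer(), cell_b = integer(),
                                 event_a = integer(), event_b = integer()),
         active_cells = sort(unique(c(edges$source, edges$target))),
         n_cells = n, n_frames = T),
    class = "dynamic_graph"
  )
}
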