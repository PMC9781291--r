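# Readers and writers: trace tables (CSV/TSV), TIFF label images and
# stacks, event and markup tables, metrics JSON, compressed-graph GraphML
# and edge lists. All frame indices in files are 1-based inclusive.

delim_for <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read and write per-cell trace tables
#'
#' Frames in rows, one column per cell, header row of cell ids. A `.tsv`
#' extension selects tab separation, anything else comma. Lines starting
#' with `#` are comments; the writer records the frame-index convention in
#' one.
#'
#' @param path File path.
#' @param traces Frames x cells data frame.
#' @param frame_rate Optional frame rate recorded in the header comment.
#' @return `read_traces()`: a tibble; `write_traces()`: `path`, invisibly.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  out <- readr::read_delim(path, delim = delim_for(path), comment = "#",
                           show_col_types = FALSE, progress = FALSE)
  if (!nrow(out) || !ncol(out)) {
    stop("malformed trace table (no data rows/columns): ", path,
         call. = FALSE)
  }
  bad <- names(out)[!purrr::map_lgl(out, is.numeric)]
  if (length(bad)) {
    stop("malformed trace table ", path, ": non-numeric column(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

#' @rdname read_traces
#' @export
write_traces <- function(traces, path, frame_rate = NULL) {
  traces <- tibble::as_tibble(as_trace_matrix(traces), .name_repair = "minimal")
  hdr <- "# per-cell intensity traces; rows = frames (1-based), columns = cells"
  if (!is.null(frame_rate)) hdr <- c(hdr, paste0("# frame_rate_hz: ",
                                                 frame_rate))
  writeLines(hdr, path)
  readr::write_delim(traces, path, delim = delim_for(path), append = TRUE,
                     col_names = TRUE)
  invisible(path)
}

#' Read and write label images and intensity stacks as TIFF
#'
#' Label images are stored as 16-bit grayscale (region ids up to 65535);
#' stacks as multi-page 32-bit float TIFF, one page per frame.
#'
#' @param path File path.
#' @param labels Integer H x W label matrix.
#' @param video 3-D array, frames x height x width.
#' @return Readers return the matrix/array; writers return `path`,
#'   invisibly.
#' @export
read_labels_tiff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (is.list(img)) img <- img[[1L]]
  labels <- matrix(as.integer(round(img)), nrow(img), ncol(img))
  check_label_image(labels)
  labels
}

#' @rdname read_labels_tiff
#' @export
write_labels_tiff <- function(labels, path) {
  check_label_image(labels)
  if (max(labels) > 65535L) {
    stop("more than 65535 regions cannot be stored as 16-bit TIFF.",
         call. = FALSE)
  }
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname read_labels_tiff
#' @export
read_stack_tiff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  H <- nrow(pages[[1L]]); W <- ncol(pages[[1L]])
  stack <- array(0, dim = c(length(pages), H, W))
  for (t in seq_along(pages)) stack[t, , ] <- pages[[t]]
  stack
}

#' @rdname read_labels_tiff
#' @export
write_stack_tiff <- function(video, path) {
  stopifnot(is.array(video), length(dim(video)) == 3L)
  pages <- lapply(seq_len(dim(video)[1L]), function(t) video[t, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read and write event and markup tables
#'
#' Event tables carry `cell_id`, `start`, `peak`, `finish`, `amplitude`,
#' `significant` (0/1 in the file); markup tables `cell_id`, `start`,
#' `finish`. Frames are 1-based inclusive.
#'
#' @param events Event tibble from [detect_events()].
#' @param markup Markup data frame.
#' @param path File path.
#' @return Readers return tibbles; writers return `path`, invisibly.
#' @export
read_events <- function(path) {
  out <- read_table_checked(path, c("cell_id", "start", "peak", "finish",
                                    "amplitude", "significant"))
  out$significant <- as.logical(out$significant)
  out
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  events <- tibble::as_tibble(events)
  out <- dplyr::mutate(
    events[, c("cell_id", "start", "peak", "finish", "amplitude",
               "significant")],
    significant = as.integer(.data$significant))
  writeLines("# calcium events; frames 1-based inclusive", path)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname read_events
#' @export
read_markup <- function(path) {
  read_table_checked(path, c("cell_id", "start", "finish"))
}

#' @rdname read_events
#' @export
write_markup <- function(markup, path) {
  markup <- tibble::as_tibble(markup)
  writeLines("# manual event markup; frames 1-based inclusive", path)
  readr::write_csv(markup[, c("cell_id", "start", "finish")], path,
                   append = TRUE, col_names = TRUE)
  invisible(path)
}

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  missing <- setdiff(required, names(out))
  if (length(missing)) {
    stop("malformed table ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out
}

#' Read and write dynamic-graph edge lists
#'
#' Columns `source`, `target`, `first_frame`, `last_frame`, `source_event`,
#' `target_event`; frames 1-based inclusive.
#'
#' @param g A `dynamic_graph`.
#' @param path File path.
#' @param n_cells,n_frames Graph dimensions to restore on reading (the edge
#'   list alone does not determine them).
#' @return `read_dynamic_edges()`: a `dynamic_graph` (without
#'   simultaneous-pair records); `write_dynamic_edges()`: `path`, invisibly.
#' @export
write_dynamic_edges <- function(g, path) {
  stopifnot(inherits(g, "dynamic_graph"))
  writeLines(c("# dynamic propagation edges; frames 1-based inclusive",
               paste0("# n_cells: ", g$n_cells),
               paste0("# n_frames: ", g$n_frames)), path)
  readr::write_csv(g$edges, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_dynamic_edges
#' @export
read_dynamic_edges <- function(path, n_cells = NULL, n_frames = NULL) {
  hdr <- readLines(path, n = 10L)
  get_hdr <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(ln)) as.integer(sub(paste0("^# ", key, ": "), "", ln[1L]))
    else NULL
  }
  n_cells <- n_cells %||% get_hdr("n_cells")
  n_frames <- n_frames %||% get_hdr("n_frames")
  e <- read_table_checked(path, c("source", "target", "first_frame",
                                  "last_frame"))
  if (is.null(n_cells)) n_cells <- max(c(e$source, e$target, 0L))
  if (is.null(n_frames)) n_frames <- max(c(e$last_frame, 0L))
  if (!all(c("source_event", "target_event") %in% names(e))) {
    e$source_event <- NA_integer_; e$target_event <- NA_integer_
  }
  structure(
    list(edges = tibble::as_tibble(e),
         simultaneous = tibble::tibble(cell_a = integer(),
                                       cell_b = integer(),
                                       event_a = integer(),
                                       event_b = integer()),
         nested = tibble::tibble(cell_a = integer(), cell_b = integer(),
                                 event_a = integer(), event_b = integer()),
         active_cells = sort(unique(c(e$source, e$target))),
         n_cells = as.integer(n_cells), n_frames = as.integer(n_frames)),
    class = "dynamic_graph")
}

#' Export and import the compressed transmission graph
#'
#' GraphML carries one vertex per cell (`name` = cell id) and one edge per
#' ordered pair with positive transmission count, with `count` and
#' `balance` edge attributes. The CSV edge list carries the same columns as
#' `cg$edges`.
#'
#' @param cg A `compressed_graph`.
#' @param path File path.
#' @param n_cells Cell count on import (GraphML keeps it; CSV needs it when
#'   isolated trailing cells exist).
#' @return Readers return a `compressed_graph`; writers return `path`,
#'   invisibly.
#' @export
write_compressed_graphml <- function(cg, path) {
  stopifnot(inherits(cg, "compressed_graph"))
  ig <- igraph::graph_from_data_frame(
    dplyr::mutate(cg$edges, source = as.character(.data$source),
                  target = as.character(.data$target)),
    directed = TRUE,
    vertices = data.frame(name = as.character(seq_len(cg$n_cells))))
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' @rdname write_compressed_graphml
#' @export
read_compressed_graphml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ig <- igraph::read_graph(path, format = "graphml")
  n <- igraph::vcount(ig)
  ids <- as.integer(igraph::vertex_attr(ig, "name"))
  el <- igraph::as_edgelist(ig, names = FALSE)
  counts <- matrix(0L, n, n)
  if (nrow(el)) {
    counts[cbind(ids[el[, 1L]], ids[el[, 2L]])] <-
      as.integer(round(igraph::edge_attr(ig, "count")))
  }
  compressed_from_counts(counts)
}

#' @rdname write_compressed_graphml
#' @export
write_compressed_csv <- function(cg, path) {
  stopifnot(inherits(cg, "compressed_graph"))
  writeLines(c("# compressed transmission graph edges",
               paste0("# n_cells: ", cg$n_cells)), path)
  readr::write_csv(cg$edges, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_compressed_graphml
#' @export
read_compressed_csv <- function(path, n_cells = NULL) {
  hdr <- readLines(path, n = 5L)
  ln <- grep("^# n_cells: ", hdr, value = TRUE)
  if (is.null(n_cells) && length(ln)) {
    n_cells <- as.integer(sub("^# n_cells: ", "", ln[1L]))
  }
  e <- read_table_checked(path, c("source", "target", "count"))
  if (is.null(n_cells)) n_cells <- max(c(e$source, e$target, 0L))
  counts <- matrix(0L, n_cells, n_cells)
  if (nrow(e)) counts[cbind(e$source, e$target)] <- as.integer(e$count)
  compressed_from_counts(counts)
}

# Rebuild a compressed_graph object from its count matrix.
compressed_from_counts <- function(counts) {
  n <- nrow(counts)
  b <- counts - t(counts)
  idx <- which(counts > 0L, arr.ind = TRUE)
  edges <- tibble::tibble(
    source = as.integer(idx[, 1L]), target = as.integer(idx[, 2L]),
    count = counts[idx], balance = b[idx]) |>
    dplyr::arrange(.data$source, .data$target)
  structure(list(counts = counts, b = b, edges = edges, n_cells = n),
            class = "compressed_graph")
}

#' Write and read a metrics report as JSON
#'
#' @param metrics One-row data frame from [graph_metrics()] (any one-row
#'   data frame of scalars works).
#' @param path File path.
#' @return `read_metrics_json()`: a one-row tibble; the writer returns
#'   `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  stopifnot(is.data.frame(metrics), nrow(metrics) == 1L)
  jsonlite::write_json(as.list(metrics), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_metrics_json
#' @export
read_metrics_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}
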