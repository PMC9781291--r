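# Labelled-image operations: per-region traces, region adjacency, centers.
# A label image is an H x W integer matrix; region ids 1..n, 0 = background.

check_label_image <- function(labels) {
  if (!is.matrix(labels) || !is.numeric(labels)) {
    stop("`labels` must be an integer H x W matrix.", call. = FALSE)
  }
  if (anyNA(labels) || any(labels < 0) || any(labels != round(labels))) {
    stop("`labels` must contain non-negative integers (0 = background).",
         call. = FALSE)
  }
  n <- max(labels)
  if (n < 1L) stop("`labels` contains no region (all background).",
                   call. = FALSE)
  present <- sort(unique(labels[labels > 0]))
  missing <- setdiff(seq_len(n), present)
  if (length(missing)) {
    stop("empty region id(s) in `labels`: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  as.integer(n)
}

#' Mean-intensity traces of labelled regions
#'
#' Each cell's calcium signal is the arithmetic mean of the video intensity
#' over the pixels of its region, frame by frame.
#'
#' @param video 3-D numeric array, frames x height x width.
#' @param labels Integer H x W label matrix; ids 1..n, 0 = background
#'   (excluded).
#' @return A tibble with one row per frame and one column per region, named
#'   by region id.
#' @export
extract_traces <- function(video, labels) {
  if (!(is.array(video) && length(dim(video)) == 3L)) {
    stop("`video` must be a 3-D array (frames x height x width).",
         call. = FALSE)
  }
  n <- check_label_image(labels)
  dv <- dim(video)
  if (dv[2L] != nrow(labels) || dv[3L] != ncol(labels)) {
    stop(sprintf(
      "shape mismatch: video frames are %d x %d but labels are %d x %d",
      dv[2L], dv[3L], nrow(labels), ncol(labels)), call. = FALSE)
  }
  if (anyNA(video) || !all(is.finite(video))) {
    stop("`video` must be finite.", call. = FALSE)
  }
  lab_vec <- as.vector(labels)
  keep <- lab_vec > 0
  sizes <- tabulate(lab_vec[keep], nbins = n)
  tr <- matrix(0, dv[1L], n)
  for (t in seq_len(dv[1L])) {
    frame <- as.vector(video[t, , ])
    tr[t, ] <- rowsum(frame[keep], lab_vec[keep], reorder = TRUE) / sizes
  }
  colnames(tr) <- as.character(seq_len(n))
  tibble::as_tibble(tr)
}

#' Region adjacency from a label image
#'
#' Two regions are adjacent when some pixel of one touches some pixel of the
#' other under the chosen pixel connectivity. Under 8-connectivity (the
#' default) diagonal contact counts; 4-connectivity requires a shared edge.
#' The background never neighbours anything.
#'
#' @inheritParams extract_traces
#' @param connectivity 4 or 8.
#' @return Symmetric n x n binary matrix with zero diagonal.
#' @export
compute_adjacency <- function(labels, connectivity = 8) {
  n <- check_label_image(labels)
  if (!connectivity %in% c(4, 8)) {
    stop("`connectivity` must be 4 or 8, got ", connectivity, call. = FALSE)
  }
  H <- nrow(labels); W <- ncol(labels)
  a <- matrix(0L, n, n)
  link <- function(u, v) {
    keep <- u > 0 & v > 0 & u != v
    if (any(keep)) {
      idx <- cbind(u[keep], v[keep])
      a[idx] <<- 1L
      a[idx[, 2:1, drop = FALSE]] <<- 1L
    }
  }
  if (H > 1L) link(labels[-H, ], labels[-1L, ])            # vertical
  if (W > 1L) link(labels[, -W], labels[, -1L])            # horizontal
  if (connectivity == 8 && H > 1L && W > 1L) {
    link(labels[-H, -W], labels[-1L, -1L])                 # down-right
    link(labels[-H, -1L], labels[-1L, -W])                 # down-left
  }
  a
}

#' Region centers of a label image
#'
#' The center of a region is the arithmetic mean of its pixel coordinates
#' (1-based row and column indices).
#'
#' @inheritParams extract_traces
#' @return A tibble with columns `cell_id`, `row`, `col`.
#' @export
region_centers <- function(labels) {
  n <- check_label_image(labels)
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[idx]
  tibble::tibble(
    cell_id = seq_len(n),
    row = as.numeric(rowsum(idx[, 1L], lab) / tabulate(lab, n)),
    col = as.numeric(rowsum(idx[, 2L], lab) / tabulate(lab, n))
  )
}
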