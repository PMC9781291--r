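# Event detection on single traces: super-average peaks, sub-average minima
# baseline, forward/backward EMA crossings for boundaries.

# Maximal runs where `above` is TRUE; tibble of first/last frame per run.
runs_of <- function(above) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(first = starts[r$values], last = ends[r$values])
}

#' Locate event peaks above the moving average
#'
#' Partitions the trace into maximal runs of frames where the intensity lies
#' strictly above its forward exponential moving average; each run contributes
#' one peak, the frame of maximal intensity within the run (first frame on
#' ties).
#'
#' @param trace Numeric intensity vector.
#' @param ema Forward EMA of `trace`, same length (see [ema_forward()]).
#' @return A tibble with columns `peak` (frame index) and `peak_intensity`.
#' @export
find_event_peaks <- function(trace, ema) {
  stopifnot(length(trace) == length(ema))
  runs <- runs_of(trace > ema)
  if (nrow(runs) == 0L) {
    return(tibble::tibble(peak = integer(), peak_intensity = numeric()))
  }
  peak <- purrr::map2_int(runs$first, runs$last, function(a, b) {
    seg <- a:b
    seg[which.max(trace[seg])]
  })
  tibble::tibble(peak = peak, peak_intensity = trace[peak])
}

#' Piecewise-linear baseline through sub-average local minima
#'
#' Anchors are the per-run minima of the trace over maximal runs where the
#' intensity lies strictly below its forward EMA (first frame on ties); the
#' baseline interpolates linearly between consecutive anchors and continues
#' horizontally beyond the first and last anchor. A trace that never dips
#' below its EMA (e.g. a constant trace) degenerates to the trace itself.
#'
#' @inheritParams find_event_peaks
#' @return Numeric baseline vector, same length as `trace`, with an
#'   `anchors` attribute: a tibble of anchor `frame` and `intensity`.
#' @export
compute_baseline <- function(trace, ema) {
  stopifnot(length(trace) == length(ema))
  runs <- runs_of(trace < ema)
  if (nrow(runs) == 0L) {
    out <- as.numeric(trace)
    attr(out, "anchors") <- tibble::tibble(frame = integer(),
                                           intensity = numeric())
    return(out)
  }
  anchor <- purrr::map2_int(runs$first, runs$last, function(a, b) {
    seg <- a:b
    seg[which.min(trace[seg])]
  })
  if (length(anchor) == 1L) {
    out <- rep(trace[anchor], length(trace))
  } else {
    out <- stats::approx(anchor, trace[anchor], xout = seq_along(trace),
                         method = "linear", rule = 2)$y
  }
  attr(out, "anchors") <- tibble::tibble(frame = anchor,
                                         intensity = trace[anchor])
  out
}

# Event table for one numeric trace. Frames are 1-based inclusive.
detect_events_trace <- function(trace, k, threshold, keep_insignificant) {
  ef <- ema_forward(trace, k)
  eb <- ema_backward(trace, k)
  bl <- compute_baseline(trace, ef)
  runs <- runs_of(trace > ef)
  if (nrow(runs) == 0L) return(empty_event_table())
  n_ev <- nrow(runs)
  peak <- purrr::map2_int(runs$first, runs$last, function(a, b) {
    seg <- a:b
    seg[which.max(trace[seg])]
  })
  start <- runs$first
  below_b <- which(trace <= eb)
  finish <- purrr::map_int(peak, function(p) {
    hit <- below_b[below_b >= p]
    if (length(hit)) hit[1L] else length(trace)
  })
  # Keep events of one cell non-overlapping: a finish that reaches into the
  # next super-EMA run is clipped to just before that run's start.
  if (n_ev > 1L) {
    finish[-n_ev] <- pmin(finish[-n_ev], start[-1L] - 1L)
  }
  amplitude <- trace[peak] - bl[peak]
  out <- tibble::tibble(
    start = start, peak = peak, finish = finish,
    peak_intensity = trace[peak],
    amplitude = amplitude,
    significant = amplitude > threshold
  )
  if (!keep_insignificant) out <- dplyr::filter(out, .data$significant)
  out
}

empty_event_table <- function() {
  tibble::tibble(start = integer(), peak = integer(), finish = integer(),
                 peak_intensity = numeric(), amplitude = numeric(),
                 significant = logical())
}

#' Detect calcium events in per-cell intensity traces
#'
#' For every cell, an event candidate is a maximal run of frames where the
#' intensity lies strictly above its forward EMA. Its start is the first frame
#' of the run (the upward crossing), its finish the first frame at or after
#' the peak where the intensity falls to or below the backward EMA (the
#' downward crossing), clipped so that one cell's events never overlap. The
#' event amplitude is the peak intensity minus the interpolated baseline at
#' the peak; an event is significant when the amplitude strictly exceeds
#' `threshold`. Only significant events are returned unless
#' `keep_insignificant = TRUE`.
#'
#' Detection is invariant to adding a constant to a whole trace: the EMAs and
#' the baseline shift by the same constant, so boundaries and amplitudes are
#' unchanged.
#'
#' @param traces A data frame or matrix, frames in rows and one column per
#'   cell (column order defines cell ids 1..n), or a bare numeric vector for
#'   a single cell.
#' @param k EMA filtration coefficient in (0, 1); default 0.97.
#' @param threshold Non-negative significance threshold in intensity units,
#'   typically from [estimate_noise_threshold()].
#' @param keep_insignificant Keep sub-threshold events (flagged
#'   `significant = FALSE`)? Default drops them.
#' @return A tibble with columns `cell_id`, `start`, `peak`, `finish`,
#'   `peak_intensity`, `amplitude`, `significant`; frames 1-based inclusive.
#' @examples
#' tr <- c(rep(1, 20), 1 + 10 * exp(-abs(seq(-5, 14)) / 3), rep(1, 20))
#' detect_events(tr, k = 0.9, threshold = 1)
#' @export
detect_events <- function(traces, k = 0.97, threshold = 0,
                          keep_insignificant = FALSE) {
  check_ema_k(k)
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0) {
    stop("`threshold` must be a single non-negative number.", call. = FALSE)
  }
  m <- as_trace_matrix(traces)
  purrr::map_dfr(seq_len(ncol(m)), function(i) {
    ev <- detect_events_trace(m[, i], k, threshold, keep_insignificant)
    dplyr::bind_cols(tibble::tibble(cell_id = rep(i, nrow(ev))), ev)
  })
}

# Coerce the accepted trace containers to a frames x cells numeric matrix.
as_trace_matrix <- function(traces) {
  if (is.numeric(traces) && is.null(dim(traces))) {
    traces <- matrix(traces, ncol = 1L)
  }
  m <- as.matrix(traces)
  storage.mode(m) <- "double"
  if (nrow(m) < 1L || ncol(m) < 1L) {
    stop("`traces` must have at least one frame and one cell.", call. = FALSE)
  }
  if (anyNA(m) || !all(is.finite(m))) {
    stop("`traces` must be finite and free of NA values.", call. = FALSE)
  }
  m
}

#' Significance threshold from noise-only traces
#'
#' Pools the per-frame deviations of each noise trace from its interpolated
#' baseline across all cells of a non-signalling culture and returns
#' `multiplier` times their standard deviation. The conventional multiplier
#' of 3 makes the threshold "3 standard deviations of biological noise".
#'
#' @param noise_traces Data frame, matrix or vector of noise-only traces
#'   (frames x cells).
#' @inheritParams detect_events
#' @param multiplier Positive scale on the pooled noise SD; default 3.
#' @return A single non-negative number in intensity units.
#' @export
estimate_noise_threshold <- function(noise_traces, k = 0.97, multiplier = 3) {
  check_ema_k(k)
  m <- as_trace_matrix(noise_traces)
  devs <- purrr::map(seq_len(ncol(m)), function(i) {
    tr <- m[, i]
    tr - compute_baseline(tr, ema_forward(tr, k))
  })
  devs <- unlist(devs)
  s <- stats::sd(devs)
  if (is.na(s)) s <- 0  # single-frame traces carry no spread
  multiplier * s
}
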