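# Calibration of the EMA coefficient against manual event markup.

#' Discrepancy between manual and algorithmic event markup
#'
#' Matches the two event lists one-to-one in temporal order (an
#' order-preserving alignment minimising the total cost, found by dynamic
#' programming) and returns the summed boundary discrepancy
#' \eqn{\sum |start^m - start^a| + |finish^m - finish^a|} over matched pairs.
#' An event left unmatched on either side adds a penalty equal to its own
#' duration in frames (`finish - start + 1`), so that detectors producing too
#' many or too few events are penalised rather than silently truncated.
#'
#' When both tables carry a `cell_id` column the error is summed over cells.
#'
#' @param manual Data frame of human markup with columns `start`, `finish`
#'   (and optionally `cell_id`).
#' @param algorithmic Data frame of detected events, same columns (the output
#'   of [detect_events()] works directly).
#' @return A single non-negative number (frames).
#' @export
markup_error <- function(manual, algorithmic) {
  manual <- tibble::as_tibble(manual)
  algorithmic <- tibble::as_tibble(algorithmic)
  if (("cell_id" %in% names(manual)) && ("cell_id" %in% names(algorithmic))) {
    ids <- union(manual$cell_id, algorithmic$cell_id)
    return(sum(purrr::map_dbl(ids, function(i) {
      markup_error_one(dplyr::filter(manual, .data$cell_id == i),
                       dplyr::filter(algorithmic, .data$cell_id == i))
    })))
  }
  markup_error_one(manual, algorithmic)
}

markup_error_one <- function(manual, algorithmic) {
  stopifnot(all(c("start", "finish") %in% names(manual)),
            all(c("start", "finish") %in% names(algorithmic)))
  if (nrow(manual) && any(manual$finish < manual$start)) {
    stop("manual markup has finish < start", call. = FALSE)
  }
  m <- dplyr::arrange(manual, .data$start)
  a <- dplyr::arrange(algorithmic, .data$start)
  nm <- nrow(m); na <- nrow(a)
  pen_m <- if (nm) m$finish - m$start + 1 else numeric()
  pen_a <- if (na) a$finish - a$start + 1 else numeric()
  # D[i+1, j+1]: best cost aligning first i manual with first j algorithmic.
  D <- matrix(0, nm + 1L, na + 1L)
  if (nm) D[-1L, 1L] <- cumsum(pen_m)
  if (na) D[1L, -1L] <- cumsum(pen_a)
  if (nm && na) {
    for (i in seq_len(nm)) {
      for (j in seq_len(na)) {
        match_cost <- abs(m$start[i] - a$start[j]) +
          abs(m$finish[i] - a$finish[j])
        D[i + 1L, j + 1L] <- min(D[i, j] + match_cost,
                                 D[i, j + 1L] + pen_m[i],
                                 D[i + 1L, j] + pen_a[j])
      }
    }
  }
  D[nm + 1L, na + 1L]
}

#' Calibrate the EMA coefficient against manual markup
#'
#' Runs [detect_events()] at every coefficient of `k_grid` and scores each
#' result against the manual markup with [markup_error()]. The returned
#' object records the full error curve and the minimising coefficient
#' (smallest `k` on ties). For a well-posed markup the curve is U-shaped:
#' small `k` makes the moving average hug the signal and fragments events,
#' large `k` makes it too stiff and inflates boundaries.
#'
#' @param traces Trace container accepted by [detect_events()].
#' @param manual Manual markup data frame (`cell_id` optional, `start`,
#'   `finish`).
#' @param k_grid Numeric vector of candidate coefficients, all in (0, 1).
#' @inheritParams detect_events
#' @return An object of class `ema_calibration`: list with `k_best`,
#'   `error_best`, and `curve` (tibble of `k`, `error`). Supports
#'   [tidy()][generics::tidy], [glance()][generics::glance] and `autoplot()`.
#' @export
calibrate_k <- function(traces, manual, k_grid, threshold = 0) {
  if (length(k_grid) == 0L) stop("`k_grid` must be non-empty.", call. = FALSE)
  purrr::walk(k_grid, check_ema_k)
  k_grid <- sort(unique(as.numeric(k_grid)))
  err <- purrr::map_dbl(k_grid, function(k) {
    markup_error(manual, detect_events(traces, k = k, threshold = threshold))
  })
  best <- which.min(err)  # which.min takes the first (= smallest k) on ties
  structure(
    list(k_best = k_grid[best], error_best = err[best],
         curve = tibble::tibble(k = k_grid, error = err)),
    class = "ema_calibration"
  )
}

#' @export
print.ema_calibration <- function(x, ...) {
  cat("EMA calibration over", nrow(x$curve), "coefficients\n")
  cat("  best k:", format(x$k_best), " markup error:",
      format(x$error_best), "frames\n")
  invisible(x)
}
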