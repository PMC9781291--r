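# Shared fixtures built in code.

# Four regions as 2x2 blocks of a 10x10 field:
#   1 | 2
#   --+--
#   3 | 4
# Under 4-connectivity the adjacent pairs are 1-2, 1-3, 2-4, 3-4.
fig3_labels <- function() {
  labels <- matrix(0L, 10L, 10L)
  labels[1:5, 1:5] <- 1L
  labels[1:5, 6:10] <- 2L
  labels[6:10, 1:5] <- 3L
  labels[6:10, 6:10] <- 4L
  labels
}

# Staggered events reproducing the four-region worked example: cell 1 leads
# cells 2 and 3, cell 4 lags cell 3, and cell 4's event is nested inside
# cell 2's. Expected directed edges: 1->2, 1->3, 3->4.
fig3_events <- function() {
  tibble::tibble(
    cell_id = c(1L, 2L, 3L, 4L),
    start = c(10L, 12L, 12L, 16L),
    finish = c(30L, 40L, 32L, 36L),
    significant = TRUE)
}

# A single clean pulse on a flat background.
pulse_trace <- function(n_frames = 120L, at = 50L, amplitude = 20,
                        level = 100) {
  tr <- rep(level, n_frames)
  span <- at:min(at + 30L, n_frames)
  tr[span] <- level + amplitude *
    (exp(-(seq_along(span) - 1) / 8) - exp(-(seq_along(span) - 1) / 1.5)) /
    max(exp(-(0:30) / 8) - exp(-(0:30) / 1.5))
  tr
}
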