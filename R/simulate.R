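# Synthetic-culture simulator: Voronoi region geometry, calcium transients
# with fast rise and slow decay on a drifting baseline, probabilistic
# propagation to adjacent regions with frame-scale delays, additive Gaussian
# noise, and full ground truth for validation.

#' Simulation configuration
#'
#' Defaults emulate a desk-scale version of a 2 Hz, 20-minute recording of a
#' cultured field: 25 regions tiling a 128 x 128 px field, 2400 frames,
#' transients with a 1 s rise and 10 s decay, a slow sinusoidal baseline
#' drift, and spontaneous initiator events at about two per cell per
#' recording. The default amplitude/noise ratio is 10.
#'
#' @param n_cells Number of regions.
#' @param field Field size in pixels, `c(height, width)`.
#' @param n_frames Number of frames.
#' @param frame_rate Frames per second.
#' @param rise_frames,decay_frames Transient kernel time constants (frames).
#' @param amplitude Transient peak amplitude (intensity units).
#' @param baseline_level Resting intensity level.
#' @param drift_amplitude,drift_period Sinusoidal baseline drift (intensity
#'   units; frames).
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param prop_prob Probability that an event propagates to each adjacent
#'   region.
#' @param delay_range Propagation delay bounds in frames, `c(min, max)`;
#'   minimum 1 so that propagated events start strictly later.
#' @param event_rate Spontaneous initiator-event rate per cell per frame.
#' @param connectivity Pixel connectivity used for region adjacency (4 or 8).
#' @param seed Integer RNG seed; every simulator output is reproducible
#'   given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 25L, field = c(128L, 128L),
                       n_frames = 2400L, frame_rate = 2,
                       rise_frames = 2, decay_frames = 20, amplitude = 30,
                       baseline_level = 100, drift_amplitude = 2,
                       drift_period = 600, noise_sd = 3,
                       prop_prob = 0.3, delay_range = c(2L, 5L),
                       event_rate = 2 / 2400, connectivity = 8,
                       seed = 1L) {
  stopifnot(n_cells >= 1L, length(field) == 2L, all(field >= 1L),
            n_frames >= 1L, frame_rate > 0,
            rise_frames > 0, decay_frames > rise_frames, amplitude > 0,
            drift_amplitude >= 0, drift_period > 0, noise_sd >= 0,
            prop_prob >= 0, prop_prob <= 1,
            length(delay_range) == 2L, delay_range[1L] >= 1L,
            delay_range[1L] <= delay_range[2L],
            event_rate >= 0, connectivity %in% c(4, 8))
  if (n_cells > prod(field)) {
    stop("degenerate geometry: n_cells (", n_cells,
         ") exceeds the number of pixels (", prod(field), ").",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

# Difference-of-exponentials transient, peak-normalised to `amplitude`,
# truncated where it decays below 2% of the peak. Returns the kernel vector
# and the 1-based offset of its peak.
transient_kernel <- function(rise, decay, amplitude) {
  t <- 0:ceiling(decay * 6 + rise)
  k <- exp(-t / decay) - exp(-t / rise)
  k <- k / max(k) * amplitude
  keep <- seq_len(max(which(k >= 0.02 * amplitude)))
  list(kernel = k[keep], peak_offset = which.max(k))
}

# Voronoi tessellation of the pixel grid around sampled seed points.
voronoi_labels <- function(field, n_cells) {
  H <- field[1L]; W <- field[2L]
  pick <- sample.int(H * W, n_cells)
  sr <- (pick - 1L) %% H + 1L
  sc <- (pick - 1L) %/% H + 1L
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  best_d <- matrix(Inf, H, W)
  labels <- matrix(0L, H, W)
  for (i in seq_len(n_cells)) {
    d <- (rows - sr[i])^2 + (cols - sc[i])^2
    hit <- d < best_d  # strict: ties keep the lowest id, deterministically
    labels[hit] <- i
    best_d[hit] <- d[hit]
  }
  labels
}

#' Simulate a synthetic culture with known ground truth
#'
#' Regions are the Voronoi cells of seed points sampled on the pixel grid.
#' Initiator events arrive per cell as a Poisson process; each event
#' propagates to each adjacent region with probability `prop_prob` after a
#' delay drawn uniformly from `delay_range` (at least one frame, so
#' propagated events start strictly later), and propagated events propagate
#' onwards in the same way (one activation per cell per wave). Each cell's
#' trace is the resting level plus sinusoidal drift, the sum of transient
#' kernels at its event starts, and Gaussian noise. All realised propagation
#' pairs and true event boundaries are recorded.
#'
#' @param config A [sim_config()].
#' @param video Also render the full frames x H x W intensity stack?
#'   Trace-level output (the default) exercises the same downstream code.
#' @return A list of class `sim_culture`: `labels`, `adjacency`, `centers`,
#'   `traces` (frames x cells tibble), `truth` (list of `events` and
#'   `propagations` tibbles), `config`, and optionally `video`.
#' @export
simulate_culture <- function(config = sim_config(), video = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  T <- config$n_frames
  n <- config$n_cells
  labels <- voronoi_labels(config$field, n)
  adjacency <- compute_adjacency(labels, config$connectivity)
  centers <- region_centers(labels)
  kern <- transient_kernel(config$rise_frames, config$decay_frames,
                           config$amplitude)
  L <- length(kern$kernel)

  events <- list()    # cell_id, start (frame of kernel onset), wave id
  props <- list()     # source, target, source_start, target_start, delay
  wave_id <- 0L
  add_event <- function(cell, start) {
    events[[length(events) + 1L]] <<- c(cell = cell, start = start,
                                        wave = wave_id)
  }
  neighbours <- lapply(seq_len(n), function(i) which(adjacency[i, ] == 1L))
  for (cell in seq_len(n)) {
    n_init <- stats::rpois(1L, config$event_rate * T)
    if (n_init == 0L) next
    starts <- sort(sample.int(max(T - L, 1L), n_init))
    for (s0 in starts) {
      # Breadth-first wave from the initiator; a cell fires at most once
      # per wave.
      wave_id <- wave_id + 1L
      visited <- cell
      queue <- list(c(cell = cell, start = s0))
      add_event(cell, s0)
      while (length(queue)) {
        cur <- queue[[1L]]; queue <- queue[-1L]
        for (nb in neighbours[[cur[["cell"]]]]) {
          if (nb %in% visited) next
          if (stats::runif(1L) > config$prop_prob) next
          d <- sample(config$delay_range[1L]:config$delay_range[2L], 1L)
          t_nb <- cur[["start"]] + d
          if (t_nb > T) next
          visited <- c(visited, nb)
          add_event(nb, t_nb)
          props[[length(props) + 1L]] <- c(
            source = cur[["cell"]], target = nb,
            source_start = cur[["start"]], target_start = t_nb, delay = d)
          queue[[length(queue) + 1L]] <- c(cell = nb, start = t_nb)
        }
      }
    }
  }
  ev <- if (length(events)) {
    m <- do.call(rbind, events)
    tibble::tibble(
      cell_id = as.integer(m[, "cell"]),
      start = as.integer(m[, "start"]),
      peak = pmin(as.integer(m[, "start"]) + kern$peak_offset - 1L, T),
      finish = pmin(as.integer(m[, "start"]) + L - 1L, T),
      wave = as.integer(m[, "wave"])) |>
      dplyr::arrange(.data$cell_id, .data$start)
  } else {
    tibble::tibble(cell_id = integer(), start = integer(),
                   peak = integer(), finish = integer(), wave = integer())
  }
  pr <- if (length(props)) {
    m <- do.call(rbind, props)
    tibble::tibble(
      source = as.integer(m[, "source"]), target = as.integer(m[, "target"]),
      source_start = as.integer(m[, "source_start"]),
      target_start = as.integer(m[, "target_start"]),
      delay = as.integer(m[, "delay"])) |>
      dplyr::arrange(.data$source, .data$target, .data$source_start)
  } else {
    tibble::tibble(source = integer(), target = integer(),
                   source_start = integer(), target_start = integer(),
                   delay = integer())
  }
  wp <- wave_pairs(ev, adjacency)

  tr <- drift_matrix(config) +
    matrix(stats::rnorm(T * n, 0, config$noise_sd), T, n)
  for (r in seq_len(nrow(ev))) {
    span <- ev$start[r]:min(ev$start[r] + L - 1L, T)
    tr[span, ev$cell_id[r]] <- tr[span, ev$cell_id[r]] +
      kern$kernel[seq_along(span)]
  }
  colnames(tr) <- as.character(seq_len(n))
  out <- list(labels = labels, adjacency = adjacency, centers = centers,
              traces = tibble::as_tibble(tr),
              truth = list(events = ev, propagations = pr, wave_pairs = wp),
              config = config)
  if (video) out$video <- render_video_stack(tr, labels, config)
  structure(out, class = "sim_culture")
}

# Directed adjacent pairs co-activated by one wave, earlier cell first.
# A wave reaching two adjacent regions (directly or through a relay)
# propagates signal between them in the order of activation; these are the
# directed pairs the overlap analysis is expected to recover.
wave_pairs <- function(ev, adjacency) {
  out <- tibble::tibble(source = integer(), target = integer())
  if (!nrow(ev) || !"wave" %in% names(ev)) return(out)
  by_wave <- split(ev, ev$wave)
  pairs <- list()
  for (w in by_wave) {
    if (nrow(w) < 2L) next
    g <- tidyr::expand_grid(a = seq_len(nrow(w)), b = seq_len(nrow(w)))
    keep <- w$start[g$a] < w$start[g$b] &
      adjacency[cbind(w$cell_id[g$a], w$cell_id[g$b])] == 1L
    if (any(keep)) pairs[[length(pairs) + 1L]] <- tibble::tibble(
      source = w$cell_id[g$a[keep]], target = w$cell_id[g$b[keep]])
  }
  if (length(pairs)) {
    dplyr::distinct(dplyr::arrange(dplyr::bind_rows(pairs), .data$source,
                                   .data$target))
  } else out
}

# Resting level + per-cell phase-shifted sinusoidal drift, frames x cells.
drift_matrix <- function(config) {
  T <- config$n_frames; n <- config$n_cells
  phase <- stats::runif(n, 0, 2 * pi)
  t <- seq_len(T)
  config$baseline_level +
    config$drift_amplitude *
      sin(outer(t, rep(2 * pi / config$drift_period, n)) +
            matrix(phase, T, n, byrow = TRUE))
}

# Paint per-cell trace values onto the label image for each frame.
render_video_stack <- function(tr, labels, config) {
  T <- nrow(tr)
  H <- nrow(labels); W <- ncol(labels)
  stack <- array(0, dim = c(T, H, W))
  lab_vec <- as.vector(labels)
  for (t in seq_len(T)) {
    frame <- numeric(H * W)
    frame[lab_vec > 0] <- tr[t, lab_vec[lab_vec > 0]]
    stack[t, , ] <- matrix(frame, H, W)
  }
  stack
}

#' @export
print.sim_culture <- function(x, ...) {
  cat("Synthetic culture:", x$config$n_cells, "cells,",
      x$config$n_frames, "frames\n")
  cat("  true events:", nrow(x$truth$events),
      " true propagations:", nrow(x$truth$propagations), "\n")
  invisible(x)
}

#' Simulate a noise-only (non-signalling) culture
#'
#' Traces contain only the resting level, the sinusoidal drift and Gaussian
#' noise — no transients. Models the fluorescence of a non-signalling cell
#' line used as a biological-noise negative control for
#' [estimate_noise_threshold()].
#'
#' @inheritParams simulate_culture
#' @return A frames x cells tibble of traces.
#' @export
simulate_noise_culture <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  T <- config$n_frames; n <- config$n_cells
  tr <- drift_matrix(config) +
    matrix(stats::rnorm(T * n, 0, config$noise_sd), T, n)
  colnames(tr) <- as.character(seq_len(n))
  tibble::as_tibble(tr)
}

#' Simulate a group of cultures with per-culture jitter
#'
#' Generates `n_cultures` seeded cultures from a template configuration,
#' jittering the propagation probability and spontaneous event rate by a
#' uniform factor in `1 +/- jitter` per culture, and returns both the
#' simulated cultures and a manifest table.
#'
#' @inheritParams simulate_culture
#' @param n_cultures Number of cultures in the group.
#' @param group Group label attached to the manifest.
#' @param jitter Relative jitter of `prop_prob` and `event_rate`;
#'   default 0.1.
#' @return A list with `cultures` (list of `sim_culture`) and `manifest`
#'   (tibble: `culture_id`, `group`, `seed`, `prop_prob`, `event_rate`).
#' @export
make_group <- function(config = sim_config(), n_cultures, group,
                       jitter = 0.1) {
  stopifnot(inherits(config, "sim_config"), n_cultures >= 1L,
            jitter >= 0, jitter < 1)
  set.seed(config$seed)
  fac_p <- stats::runif(n_cultures, 1 - jitter, 1 + jitter)
  fac_r <- stats::runif(n_cultures, 1 - jitter, 1 + jitter)
  cultures <- vector("list", n_cultures)
  manifest <- vector("list", n_cultures)
  for (i in seq_len(n_cultures)) {
    cfg <- config
    cfg$seed <- config$seed + i
    cfg$prop_prob <- min(1, config$prop_prob * fac_p[i])
    cfg$event_rate <- config$event_rate * fac_r[i]
    cultures[[i]] <- simulate_culture(cfg)
    manifest[[i]] <- tibble::tibble(
      culture_id = paste0(group, "_", i), group = group, seed = cfg$seed,
      prop_prob = cfg$prop_prob, event_rate = cfg$event_rate)
  }
  list(cultures = cultures, manifest = dplyr::bind_rows(manifest))
}

#' Score recovered propagation pairs against simulator ground truth
#'
#' Compares the directed cell pairs of a compressed transmission graph with
#' the true propagation pairs of a simulated culture: the adjacent pairs
#' co-activated by one wave (directly or through a relay cell), ordered by
#' activation time (`truth$wave_pairs`). `recovery` is the fraction of true
#' directed pairs present in the graph; `spurious` is the fraction of
#' recovered pairs whose cell pair was never co-activated in either order;
#' `direction_accuracy` is, among recovered pairs whose undirected pair is
#' true, the fraction recovered with the correct direction.
#'
#' @param truth The `truth` element of a [simulate_culture()] result.
#' @param cg The `compressed_graph` recovered by the analysis pipeline.
#' @return A one-row tibble: `n_true`, `n_recovered`, `recovery`,
#'   `spurious`, `direction_accuracy` (NA where undefined).
#' @export
evaluate_recovery <- function(truth, cg) {
  stopifnot(inherits(cg, "compressed_graph"))
  tp <- truth$wave_pairs %||% truth$propagations
  true_dir <- unique(paste(tp$source, tp$target))
  true_und <- unique(paste(pmin(tp$source, tp$target),
                           pmax(tp$source, tp$target)))
  rec <- cg$edges
  rec_dir <- paste(rec$source, rec$target)
  rec_und <- paste(pmin(rec$source, rec$target),
                   pmax(rec$source, rec$target))
  on_true <- rec_und %in% true_und
  tibble::tibble(
    n_true = length(true_dir),
    n_recovered = length(rec_dir),
    recovery = if (length(true_dir)) mean(true_dir %in% rec_dir) else NA_real_,
    spurious = if (length(rec_dir)) mean(!on_true) else 0,
    direction_accuracy = if (any(on_true)) {
      mean(rec_dir[on_true] %in% true_dir)
    } else NA_real_
  )
}
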