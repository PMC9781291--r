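# Independent reference implementations used as oracles. Everything here is
# written as plain frame-by-frame / pixel-by-pixel scans, deliberately
# avoiding the vectorised code paths of the package.

# Exhaustive crossing-scan event detector: explicit recursions and scans.
oracle_detect_events <- function(trace, k, threshold) {
  T <- length(trace)
  ef <- numeric(T); ef[1] <- trace[1]
  if (T > 1) for (j in 2:T) ef[j] <- ef[j - 1] * k + (1 - k) * trace[j]
  eb <- numeric(T); eb[T] <- trace[T]
  if (T > 1) for (j in (T - 1):1) eb[j] <- eb[j + 1] * k + (1 - k) * trace[j]

  # baseline: per-run minima of frames strictly below the forward EMA,
  # linear interpolation between anchors, horizontal extension outside
  anchors <- integer(0)
  j <- 1
  while (j <= T) {
    if (trace[j] < ef[j]) {
      s <- j
      while (j <= T && trace[j] < ef[j]) j <- j + 1
      seg <- s:(j - 1)
      best <- seg[1]
      for (q in seg) if (trace[q] < trace[best]) best <- q
      anchors <- c(anchors, best)
    } else j <- j + 1
  }
  bl <- numeric(T)
  if (length(anchors) == 0) {
    bl <- trace
  } else {
    for (j in seq_len(T)) {
      if (j <= anchors[1]) {
        bl[j] <- trace[anchors[1]]
      } else if (j >= anchors[length(anchors)]) {
        bl[j] <- trace[anchors[length(anchors)]]
      } else {
        kk <- max(which(anchors <= j))
        t0 <- anchors[kk]; t1 <- anchors[kk + 1]
        bl[j] <- trace[t0] + (j - t0) * (trace[t1] - trace[t0]) / (t1 - t0)
      }
    }
  }

  # events: runs strictly above the forward EMA
  rows <- list()
  j <- 1
  while (j <= T) {
    if (trace[j] > ef[j]) {
      s <- j
      while (j <= T && trace[j] > ef[j]) j <- j + 1
      seg <- s:(j - 1)
      peak <- seg[1]
      for (q in seg) if (trace[q] > trace[peak]) peak <- q
      f <- peak
      while (f <= T && trace[f] > eb[f]) f <- f + 1
      if (f > T) f <- T
      rows[[length(rows) + 1]] <- c(start = s, peak = peak, finish = f)
    } else j <- j + 1
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), peak = integer(),
                      finish = integer(), amplitude = numeric()))
  }
  m <- as.data.frame(do.call(rbind, rows))
  # clip finishes into the next event's start
  if (nrow(m) > 1) {
    for (r in 1:(nrow(m) - 1)) {
      if (m$finish[r] >= m$start[r + 1]) m$finish[r] <- m$start[r + 1] - 1
    }
  }
  m$amplitude <- trace[m$peak] - bl[m$peak]
  m[m$amplitude > threshold, , drop = FALSE]
}

# Brute-force dense dynamic graph: all pairs, all event pairs, all frames.
oracle_dense_graph <- function(events, adjacency, n_frames) {
  n <- nrow(adjacency)
  arr <- array(FALSE, dim = c(n, n, n_frames))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || adjacency[i, j] != 1) next
    ei <- events[events$cell_id == i, , drop = FALSE]
    ej <- events[events$cell_id == j, , drop = FALSE]
    for (a in seq_len(nrow(ei))) for (b in seq_len(nrow(ej))) {
      sa <- ei$start[a]; fa <- ei$finish[a]
      sb <- ej$start[b]; fb <- ej$finish[b]
      if (sa < sb && sb <= fa && fa <= fb) {
        arr[i, j, sb:fa] <- TRUE
      }
    }
  }
  arr
}

# Frame-sum, per-frame max, and per-pair onset tallies from a dense array.
oracle_dense_metrics <- function(arr) {
  n <- dim(arr)[1]; T <- dim(arr)[3]
  per_frame <- integer(T)
  for (t in seq_len(T)) per_frame[t] <- sum(arr[, , t])
  counts <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    prev <- FALSE
    for (t in seq_len(T)) {
      if (arr[i, j, t] && !prev) counts[i, j] <- counts[i, j] + 1L
      prev <- arr[i, j, t]
    }
  }
  list(edge_count = sum(per_frame),
       max_per_frame = if (T) max(per_frame) else 0L,
       counts = counts)
}

# All-pairs pixel scan for region adjacency.
oracle_adjacency <- function(labels, connectivity) {
  n <- max(labels)
  a <- matrix(0L, n, n)
  H <- nrow(labels); W <- ncol(labels)
  offs <- if (connectivity == 4) {
    list(c(0, 1), c(1, 0), c(0, -1), c(-1, 0))
  } else {
    list(c(0, 1), c(1, 0), c(0, -1), c(-1, 0),
         c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  }
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    u <- labels[r, cc]
    if (u == 0) next
    for (o in offs) {
      r2 <- r + o[1]; c2 <- cc + o[2]
      if (r2 < 1 || r2 > H || c2 < 1 || c2 > W) next
      v <- labels[r2, c2]
      if (v > 0 && v != u) { a[u, v] <- 1L; a[v, u] <- 1L }
    }
  }
  a
}

# Exhaustive order-preserving matching cost for markup_error (tiny inputs).
oracle_markup_error <- function(manual, algorithmic) {
  m <- manual[order(manual$start), , drop = FALSE]
  a <- algorithmic[order(algorithmic$start), , drop = FALSE]
  pen_m <- m$finish - m$start + 1
  pen_a <- a$finish - a$start + 1
  rec <- function(i, j) {
    if (i > nrow(m) && j > nrow(a)) return(0)
    if (i > nrow(m)) return(sum(pen_a[j:nrow(a)]))
    if (j > nrow(a)) return(sum(pen_m[i:nrow(m)]))
    best <- abs(m$start[i] - a$start[j]) + abs(m$finish[i] - a$finish[j]) +
      rec(i + 1, j + 1)
    best <- min(best, pen_m[i] + rec(i + 1, j))
    min(best, pen_a[j] + rec(i, j + 1))
  }
  rec(1, 1)
}

# Random non-overlapping event table for n cells over T frames.
random_events <- function(n_cells, n_frames, max_events = 4L,
                          max_len = 40L) {
  rows <- list()
  for (i in seq_len(n_cells)) {
    k <- sample(0:max_events, 1)
    if (k == 0) next
    pts <- sort(sample.int(n_frames, 2L * k))
    for (q in seq_len(k)) {
      s <- pts[2 * q - 1]
      f <- min(pts[2 * q], s + max_len)
      if (q > 1 && s <= rows[[length(rows)]]["finish"] &&
          rows[[length(rows)]]["cell"] == i) next
      rows[[length(rows) + 1]] <- c(cell = i, start = s, finish = f)
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(cell_id = integer(), start = integer(),
                          finish = integer()))
  }
  m <- do.call(rbind, rows)
  tibble::tibble(cell_id = as.integer(m[, "cell"]),
                 start = as.integer(m[, "start"]),
                 finish = as.integer(m[, "finish"]))
}

# Random symmetric zero-diagonal adjacency.
random_adjacency <- function(n, p = 0.5) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p) { a[i, j] <- 1L; a[j, i] <- 1L }
  }
  a
}

# Compressed graph straight from a count matrix (internal constructor).
compressed_from_counts_test <- function(C) {
  capnet:::compressed_from_counts(matrix(as.integer(C), nrow(C)))
}

# Random trace: drifting mean + noise + a few positive pulses.
random_trace <- function(n_frames) {
  tr <- 100 + cumsum(stats::rnorm(n_frames, 0, 0.3)) +
    stats::rnorm(n_frames, 0, 2)
  for (q in seq_len(sample(0:3, 1))) {
    s <- sample.int(max(n_frames - 20, 1), 1)
    len <- sample(5:20, 1)
    span <- s:min(s + len, n_frames)
    tr[span] <- tr[span] + 15 * exp(-(seq_along(span) - 1) / 6)
  }
  tr
}
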