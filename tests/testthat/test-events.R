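test_that("event peaks are per-run maxima above the forward EMA", {
  # trace always below its EMA: no peaks
  tr <- c(10, 9, 8, 7, 6)
  expect_identical(nrow(find_event_peaks(tr, ema_forward(tr, 0.9))), 0L)
  # single triangular pulse: one peak at the apex
  tr <- c(rep(1, 10), 1:5, 4:1, rep(1, 10))
  pk <- find_event_peaks(tr, ema_forward(tr, 0.9))
  expect_equal(pk$peak, 15L)
  expect_equal(pk$peak_intensity, 5)
  # multi-pulse trace matches a brute-force run scan
  set.seed(21)
  for (rep in 1:30) {
    tr <- random_trace(150)
    ef <- ema_forward(tr, 0.9)
    got <- find_event_peaks(tr, ef)
    runs <- list(); j <- 1
    while (j <= length(tr)) {
      if (tr[j] > ef[j]) {
        s <- j
        while (j <= length(tr) && tr[j] > ef[j]) j <- j + 1
        seg <- s:(j - 1)
        runs[[length(runs) + 1]] <- seg[which.max(tr[seg])]
      } else j <- j + 1
    }
    expect_equal(got$peak, as.integer(unlist(runs)))
  }
})

test_that("baseline interpolates sub-EMA minima and degenerates gracefully", {
  # constant trace: baseline equals the trace
  tr <- rep(5, 40)
  bl <- compute_baseline(tr, ema_forward(tr, 0.9))
  expect_equal(as.numeric(bl), tr)
  expect_identical(nrow(attr(bl, "anchors")), 0L)
  # two anchors (t = 2, I = 1) and (t = 6, I = 3): direct substitution into
  # the interpolation formula gives bl_4 = 1 + (4-2)*(3-1)/(6-2) = 2;
  # craft a trace whose sub-EMA minima sit exactly there
  tr <- c(10, 1, 10, 10, 10, 3, 10)
  ef <- rep(5, 7)
  bl <- compute_baseline(tr, ef)
  expect_equal(attr(bl, "anchors")$frame, c(2L, 6L))
  expect_equal(as.numeric(bl)[4], 2)
  # horizontal extension outside the anchors
  expect_equal(as.numeric(bl)[1], 1)
  expect_equal(as.numeric(bl)[7], 3)
  # a flat trace with one positive pulse: baseline stays near the flat level
  tr <- pulse_trace()
  bl <- compute_baseline(tr, ema_forward(tr, 0.95))
  expect_lt(max(abs(as.numeric(bl) - 100)), 1e-6)
})

test_that("a single large pulse yields exactly one event bracketing it", {
  tr <- pulse_trace(amplitude = 20)
  ev <- detect_events(tr, k = 0.95, threshold = 2)
  expect_identical(nrow(ev), 1L)
  expect_lte(ev$start, 51L)
  expect_gte(ev$finish, ev$peak)
  expect_true(ev$start <= ev$peak && ev$peak <= ev$finish)
  expect_equal(ev$peak_intensity, max(tr))
  expect_gt(ev$amplitude, 19)
})

test_that("detected boundaries equal the exhaustive crossing-scan oracle", {
  set.seed(31)
  for (rep in 1:60) {
    tr <- random_trace(sample(20:200, 1))
    k <- runif(1, 0.6, 0.98)
    thr <- runif(1, 0, 8)
    got <- detect_events(tr, k = k, threshold = thr)
    ora <- oracle_detect_events(tr, k, thr)
    expect_equal(got$start, as.integer(ora$start))
    expect_equal(got$peak, as.integer(ora$peak))
    expect_equal(got$finish, as.integer(ora$finish))
    expect_equal(got$amplitude, ora$amplitude)
  }
})

test_that("detection is invariant to a constant intensity offset", {
  set.seed(41)
  tr <- random_trace(300)
  a <- detect_events(tr, k = 0.95, threshold = 3)
  b <- detect_events(tr + 250, k = 0.95, threshold = 3)
  expect_equal(a$start, b$start)
  expect_equal(a$finish, b$finish)
  expect_equal(a$amplitude, b$amplitude, tolerance = 1e-9)
})

test_that("raising the threshold never increases the event count", {
  set.seed(51)
  for (rep in 1:10) {
    tr <- random_trace(250)
    counts <- vapply(c(0, 2, 5, 10, 20),
                     function(th) nrow(detect_events(tr, 0.95, th)),
                     integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("every detected event satisfies the ordering invariants", {
  set.seed(61)
  for (rep in 1:20) {
    tr <- random_trace(200)
    ev <- detect_events(tr, k = 0.9, threshold = 1)
    if (!nrow(ev)) next
    expect_true(all(ev$start <= ev$peak & ev$peak <= ev$finish))
    ef <- ema_forward(tr, 0.9)
    expect_true(all(tr[ev$peak] > ef[ev$peak]))
    # events of one cell are non-overlapping in start order
    if (nrow(ev) > 1) {
      expect_true(all(ev$start[-1] > ev$finish[-nrow(ev)]))
    }
  }
})

test_that("significant events are rare on pure noise at the 3-SD threshold", {
  # Monte-Carlo: iid Gaussian noise, threshold = 3 x pooled SD of the
  # deviations from baseline. The per-frame event rate stays below a bound
  # itself derived by Monte-Carlo for this rule (0.05/frame).
  set.seed(71)
  n_frames <- 200
  rates <- replicate(100, {
    tr <- rnorm(n_frames, 100, 4)
    thr <- estimate_noise_threshold(tr, k = 0.97)
    nrow(detect_events(tr, k = 0.97, threshold = thr)) / n_frames
  })
  expect_lt(mean(rates), 0.05)
})

test_that("noise threshold recovers 3 sigma and scales linearly", {
  # zero traces give a zero threshold
  expect_equal(estimate_noise_threshold(matrix(0, 100, 3)), 0)
  # iid noise with SD sigma, drift-free
  set.seed(81)
  m <- matrix(rnorm(2400 * 10, 100, 4), 2400, 10)
  thr <- estimate_noise_threshold(m, k = 0.97)
  expect_equal(thr, 12, tolerance = 0.05)
  # multiplier linearity
  expect_equal(estimate_noise_threshold(m, k = 0.97, multiplier = 1),
               thr / 3)
  expect_error(estimate_noise_threshold(matrix(numeric(0), 0, 0)),
               "at least one")
})
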