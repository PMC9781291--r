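test_that("overlap classification follows the staggered rule", {
  expect_identical(classify_overlap(c(10, 20), c(15, 25)), "forward")
  expect_identical(classify_overlap(c(15, 25), c(10, 20)), "backward")
  expect_identical(classify_overlap(c(10, 20), c(30, 40)), "none")
  expect_identical(classify_overlap(c(10, 20), c(10, 18)), "simultaneous")
  # nested events carry no direction
  expect_identical(classify_overlap(c(10, 30), c(15, 25)), "none")
  # coinciding finishes are allowed (ties are common on integer frames)
  expect_identical(classify_overlap(c(10, 20), c(15, 20)), "forward")
  # touching at a single frame still overlaps
  expect_identical(classify_overlap(c(10, 20), c(20, 25)), "forward")
  # data-frame input
  expect_identical(
    classify_overlap(tibble::tibble(start = 1, finish = 5),
                     tibble::tibble(start = 3, finish = 8)),
    "forward")
})

test_that("overlap classification is antisymmetric on random events", {
  set.seed(151)
  for (rep in 1:200) {
    a <- sort(sample.int(50, 2)); b <- sort(sample.int(50, 2))
    ra <- classify_overlap(a, b); rb <- classify_overlap(b, a)
    expected <- switch(ra, forward = "backward", backward = "forward",
                       simultaneous = "simultaneous", none = "none")
    expect_identical(rb, expected)
  }
})

test_that("the four-region worked example yields exactly 1->2, 1->3, 3->4", {
  adj <- compute_adjacency(fig3_labels(), connectivity = 4)
  g <- build_dynamic_graph(fig3_events(), adj, n_frames = 50L)
  got <- unique(g$edges[, c("source", "target")])
  expect_equal(dplyr::arrange(got, source, target),
               tibble::tibble(source = c(1L, 1L, 3L),
                              target = c(2L, 3L, 4L)))
  cg <- compress_graph(g)
  expect_equal(cg$edges$source, c(1L, 1L, 3L))
  expect_equal(cg$edges$target, c(2L, 3L, 4L))
  expect_equal(cg$edges$count, c(1L, 1L, 1L))
  # the nested pair (2, 4) is flagged for audit, not turned into an edge
  expect_true(nrow(g$nested) >= 1)
})

test_that("without adjacency there are no edges regardless of events", {
  g <- build_dynamic_graph(fig3_events(), matrix(0L, 4, 4), n_frames = 50L)
  expect_identical(nrow(g$edges), 0L)
  expect_identical(length(g$active_cells), 0L)
})

test_that("graph construction matches the dense all-frames oracle", {
  set.seed(161)
  for (rep in 1:25) {
    n <- sample(3:6, 1); T <- sample(30:120, 1)
    adj <- random_adjacency(n)
    ev <- random_events(n, T)
    ev$finish <- pmin(ev$finish, T)
    g <- build_dynamic_graph(ev, adj, n_frames = T)
    expect_identical(unname(to_dense(g)),
                     unname(oracle_dense_graph(as.data.frame(ev), adj, T)))
  }
})

test_that("event cell ids outside the adjacency dimension are rejected", {
  ev <- tibble::tibble(cell_id = 7L, start = 1L, finish = 5L)
  expect_error(build_dynamic_graph(ev, matrix(0L, 4, 4)),
               "outside the adjacency dimension.*7")
})

test_that("dense conversion is exact and memory-guarded", {
  # empty graph: all-zero array
  g <- build_dynamic_graph(tibble::tibble(cell_id = integer(),
                                          start = integer(),
                                          finish = integer()),
                           matrix(0L, 3, 3), n_frames = 10L)
  expect_true(all(!to_dense(g)))
  # a single edge over 3 frames has exactly 3 true entries
  adj <- matrix(0L, 2, 2); adj[1, 2] <- adj[2, 1] <- 1L
  ev <- tibble::tibble(cell_id = c(1L, 2L), start = c(1L, 3L),
                       finish = c(5L, 8L))
  g <- build_dynamic_graph(ev, adj, n_frames = 8L)
  expect_identical(sum(to_dense(g)), 3L)
  expect_error(to_dense(g, budget = 10), "exceeds the budget")
})

test_that("dense -> edges -> dense round-trips on random graphs", {
  set.seed(171)
  for (rep in 1:15) {
    n <- sample(2:5, 1); T <- sample(20:60, 1)
    g <- build_dynamic_graph(random_events(n, T), random_adjacency(n),
                             n_frames = T)
    arr <- to_dense(g)
    expect_identical(to_dense(dense_to_edges(arr)), arr)
  }
})

test_that("removing an adjacency entry removes exactly that pair's edges", {
  set.seed(181)
  n <- 6; T <- 100
  adj <- random_adjacency(n, p = 0.8)
  ev <- random_events(n, T)
  g_full <- build_dynamic_graph(ev, adj, n_frames = T)
  pairs <- which(adj == 1L & upper.tri(adj), arr.ind = TRUE)
  i <- pairs[1, 1]; j <- pairs[1, 2]
  adj2 <- adj; adj2[i, j] <- adj2[j, i] <- 0L
  g_cut <- build_dynamic_graph(ev, adj2, n_frames = T)
  kept <- dplyr::filter(g_full$edges,
                        !(source %in% c(i, j) & target %in% c(i, j)))
  expect_equal(g_cut$edges, dplyr::arrange(kept, source, target,
                                           first_frame, target_event))
})

test_that("construction is deterministic with stable edge ordering", {
  set.seed(191)
  ev <- random_events(5, 80)
  adj <- random_adjacency(5)
  g1 <- build_dynamic_graph(ev, adj, n_frames = 80L)
  g2 <- build_dynamic_graph(ev[sample.int(nrow(ev)), ], adj, n_frames = 80L)
  expect_identical(g1$edges, g2$edges)
  e <- g1$edges
  if (nrow(e) > 1) {
    o <- order(e$source, e$target, e$first_frame, e$target_event)
    expect_identical(o, seq_len(nrow(e)))
  }
})

test_that("time reversal flips every directed relation", {
  # mirror the event table in time: starts and finishes swap roles. With
  # all boundary frames distinct (no ties), every forward edge must become
  # a backward edge of the reversed table and vice versa.
  set.seed(201)
  T <- 100L
  adj <- random_adjacency(4, p = 1)
  for (rep in 1:30) {
    vals <- sample.int(T, 8L)
    ev <- tibble::tibble(
      cell_id = 1:4,
      start = pmin(vals[1:4], vals[5:8]),
      finish = pmax(vals[1:4], vals[5:8]))
    fwd <- build_dynamic_graph(ev, adj, n_frames = T)
    rev_ev <- tibble::tibble(cell_id = ev$cell_id,
                             start = T + 1L - ev$finish,
                             finish = T + 1L - ev$start)
    bwd <- build_dynamic_graph(rev_ev, adj, n_frames = T)
    expect_identical(sort(paste(bwd$edges$source, bwd$edges$target)),
                     sort(paste(fwd$edges$target, fwd$edges$source)))
  }
})
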