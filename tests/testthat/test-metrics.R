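# Build a dynamic graph directly from an edge specification (dense route).
make_graph <- function(edges, n, T) {
  arr <- array(FALSE, dim = c(n, n, T))
  for (r in seq_len(nrow(edges))) {
    arr[edges$source[r], edges$target[r],
        edges$first[r]:edges$last[r]] <- TRUE
  }
  dense_to_edges(arr)
}

test_that("dynamic edge count sums overlap-interval lengths", {
  g <- make_graph(tibble::tibble(source = integer(), target = integer(),
                                 first = integer(), last = integer()),
                  3, 10)
  expect_identical(dynamic_edge_count(g), 0L)
  g <- make_graph(tibble::tibble(source = 1L, target = 2L,
                                 first = 3L, last = 7L), 3, 10)
  expect_identical(dynamic_edge_count(g), 5L)
})

test_that("active-cell counting includes simultaneous participants", {
  ev <- tibble::tibble(cell_id = integer(), start = integer(),
                       finish = integer())
  g <- build_dynamic_graph(ev, matrix(0L, 4, 4), n_frames = 10L)
  expect_equal(active_cells(g)$count, 0)
  expect_equal(active_cells(g)$percent, 0)
  # chain through all cells
  adj <- matrix(0L, 3, 3)
  adj[1, 2] <- adj[2, 1] <- adj[2, 3] <- adj[3, 2] <- 1L
  ev <- tibble::tibble(cell_id = 1:3, start = c(1L, 3L, 5L),
                       finish = c(10L, 12L, 14L))
  g <- build_dynamic_graph(ev, adj, n_frames = 14L)
  expect_equal(active_cells(g)$count, 3)
  expect_equal(active_cells(g)$percent, 100)
  # simultaneous-only pair counts as active without any directed edge
  ev <- tibble::tibble(cell_id = 1:2, start = c(5L, 5L),
                       finish = c(9L, 8L))
  g <- build_dynamic_graph(ev, adj, n_frames = 14L)
  expect_identical(nrow(g$edges), 0L)
  expect_equal(active_cells(g)$count, 2)
  expect_equal(active_cells(g, n = 8)$percent, 25)
})

test_that("per-frame maximum and totals match the dense oracle", {
  # two disjoint-in-time edges never coexist
  g <- make_graph(tibble::tibble(source = c(1L, 2L), target = c(2L, 3L),
                                 first = c(1L, 8L), last = c(4L, 11L)),
                  3, 12)
  expect_identical(max_transmissions_per_frame(g), 1L)
  set.seed(211)
  for (rep in 1:20) {
    n <- sample(3:6, 1); T <- sample(30:100, 1)
    g <- build_dynamic_graph(random_events(n, T), random_adjacency(n),
                             n_frames = T)
    m <- oracle_dense_metrics(to_dense(g))
    expect_identical(dynamic_edge_count(g), as.integer(m$edge_count))
    expect_identical(max_transmissions_per_frame(g),
                     as.integer(m$max_per_frame))
  }
})

test_that("compression counts each transmission once per direction", {
  # a single transmission lasting 6 frames counts once
  g <- make_graph(tibble::tibble(source = 1L, target = 2L,
                                 first = 2L, last = 7L), 2, 10)
  cg <- compress_graph(g)
  expect_identical(cg$counts[1, 2], 1L)
  # three cells over eight frames, transmissions in both directions
  # counted separately (compressed-graph schematic)
  edges <- tibble::tibble(
    source = c(1L, 2L, 1L, 3L, 2L),
    target = c(2L, 1L, 2L, 2L, 3L),
    first  = c(1L, 4L, 6L, 2L, 7L),
    last   = c(2L, 5L, 8L, 3L, 8L))
  g <- make_graph(edges, 3, 8)
  cg <- compress_graph(g)
  expect_identical(cg$counts[1, 2], 2L)  # frames 1-2 and 6-8: two onsets
  expect_identical(cg$counts[2, 1], 1L)
  expect_identical(cg$counts[3, 2], 1L)
  expect_identical(cg$counts[2, 3], 1L)
  expect_identical(compressed_edge_count(cg), 5L)
  expect_equal(cg$b, cg$counts - t(cg$counts))
})

test_that("compression equals the dense onset-scan oracle", {
  set.seed(221)
  for (rep in 1:20) {
    n <- sample(3:6, 1); T <- sample(30:100, 1)
    g <- build_dynamic_graph(random_events(n, T), random_adjacency(n),
                             n_frames = T)
    m <- oracle_dense_metrics(to_dense(g))
    expect_identical(compress_graph(g)$counts, m$counts)
  }
})

test_that("periodic connections ignore one-off links", {
  # every pair transmits once: nothing is periodic
  g <- make_graph(tibble::tibble(source = c(1L, 2L), target = c(2L, 3L),
                                 first = c(1L, 5L), last = c(2L, 6L)),
                  3, 10)
  expect_equal(mean_periodic_connections(g), 0)
  # one ordered pair transmits twice: both endpoints gain one degree
  g <- make_graph(tibble::tibble(source = c(1L, 1L), target = c(2L, 2L),
                                 first = c(1L, 6L), last = c(2L, 7L)),
                  3, 10)
  expect_equal(mean_periodic_connections(g), 2 / 3)
  expect_equal(mean_periodic_connections(g, n = 10), 2 / 10)
  # repetition mode counts each repeated transmission
  expect_equal(mean_periodic_connections(g, count_mode = "repetitions"),
               4 / 3)
})

test_that("degrees conserve the total transmission count", {
  # star: center sends one transmission to each of four leaves
  edges <- tibble::tibble(source = rep(1L, 4), target = 2:5,
                          first = c(1L, 5L, 9L, 13L),
                          last = c(2L, 6L, 10L, 14L))
  cg <- compress_graph(make_graph(edges, 5, 20))
  deg <- degree_centrality(cg)
  expect_identical(deg$outdegree, c(4L, 0L, 0L, 0L, 0L))
  expect_identical(deg$indegree, c(0L, 1L, 1L, 1L, 1L))
  set.seed(231)
  for (rep in 1:10) {
    n <- sample(3:7, 1); T <- sample(30:80, 1)
    g <- build_dynamic_graph(random_events(n, T), random_adjacency(n),
                             n_frames = T)
    cg <- compress_graph(g)
    deg <- degree_centrality(cg)
    nec <- compressed_edge_count(cg)
    expect_identical(sum(deg$indegree), nec)
    expect_identical(sum(deg$outdegree), nec)
    expect_lte(nec, dynamic_edge_count(g))
    expect_equal(cg$b, -t(cg$b))
  }
})

test_that("compression is equivariant under cell relabelling", {
  set.seed(241)
  n <- 5; T <- 60
  ev <- random_events(n, T)
  adj <- random_adjacency(n)
  perm <- sample.int(n)
  ev2 <- dplyr::mutate(ev, cell_id = perm[cell_id])
  adj2 <- matrix(0L, n, n)
  adj2[perm, perm] <- adj
  c1 <- compress_graph(build_dynamic_graph(ev, adj, n_frames = T))$counts
  c2 <- compress_graph(build_dynamic_graph(ev2, adj2, n_frames = T))$counts
  expect_identical(c2[perm, perm], c1)
})

test_that("HITS scores match the eigenvector formulation", {
  # single edge i -> j: i is the only hub, j the only authority
  cg <- compress_graph(make_graph(
    tibble::tibble(source = 1L, target = 2L, first = 1L, last = 3L), 3, 5))
  h <- hits_centrality(cg)
  expect_equal(h$hub, c(1, 0, 0))
  expect_equal(h$authority, c(0, 1, 0))
  # symmetric complete digraph: uniform scores
  n <- 4
  arr <- array(FALSE, dim = c(n, n, 2))
  for (i in 1:n) for (j in 1:n) if (i != j) arr[i, j, 1] <- TRUE
  cg <- compress_graph(dense_to_edges(arr))
  h <- hits_centrality(cg)
  expect_equal(h$hub, rep(1 / sqrt(n), n))
  expect_equal(h$authority, rep(1 / sqrt(n), n))
  # random instances against principal eigenvectors of C'C and CC'
  set.seed(251)
  for (rep in 1:10) {
    n <- 5
    C <- matrix(rpois(n * n, 1), n, n); diag(C) <- 0
    if (all(C == 0)) next
    cg <- compressed_from_counts_test(C)
    h <- hits_centrality(cg, tol = 1e-12, max_iter = 5000)
    ea <- eigen(t(C) %*% C)$vectors[, 1]
    eh <- eigen(C %*% t(C))$vectors[, 1]
    ea <- abs(ea) / sqrt(sum(ea^2)); eh <- abs(eh) / sqrt(sum(eh^2))
    expect_equal(h$authority, ea, tolerance = 1e-5)
    expect_equal(h$hub, eh, tolerance = 1e-5)
    expect_equal(sum(h$hub^2), 1, tolerance = 1e-9)
    expect_true(all(h$hub >= 0 & h$authority >= 0))
  }
  # empty graph warns and returns zeros
  cg0 <- compressed_from_counts_test(matrix(0L, 3, 3))
  expect_warning(h0 <- hits_centrality(cg0), "no edges")
  expect_true(all(h0$hub == 0 & h0$authority == 0))
})

test_that("HITS agrees with igraph on weighted digraphs", {
  set.seed(261)
  C <- matrix(rpois(36, 1.2), 6, 6); diag(C) <- 0
  cg <- compressed_from_counts_test(C)
  h <- hits_centrality(cg, tol = 1e-12, max_iter = 5000)
  ig <- igraph::graph_from_adjacency_matrix(C, mode = "directed",
                                            weighted = TRUE)
  hs <- igraph::hits_scores(ig, scale = TRUE)
  ig_hub <- hs$hub / sqrt(sum(hs$hub^2))
  ig_auth <- hs$authority / sqrt(sum(hs$authority^2))
  expect_equal(h$hub, unname(ig_hub), tolerance = 1e-6)
  expect_equal(h$authority, unname(ig_auth), tolerance = 1e-6)
})

test_that("the metrics report collects every summary", {
  adj <- compute_adjacency(fig3_labels(), connectivity = 4)
  g <- build_dynamic_graph(fig3_events(), adj, n_frames = 50L)
  m <- graph_metrics(g)
  expect_identical(m$dynamic_edge_count, dynamic_edge_count(g))
  expect_equal(m$n_active, 4)
  expect_equal(m$pct_active, 100)
  expect_identical(m$compressed_edge_count, 3L)
  gl <- glance(g)
  expect_identical(gl$n_cells, 4L)
  expect_identical(tidy(g), g$edges)
  cg <- compress_graph(g)
  expect_identical(tidy(cg), cg$edges)
  expect_identical(glance(cg)$n_transmissions, 3L)
})
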