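test_that("prepare_adjacency preserves negative edges as magnitudes", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- -0.8
  m[1, 3] <- m[3, 1] <- 0.5
  m[2, 3] <- m[3, 2] <- 0.1
  g <- prepare_adjacency(m, 1.0)
  expect_identical(g$adjacency[1, 2], 0.8)
  expect_identical(g$adjacency, abs(m))   # cost 1 keeps everything
})

test_that("proportional threshold keeps the strongest ceil(cost*E) edges", {
  m <- matrix(0, 4, 4)
  m[upper.tri(m)] <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  m <- m + t(m)
  g <- prepare_adjacency(m, 0.5)
  kept <- sort(g$adjacency[upper.tri(g$adjacency)], decreasing = TRUE)
  expect_equal(kept[1:3], c(0.9, 0.8, 0.7))
  expect_true(all(kept[4:6] == 0))
  expect_error(prepare_adjacency(m, 0), "cost")
  expect_error(prepare_adjacency(m, 1.2), "cost")
})

test_that("threshold sweep is monotone in edge count", {
  set.seed(21)
  m <- matrix(rnorm(100), 10, 10)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  counts <- vapply(c(0.1, 0.3, 0.5, 0.8, 1.0),
                   function(c) prepare_adjacency(m, c)$n_edges, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("participation coefficient matches hand-computed values", {
  # all edges inside own community -> 0
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[2, 1] <- 1
  g <- weighted_graph(a)
  expect_equal(participation_coefficient(g, c(1, 1, 2)), c(0, 0, 0))
  # strength split equally over 2 communities -> 0.5
  a2 <- matrix(0, 3, 3)
  a2[1, 2] <- a2[2, 1] <- 1
  a2[1, 3] <- a2[3, 1] <- 1
  expect_equal(participation_coefficient(weighted_graph(a2), c(1, 1, 2))[1],
               0.5)
  # community strengths (2,1,1), k = 4 -> 0.625
  a3 <- matrix(0, 5, 5)
  a3[1, 2] <- a3[2, 1] <- 2
  a3[1, 3] <- a3[3, 1] <- 1
  a3[1, 4] <- a3[4, 1] <- 1
  expect_equal(participation_coefficient(weighted_graph(a3),
                                         c(1, 1, 2, 3, 3))[1], 0.625)
})

test_that("pc stays within [0, 1 - 1/M] on random graphs", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    a <- random_test_graph(n)
    mem <- sample(1:3, n, replace = TRUE)
    m_comm <- length(unique(mem))
    pc <- participation_coefficient(weighted_graph(a), mem)
    expect_true(all(pc >= 0 - 1e-12))
    expect_true(all(pc <= 1 - 1 / m_comm + 1e-12))
  }
})

test_that("betweenness and efficiency match closed-form toys", {
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- 1
  path3[2, 3] <- path3[3, 2] <- 1
  g <- weighted_graph(path3)
  expect_equal(betweenness_centrality(g), c(0, 1, 0))
  expect_equal(global_efficiency(g), 5 / 6)

  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(betweenness_centrality(weighted_graph(star)), c(3, 0, 0, 0))

  cyc4 <- matrix(0, 4, 4)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
    cyc4[e[1], e[2]] <- cyc4[e[2], e[1]] <- 1
  expect_equal(betweenness_centrality(weighted_graph(cyc4)),
               rep(0.5, 4))

  complete <- matrix(1, 5, 5)
  diag(complete) <- 0
  expect_equal(global_efficiency(weighted_graph(complete)), 1)
  expect_equal(global_efficiency(weighted_graph(matrix(0, 5, 5))), 0)
  expect_error(global_efficiency(weighted_graph(matrix(0, 1, 1))),
               "at least 2")
})

test_that("modularity formula and conventions hold", {
  tri2 <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
    tri2[e[1], e[2]] <- tri2[e[2], e[1]] <- 1
  g <- weighted_graph(tri2)
  expect_equal(modularity_q(g, c(1, 1, 1, 2, 2, 2)), 0.5)
  expect_equal(modularity_q(g, rep(1, 6)), 0, tolerance = 1e-12)
  expect_lt(modularity_q(g, c(1, 1, 2, 3, 3, 3)), 0.5)
  expect_error(modularity_q(weighted_graph(matrix(0, 3, 3)), c(1, 1, 1)),
               "undefined")
})

test_that("newman communities recover planted structure", {
  tri2 <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
    tri2[e[1], e[2]] <- tri2[e[2], e[1]] <- 1
  mem <- newman_communities(weighted_graph(tri2))
  expect_identical(mem, c(1L, 1L, 1L, 2L, 2L, 2L))

  k4 <- matrix(1, 4, 4)
  diag(k4) <- 0
  expect_identical(newman_communities(weighted_graph(k4)), rep(1L, 4))

  two_k4 <- matrix(0, 8, 8)
  two_k4[1:4, 1:4] <- 1
  two_k4[5:8, 5:8] <- 1
  diag(two_k4) <- 0
  two_k4[4, 5] <- two_k4[5, 4] <- 1
  expect_identical(newman_communities(weighted_graph(two_k4)),
                   rep(c(1L, 2L), each = 4))

  expect_warning(m0 <- newman_communities(weighted_graph(matrix(0, 3, 3))),
                 "no edges")
  expect_identical(m0, rep(1L, 3))
})

test_that("path metrics agree with igraph on random graphs", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    a <- random_test_graph(n, density = 0.6)
    if (sum(a) == 0) next
    g <- weighted_graph(a)
    ig <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
    wl <- 1 / igraph::E(ig)$weight
    expect_equal(betweenness_centrality(g),
                 unname(igraph::betweenness(ig, directed = FALSE,
                                            weights = wl)),
                 tolerance = 1e-9)
    d <- igraph::distances(ig, weights = wl)
    inv <- 1 / d
    diag(inv) <- 0
    inv[is.infinite(d)] <- 0
    expect_equal(global_efficiency(g), sum(inv) / (n * (n - 1)),
                 tolerance = 1e-12)
  }
})

test_that("per-node metrics are equivariant under node relabeling", {
  set.seed(77)
  for (i in 1:10) {
    n <- 7
    a <- random_test_graph(n)
    if (sum(a) == 0) next
    perm <- sample(n)
    ap <- a[perm, perm]
    mem <- sample(1:2, n, replace = TRUE)
    g <- weighted_graph(a)
    gp <- weighted_graph(ap)
    expect_equal(participation_coefficient(gp, mem[perm]),
                 participation_coefficient(g, mem)[perm], tolerance = 1e-12)
    expect_equal(betweenness_centrality(gp),
                 betweenness_centrality(g)[perm], tolerance = 1e-9)
    expect_equal(global_efficiency(gp), global_efficiency(g),
                 tolerance = 1e-12)
    expect_equal(modularity_q(gp, newman_communities(gp)),
                 modularity_q(g, newman_communities(g)), tolerance = 1e-9)
  }
})
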