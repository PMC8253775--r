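two_cliques <- function(n1 = 5, n2 = 5) {
  n <- n1 + n2
  adj <- matrix(0, n, n)
  adj[1:n1, 1:n1] <- 1
  adj[(n1 + 1):n, (n1 + 1):n] <- 1
  diag(adj) <- 0
  adj[1, n1 + 1] <- 1  # single bridge
  adj
}

test_that("largest weakly connected component with deterministic ties", {
  adj <- matrix(0, 7, 7)
  adj[1, 2] <- 1; adj[2, 3] <- 1; adj[3, 1] <- 1   # triangle A (1-3)
  adj[4, 5] <- 1; adj[5, 6] <- 1; adj[6, 4] <- 1   # triangle B (4-6)
  expect_equal(largest_component(adj), 1:3)  # tie broken by lowest node id
  adj[3, 4] <- 1
  expect_equal(largest_component(adj), 1:6)
  expect_equal(largest_component(matrix(0, 0, 0)), integer(0))
})

test_that("components agree with flood fill on random graphs", {
  for (s in 1:15) {
    adj <- random_adjacency(20, 0.06, seed = s)
    comp <- components_bruteforce(adj)
    sizes <- table(comp)
    best <- as.integer(names(sizes)[sizes == max(sizes)])
    first_nodes <- vapply(best, function(b) min(which(comp == b)), integer(1))
    winner <- best[which.min(first_nodes)]
    expect_equal(largest_component(adj), which(comp == winner))
  }
})

test_that("two dense cliques joined by one edge split into two communities", {
  adj <- two_cliques()
  part <- detect_communities(adj, seed = 1)
  expect_equal(attr(part, "n_communities"), 2L)
  expect_equal(length(unique(part$community[1:5])), 1L)
  expect_equal(length(unique(part$community[6:10])), 1L)
  # exhaustive search agrees on the best-modularity partition
  best <- best_partition_bruteforce(adj)
  expect_equal(attr(part, "q"), modularity_bruteforce(adj, best),
               tolerance = 1e-12)
})

test_that("a complete graph is a single community with Q = 0", {
  adj <- matrix(1, 8, 8) - diag(8)
  part <- detect_communities(adj, seed = 3)
  expect_equal(attr(part, "n_communities"), 1L)
  expect_equal(attr(part, "q"), 0)
  expect_equal(modularity_q(adj, rep(1, 8)), 0)
})

test_that("community detection is deterministic under a fixed seed", {
  adj <- random_adjacency(40, 0.15, seed = 2)
  p1 <- detect_communities(adj, seed = 11)
  p2 <- detect_communities(adj, seed = 11)
  expect_identical(p1$community, p2$community)
  expect_identical(attr(p1, "q"), attr(p2, "q"))
})

test_that("modularity matches the brute-force sum and igraph", {
  for (s in 1:10) {
    adj <- random_adjacency(15, 0.25, seed = 40 + s)
    membership <- withr::with_seed(s, sample(1:4, 15, replace = TRUE))
    q <- modularity_q(adj, membership)
    expect_equal(q, modularity_bruteforce(adj, membership), tolerance = 1e-12)
    sym <- 1 * ((adj + t(adj)) > 0); diag(sym) <- 0
    g <- igraph::graph_from_adjacency_matrix(sym, mode = "undirected")
    expect_equal(q, igraph::modularity(g, membership), tolerance = 1e-12)
    expect_gte(q, -0.5)
    expect_lte(q, 1)
    # single community is exactly 0
    expect_equal(modularity_q(adj, rep(1, 15)), 0)
  }
  expect_error(modularity_q(matrix(0, 4, 4), rep(1, 4)), "no edges")
})

test_that("disjoint cliques drive Q toward 1 as their number grows", {
  q_of_k_cliques <- function(k) {
    n <- 4 * k
    adj <- matrix(0, n, n)
    membership <- rep(seq_len(k), each = 4)
    for (c_ in seq_len(k)) {
      idx <- which(membership == c_)
      adj[idx, idx] <- 1
    }
    diag(adj) <- 0
    modularity_q(adj, membership)
  }
  qs <- vapply(c(2, 4, 8, 16), q_of_k_cliques, numeric(1))
  expect_true(all(diff(qs) > 0))
  expect_equal(qs, 1 - 1 / c(2, 4, 8, 16))  # closed form for equal cliques
})

test_that("detected partitions never score below the trivial partition", {
  for (s in 1:8) {
    adj <- random_adjacency(25, 0.12, seed = 70 + s)
    comp <- largest_component(adj)
    part <- detect_communities(adj, seed = s)
    expect_gte(attr(part, "q"), 0 - 1e-12)
  }
})

test_that("edgeless components give singleton communities with undefined Q", {
  # a component with nodes but no edges: every node its own community
  adj <- matrix(0, 4, 4)
  part <- detect_communities(adj, seed = 1)
  expect_equal(attr(part, "n_communities"), nrow(part))
  expect_true(is.na(attr(part, "q")))
  expect_error(detect_communities(matrix(0, 0, 0)), "empty graph")
  expect_error(modularity_q(matrix(0, 4, 4), rep(1, 4)), "no edges")
})

test_that("planted partitions are recovered at small scale", {
  hits <- vapply(1:10, function(s) {
    adj <- withr::with_seed(s, {
      n <- 60; blocks <- rep(1:3, each = 20)
      m <- matrix(rbinom(n * n, 1,
                         ifelse(outer(blocks, blocks, "==") , 0.5, 0.02)),
                  n, n)
      diag(m) <- 0
      m
    })
    part <- detect_communities(adj, seed = s)
    attr(part, "n_communities") == 3
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
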