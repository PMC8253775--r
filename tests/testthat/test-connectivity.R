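test_that("binarization follows the half-open bin convention", {
  empty <- spike_raster(tibble::tibble(neuron_id = integer(), time = double()),
                        3, 1)
  expect_true(all(binarize(empty, 0.05) == 0L))
  r <- spike_raster(tibble::tibble(neuron_id = c(1L, 2L, 2L),
                                   time = c(0.049, 0.12, 0.13)),
                    3, 1)
  b <- binarize(r, 0.05)
  expect_equal(b[1, 1], 1L)            # 0.049 falls in bin 0
  expect_equal(sum(b[2, ]), 1L)        # two onsets in one bin saturate to 1
  expect_equal(dim(b), c(3L, 20L))
})

test_that("the plug-in estimator equals the brute-force oracle", {
  set.seed(100)
  for (i in 1:100) {
    x <- rbinom(50, 1, runif(1, 0.1, 0.6))
    y <- rbinom(50, 1, runif(1, 0.1, 0.6))
    inst <- i %% 2 == 0
    expected <- te_bruteforce(x, y, k = 2, instant = inst)
    expect_lt(abs(gte_pair(x, y, k = 2, instant_feedback = inst) - expected),
              1e-12)
    m <- burstnet:::gte_matrix_cpp(rbind(x, y), 2L, inst)
    expect_lt(abs(m[1, 2] - expected), 1e-12)
    expect_lt(abs(m[2, 1] - te_bruteforce(y, x, k = 2, instant = inst)),
              1e-12)
  }
})

test_that("a deterministic one-bin copy is maximally asymmetric", {
  set.seed(5)
  x <- rbinom(30, 1, 0.4)
  y <- c(0L, x[-30])  # y_{t+1} = x_t
  expect_gt(gte_pair(x, y), 0)
  expect_equal(gte_pair(y, x), 0)
  expect_equal(gte_pair(x, y), te_bruteforce(x, y), tolerance = 1e-12)
})

test_that("independent noise scores at shuffled-bias level", {
  set.seed(6)
  x <- rbinom(5000, 1, 0.3)
  y <- rbinom(5000, 1, 0.2)
  te <- gte_pair(x, y)
  bias <- median(vapply(1:20, function(i)
    gte_pair(sample(x), y), numeric(1)))
  expect_lt(te, 5 * bias + 0.005)
})

test_that("gte is non-negative and zero under conditional independence", {
  set.seed(8)
  for (i in 1:25) {
    x <- rbinom(60, 1, runif(1, 0.2, 0.7))
    y <- rbinom(60, 1, runif(1, 0.2, 0.7))
    expect_gte(gte_pair(x, y), -1e-12)
  }
  # y a deterministic function of its own history only
  y <- rep(c(1L, 0L), 50)
  x <- rbinom(100, 1, 0.5)
  expect_equal(gte_pair(x, y), 0)
  expect_error(gte_pair(c(0L, 1L), c(1L, 0L)), "too short")
})

test_that("burst filter, subsampling and determinism of the matrix stage", {
  few <- gen_raster(30, 60, burst_model(background_rate = 0,
                                        burst_rate = 0.08,
                                        participation = 0.9), seed = 1)
  cat_few <- detect_bursts(compute_gna(few, 1, 20))
  expect_lt(nrow(cat_few), 10)
  expect_error(gte_matrix(few, catalog = cat_few, min_bursts = 10),
               "refused")
  r <- gen_raster(60, 120, burst_preset("ctr_like"), seed = 2)
  cat_r <- detect_bursts(compute_gna(r, 1, 20))
  en <- gte_matrix(r, catalog = cat_r, subsample = 40, seed = 9)
  expect_equal(nrow(en$scores), 40L)
  expect_true(all(en$ids %in% active_neurons(r)))
  en2 <- gte_matrix(r, catalog = cat_r, subsample = 40, seed = 9)
  expect_identical(en$scores, en2$scores)
  expect_identical(en$ids, en2$ids)
  # fewer active neurons than the subsample: all used, with a warning
  expect_warning(gte_matrix(r, catalog = cat_r, subsample = 340, seed = 1),
                 "using all")
})

test_that("matrix scores match pairwise scores on the same bins", {
  r <- gen_raster(8, 60, burst_preset("ctr_like"), seed = 3)
  cat_r <- detect_bursts(compute_gna(r, 1, 20))
  en <- suppressWarnings(gte_matrix(r, catalog = cat_r, min_bursts = 1,
                                    subsample = 8, seed = 1))
  bins <- binarize(r, 0.05)
  ids <- en$ids
  for (i in ids[c(1, 3)]) for (j in ids[c(2, length(ids))]) {
    if (i == j) next
    expect_lt(abs(en$scores[as.character(i), as.character(j)] -
                    gte_pair(bins[i, ], bins[j, ])), 1e-12)
  }
})

test_that("thresholding against the pooled score distribution", {
  m <- matrix(0.3, 5, 5)
  diag(m) <- 0
  expect_equal(sum(threshold_network(m, 1)), 0)  # all equal: no edges
  m2 <- m
  m2[2, 4] <- 3
  adj <- threshold_network(m2, 1)
  expect_equal(sum(adj), 1L)
  expect_equal(adj[2, 4], 1L)
  # monotone: larger n_sd keeps a subset
  set.seed(12)
  s <- matrix(abs(rnorm(400, 0.2, 0.1)), 20, 20)
  diag(s) <- 0
  a1 <- threshold_network(s, 1)
  a25 <- threshold_network(s, 2.5)
  expect_true(all(a25 <= a1))
  # fraction kept at 2.5 SD matches the empirical tail count
  off <- s[row(s) != col(s)]
  expected_frac <- mean(off > mean(off) + 2.5 * sd(off))
  expect_equal(sum(a25) / length(off), expected_frac)
})

test_that("degree distributions and CDFs match brute-force counting", {
  empty <- matrix(0, 5, 5)
  d0 <- degree_cdf(empty)
  expect_equal(d0$k, 0)
  expect_equal(d0$cdf, 1)
  n <- 6
  complete <- matrix(1, n, n) - diag(n)
  dc <- degree_cdf(complete)
  expect_equal(dc$k, 2 * (n - 1))
  expect_equal(dc$p, 1)
  for (s in 1:10) {
    adj <- random_adjacency(12, 0.3, seed = s)
    for (dir in c("total", "in", "out")) {
      got <- degree_cdf(adj, dir)
      ref <- degree_hist_bruteforce(adj, dir)
      expect_equal(got$k, ref$k)
      expect_equal(got$p, ref$p)
      expect_equal(got$cdf, cumsum(ref$p))
      expect_equal(max(got$cdf), 1)
      expect_true(all(diff(got$cdf) >= 0))
    }
  }
  pct <- degree_cdf(complete, "total", percent = TRUE)
  expect_equal(pct$k, 100)
})

test_that("KL divergence follows the formula and its guards", {
  expect_equal(kl_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(kl_divergence(c(0.8, 0.2), c(0.5, 0.5)),
               0.8 * log(1.6) + 0.2 * log(0.4))
  expect_equal(kl_divergence(c(0, 1), c(0.5, 0.5)), log(2))
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0)), "zero mass")
  set.seed(3)
  for (i in 1:30) {
    p <- runif(6); p <- p / sum(p)
    s <- runif(6) + 0.01; s <- s / sum(s)
    expect_gte(kl_divergence(p, s), 0)
  }
  d1 <- degree_cdf(random_adjacency(15, 0.2, 1))
  expect_equal(kl_divergence(d1, d1), 0)
  # disjoint-support degree distributions are undefined by the zero-mass rule
  d2 <- degree_cdf(random_adjacency(15, 0.9, 2))
  expect_error(kl_divergence(d1, d2), "zero mass")
})

test_that("the KS statistic equals the maximum ECDF gap", {
  expect_equal(compare_distributions_ks(1:10, 1:10)$statistic, 0)
  expect_equal(compare_distributions_ks(1:5, 11:15)$statistic, 1)
  set.seed(4)
  for (i in 1:10) {
    a <- rpois(40, 5)
    b <- rpois(35, 8)
    got <- compare_distributions_ks(a, b)
    expect_equal(got$statistic, ks_bruteforce(a, b), tolerance = 1e-12)
  }
})

test_that("causal motifs are directed correctly in most seeds", {
  wins <- vapply(1:40, function(s) {
    m <- gen_causal_motif(4000, 0.7, 1, seed = s)
    b <- binarize(m, attr(m, "bin"))
    gte_pair(b[1, ], b[2, ]) > gte_pair(b[2, ], b[1, ])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
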