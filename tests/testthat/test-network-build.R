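test_that("the default build has 300 neurons split 55/25/20", {
  net <- build_network(n = 300, seed = 1)
  g <- glance(net)
  expect_equal(g$n_neurons, 300L)
  expect_equal(g$n_excitatory, 165L)
  expect_equal(g$n_da, 75L)
  expect_equal(g$n_inhibitory, 60L)
  expect_true(all(net$neurons$x >= 0 & net$neurons$x <= 2800))
  expect_true(all(net$neurons$y >= 0 & net$neurons$y <= 2100))
  expect_true(all(net$edges$source != net$edges$target))  # no self-edges
})

test_that("population rounding holds for sizes that do not divide evenly", {
  net <- build_network(n = 101, seed = 2)
  tab <- table(net$neurons$type)
  expect_equal(sum(tab), 101)
  expect_equal(unname(tab[["da"]]), 25)          # 25.25 -> 25
  expect_equal(unname(tab[["excitatory"]]), 56)  # 55.55 -> 56 (largest remainder)
  expect_equal(unname(tab[["inhibitory"]]), 20)
})

test_that("zero-length axons yield zero edges", {
  net <- build_network(n = 20, seed = 3, axon_mean_length = 0)
  expect_equal(nrow(net$edges), 0L)
})

test_that("builds are reproducible bit-exactly under a fixed seed", {
  a <- build_network(n = 60, seed = 11)
  b <- build_network(n = 60, seed = 11)
  expect_identical(a$edges, b$edges)
  expect_identical(a$neurons, b$neurons)
  c_ <- build_network(n = 60, seed = 12)
  expect_false(identical(a$edges, c_$edges))
})

test_that("supplied ROI positions are subsampled and validated", {
  roi <- roi_table(50, seed = 1)
  net <- build_network(n = 30, seed = 4, positions = roi)
  expect_true(all(net$neurons$x %in% roi$x))
  expect_error(build_network(n = 80, seed = 4, positions = roi), "fewer")
})

test_that("the edge set matches brute-force segment-circle intersection", {
  net <- build_network(n = 20, seed = 7, alpha = 1)  # alpha 1: geometry only
  got <- net$edges[order(net$edges$source, net$edges$target), ]
  expected <- list()
  for (i in 1:20) {
    pts <- net$axons[[i]]
    for (j in setdiff(1:20, i)) {
      c_ <- c(net$neurons$x[j], net$neurons$y[j])
      r_ <- net$neurons$dendrite_radius[j]
      dmin <- Inf
      if (nrow(pts) >= 2) {
        for (s in seq_len(nrow(pts) - 1)) {
          a <- pts[s, ]; b <- pts[s + 1, ]
          d <- b - a
          tt <- sum((c_ - a) * d) / max(sum(d * d), 1e-300)
          tt <- min(max(tt, 0), 1)
          dmin <- min(dmin, sqrt(sum((a + tt * d - c_)^2)))
        }
      }
      if (dmin <= r_) expected[[length(expected) + 1]] <- c(i, j)
    }
  }
  exp_mat <- do.call(rbind, expected)
  expect_equal(nrow(got), nrow(exp_mat))
  expect_equal(unname(as.matrix(got[, c("source", "target")])), exp_mat)
})

test_that("axons are clipped at the field boundary", {
  net <- build_network(n = 40, seed = 9, axon_mean_length = 4000)
  for (ax in net$axons) {
    expect_true(all(ax[, 1] >= -1e-9 & ax[, 1] <= 2800 + 1e-9))
    expect_true(all(ax[, 2] >= -1e-9 & ax[, 2] <= 2100 + 1e-9))
  }
})

test_that("pruning with fraction 0 leaves the network unchanged", {
  net <- build_network(n = 50, seed = 5)
  p0 <- prune(net, 0, seed = 1)
  expect_identical(p0$edges, net$edges)
  expect_equal(nrow(p0$pruning), 0L)
})

test_that("random-edge pruning removes the exact target count", {
  net <- build_network(n = 100, seed = 6)
  da <- net$neurons$id[net$neurons$type == "da"]
  out_before <- table(factor(net$edges$source, levels = 1:100))
  pr <- prune(net, 1, mode = "random_edge", target_loss = 0.8, seed = 2)
  for (i in seq_len(nrow(pr$pruning))) {
    v <- pr$pruning$neuron[i]
    m <- pr$pruning$n_edges[i]
    expect_equal(pr$pruning$n_removed[i], round(0.8 * m))
  }
  expect_setequal(pr$pruning$neuron, da)
})

test_that("pruning touches only edges incident to selected DA neurons", {
  net <- build_network(n = 120, seed = 8)
  for (mode in c("axon_shorten", "dendrite_shrink", "random_edge")) {
    pr <- prune(net, 0.5, mode = mode, seed = 3)
    removed <- dplyr::anti_join(net$edges, pr$edges,
                                by = c("source", "target"))
    sel <- pr$pruning$neuron
    if (mode == "dendrite_shrink") {
      expect_true(all(removed$target %in% sel))
    } else {
      expect_true(all(removed$source %in% sel))
    }
    expect_lte(nrow(pr$edges), nrow(net$edges))
  }
  # edge count non-increasing in the pruned fraction
  counts <- vapply(c(0, 0.2, 0.5, 1), function(f)
    nrow(prune(net, f, seed = 4)$edges), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("double pruning is refused", {
  net <- build_network(n = 40, seed = 10)
  pr <- prune(net, 0.2, seed = 1)
  expect_error(prune(pr, 0.2, seed = 1), "already pruned")
})

test_that("axon-shorten calibration approaches the 80% target loss", {
  losses <- c()
  for (s in 1:4) {
    net <- build_network(n = 300, seed = 20 + s)
    pr <- prune(net, 0.3, mode = "axon_shorten", target_loss = 0.8,
                seed = 30 + s)
    losses <- c(losses, pr$pruning$realized_loss)
  }
  losses <- losses[!is.na(losses)]
  expect_gte(length(losses), 50)
  expect_lt(abs(mean(losses) - 0.8), 0.10)
  # truncated axons really lose the removed targets
  net <- build_network(n = 100, seed = 44)
  pr <- prune(net, 1, mode = "axon_shorten", target_loss = 0.8, seed = 45)
  shortened <- pr$pruning$neuron[pr$pruning$n_removed > 0]
  expect_true(all(pr$neurons$axon_length[shortened] <
                    net$neurons$axon_length[shortened]))
})
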