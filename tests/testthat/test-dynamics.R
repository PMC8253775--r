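test_that("average activity is events per neuron per minute", {
  empty <- spike_raster(tibble::tibble(neuron_id = integer(), time = double()),
                        10, 900)
  expect_equal(average_activity(empty), 0)
  ev <- withr::with_seed(1, tibble::tibble(
    neuron_id = sample(1:10, 150, replace = TRUE),
    time = sort(runif(150, 0, 900))))
  ev <- dplyr::distinct(ev)
  r <- spike_raster(ev, 10, 900)
  expect_equal(average_activity(r), nrow(ev) / 10 / 15)
  doubled <- spike_raster(dplyr::bind_rows(ev, dplyr::mutate(ev, time = time + 0.01)),
                          10, 900)
  expect_equal(average_activity(doubled), 2 * average_activity(r))
})

test_that("GNA spans [0, 1] with the documented extremes", {
  r <- full_sync_raster(25, 30)
  g <- compute_gna(r, window = 1, rate = 20)
  expect_equal(max(g$gna), 1)           # full-network activation
  expect_equal(min(g$gna), 0)           # silent windows
  expect_true(all(g$gna >= 0 & g$gna <= 1))
})

test_that("a neuron firing twice in one window is counted once", {
  r <- spike_raster(tibble::tibble(neuron_id = c(1L, 1L, 2L),
                                   time = c(0.2, 0.6, 5)),
                    n_neurons = 2, duration = 10)
  g <- compute_gna(r, window = 1, rate = 20)
  expect_equal(max(g$gna), 0.5)  # never both neurons in one window
})

test_that("GNA normalizes by active neurons and errors when none exist", {
  r <- spike_raster(tibble::tibble(neuron_id = c(1L, 2L), time = c(0.1, 0.5)),
                    n_neurons = 50, duration = 10)  # 48 silent neurons
  g <- compute_gna(r, window = 1, rate = 20)
  expect_equal(max(g$gna), 1)  # 2 active of 2 active
  empty <- spike_raster(tibble::tibble(neuron_id = integer(),
                                       time = double()), 50, 10)
  expect_error(compute_gna(empty), "no active neurons")
})

test_that("a flat GNA series has no bursts and its own background", {
  r <- full_sync_raster()
  g <- compute_gna(r, 1, 20)
  g$gna <- rep(0.05, nrow(g))
  cat0 <- detect_bursts(g)
  expect_equal(nrow(cat0), 0L)
  expect_equal(attr(cat0, "background"), 0.05)
})

test_that("injected peaks over a noisy background are recovered exactly", {
  set.seed(7)
  n <- 2000
  # bounded background fluctuations (uniform band stays inside mean + 2 SD),
  # so the iterative threshold separates background from the injected peaks
  base <- runif(n, 0.04, 0.06)
  peak_at <- c(200, 600, 1000, 1400, 1800)
  for (p in peak_at) base[p] <- 0.4 + runif(1, 0, 0.2)
  g <- structure(
    tibble::tibble(time = (seq_len(n) - 1) / 20, gna = base),
    window = 1, rate = 20, n_active = 25,
    class = c("gna_series", class(tibble::tibble())))
  cat5 <- detect_bursts(g, k_sd = 2)
  expect_equal(nrow(cat5), 5L)
  expect_equal(sort(cat5$time), (peak_at - 1) / 20)
  expect_lt(attr(cat5, "background"), 0.06)
})

test_that("the control reference pools peak amplitudes", {
  mk <- function(amps) {
    out <- tibble::tibble(time = seq_along(amps), amplitude = amps,
                          extreme = NA)
    structure(out, background = 0.05, background_sd = 0.01, threshold = 0.07,
              window = 1, class = c("burst_catalog", class(out)))
  }
  ref <- build_reference(mk(c(0.2, 0.4)))
  expect_equal(ref$a_ctr, 0.3)
  expect_equal(ref$sd_ctr, sd(c(0.2, 0.4)))
  same <- build_reference(mk(c(0.3, 0.3, 0.3)))
  expect_equal(same$sd_ctr, 0)
  # pooling is order-invariant
  ref_a <- build_reference(list(mk(c(0.1, 0.2)), mk(c(0.3, 0.5))))
  ref_b <- build_reference(list(mk(c(0.5, 0.3)), mk(c(0.2, 0.1))))
  expect_equal(ref_a$a_ctr, ref_b$a_ctr)
  expect_equal(ref_a$sd_ctr, ref_b$sd_ctr)
  # extreme ratio arithmetic: {A+SD, A+3SD} -> one of two above A+2SD
  cat2 <- mk(c(ref$a_ctr + ref$sd_ctr, ref$a_ctr + 3 * ref$sd_ctr))
  expect_equal(extreme_ratio(cat2, ref), 0.5)
  expect_equal(extreme_ratio(mk(c(0.05, 0.1)), ref), 0)
  expect_equal(extreme_ratio(mk(c(5, 6)), ref), 1)
  expect_error(extreme_ratio(mk(numeric(0)), ref), "no burst peaks")
  expect_error(build_reference(mk(numeric(0))), "no burst peaks")
})

test_that("the extreme ratio is monotone under amplitude upscaling", {
  set.seed(9)
  mk <- function(amps) {
    out <- tibble::tibble(time = seq_along(amps), amplitude = amps,
                          extreme = NA)
    structure(out, background = 0.05, background_sd = 0.01, threshold = 0.07,
              window = 1, class = c("burst_catalog", class(out)))
  }
  ref <- build_reference(mk(runif(50, 0.1, 0.4)))
  amps <- runif(30, 0.1, 0.6)
  ratios <- vapply(c(1, 1.2, 1.5, 2, 3),
                   function(s) extreme_ratio(mk(s * amps), ref), numeric(1))
  expect_true(all(diff(ratios) >= 0))
})

test_that("pd-like recordings show more extreme events than control ones", {
  refs <- lapply(1:5, function(s)
    detect_bursts(compute_gna(gen_raster(400, 600, burst_preset("ctr_like"),
                                         seed = s), 1, 20)))
  ref <- build_reference(refs)
  ctr_ree <- vapply(refs, extreme_ratio, numeric(1), reference = ref)
  pd_ree <- vapply(6:10, function(s) {
    cat_p <- detect_bursts(compute_gna(gen_raster(400, 600,
                                                  burst_preset("pd_like"),
                                                  seed = s), 1, 20))
    extreme_ratio(cat_p, ref)
  }, numeric(1))
  expect_gt(mean(pd_ree), mean(ctr_ree) + 0.5)
  expect_gt(mean(pd_ree), 0.9)
  expect_lt(mean(ctr_ree), 0.2)
})
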