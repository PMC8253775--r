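test_that("null model produces an empty raster", {
  m <- burst_model(background_rate = 0, burst_rate = 0)
  r <- gen_raster(20, 100, m, seed = 1)
  expect_equal(nrow(r$events), 0L)
})

test_that("forced full synchrony puts every neuron in each burst window", {
  m <- burst_model(background_rate = 0, burst_rate = 0.05,
                   participation = 1, jitter_sd = 0)
  r <- gen_raster(30, 300, m, seed = 4)
  bt <- attr(r, "burst_times")
  expect_gt(length(bt), 0)
  for (t in bt) {
    inside <- r$events$neuron_id[r$events$time >= t - 1e-9 &
                                   r$events$time <= t + 1e-9]
    expect_setequal(inside, 1:30)
  }
  expect_equal(max(compute_gna(r, 1, 20)$gna), 1)
})

test_that("background event counts match the Poisson mean over 100 seeds", {
  rate <- 0.1; dur <- 900; n <- 50
  m <- burst_model(background_rate = rate, burst_rate = 0)
  per_neuron <- vapply(1:100, function(s) {
    nrow(gen_raster(n, dur, m, seed = s)$events) / n
  }, numeric(1))
  expected <- rate * dur                     # 90
  se <- sqrt(expected / (n * 100))           # SE of the grand mean
  expect_lt(abs(mean(per_neuron) - expected), 3 * se)
})

test_that("generated rasters satisfy the raster invariants for random models", {
  for (s in 1:20) {
    pars <- withr::with_seed(1000 + s, list(
      n = sample(5:80, 1), dur = runif(1, 10, 120),
      bg = runif(1, 0, 0.3), br = runif(1, 0, 0.2),
      p = sort(runif(2)), jit = runif(1, 0, 0.2),
      g = sample(1:6, 1)))
    r <- gen_raster(pars$n, pars$dur,
                    burst_model(pars$bg, pars$br, pars$p, pars$jit,
                                n_assemblies = pars$g),
                    seed = s)
    ev <- r$events
    expect_true(all(ev$time >= 0 & ev$time < r$duration))
    expect_true(all(ev$neuron_id >= 1 & ev$neuron_id <= r$n_neurons))
    by_n <- split(ev$time, ev$neuron_id)
    expect_true(all(vapply(by_n, function(x) all(diff(x) > 0), logical(1))))
    # reproducibility under the same seed
    r2 <- gen_raster(pars$n, pars$dur,
                     burst_model(pars$bg, pars$br, pars$p, pars$jit,
                                 n_assemblies = pars$g),
                     seed = s)
    expect_identical(r$events, r2$events)
  }
})

test_that("fluorescence of a silent neuron is the flat baseline", {
  r <- spike_raster(tibble::tibble(neuron_id = integer(), time = double()),
                    n_neurons = 3, duration = 10)
  k <- calcium_kernel(noise_sd = 0)
  rec <- spikes_to_fluorescence(r, k, rate = 20, seed = 1)
  expect_true(all(rec$traces == k$f0))
})

test_that("a single transient peaks at the closed-form kernel maximum", {
  r <- spike_raster(tibble::tibble(neuron_id = 1L, time = 1), 1, 20)
  k <- calcium_kernel(amplitude = 1.4, tau_rise = 0.05, tau_decay = 0.8,
                      f0 = 100, noise_sd = 0)
  rec <- spikes_to_fluorescence(r, k, rate = 1000, seed = 1)
  peak_dff <- (max(rec$traces) - k$f0) / k$f0
  tr <- k$tau_rise; td <- k$tau_decay
  tstar <- tr * log(1 + td / tr)
  analytic <- k$amplitude * (1 - exp(-tstar / tr)) * exp(-tstar / td)
  expect_equal(peak_dff, analytic, tolerance = 1e-4)  # frame-grid resolution
})

test_that("a frame at twice the baseline gives 100% DFF downstream", {
  tr <- matrix(100, 200, 1)
  tr[100, 1] <- 200  # F = 2 F0
  rec <- fluorescence_recording(tr, 20)
  dff <- compute_dff(rec, baseline_percentile = 10, baseline_window = Inf)
  expect_equal(max(dff$dff), 100)
})

test_that("kernel invariants are enforced", {
  expect_error(calcium_kernel(tau_rise = 0.8, tau_decay = 0.5), "tau_decay")
  expect_error(calcium_kernel(f0 = 0), "f0")
  expect_error(calcium_kernel(noise_sd = -1), "noise_sd")
  expect_error(burst_model(participation = c(0.5, 1.5)), "participation")
})

test_that("causal motifs behave as specified at the p_drive extremes", {
  # p_drive = 1, delay 1, no noise: Y is X shifted by one bin
  m <- gen_causal_motif(400, 1, 1, seed = 3, p_noise = 0)
  b <- binarize(m, attr(m, "bin"))
  expect_equal(b[2, -1], b[1, -ncol(b)])
  # p_drive = 0: X and Y independent; TE roughly symmetric
  m0 <- gen_causal_motif(20000, 0, 1, seed = 3, p_noise = 0.2)
  b0 <- binarize(m0, attr(m0, "bin"))
  te_xy <- gte_pair(b0[1, ], b0[2, ])
  te_yx <- gte_pair(b0[2, ], b0[1, ])
  expect_lt(abs(te_xy - te_yx), 0.005)  # both are plug-in bias-level
  expect_lt(te_xy, 0.01)
})
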