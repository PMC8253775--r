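# Shared fixtures for round-trip and matching tests.

# Peak DFF (fraction of f0) of a unit-amplitude calcium kernel.
kernel_gain <- function() {
  k <- calcium_kernel(amplitude = 1, noise_sd = 0)
  tstar <- k$tau_rise * log(1 + k$tau_decay / k$tau_rise)
  (1 - exp(-tstar / k$tau_rise)) * exp(-tstar / k$tau_decay)
}

# Greedy per-neuron matching of detected onsets to ground truth within a
# time tolerance; reports hit and false-positive rates.
match_onsets <- function(truth, detected, tol) {
  n_true <- nrow(truth$events)
  n_det <- nrow(detected$events)
  hits <- 0L
  matched_det <- 0L
  for (j in seq_len(truth$n_neurons)) {
    tt <- truth$events$time[truth$events$neuron_id == j]
    dd <- detected$events$time[detected$events$neuron_id == j]
    used <- rep(FALSE, length(dd))
    for (t in tt) {
      ok <- which(!used & abs(dd - t) <= tol)
      if (length(ok) > 0) {
        used[ok[1]] <- TRUE
        hits <- hits + 1L
      }
    }
    matched_det <- matched_det + sum(used)
  }
  list(hit_rate = if (n_true > 0) hits / n_true else NA_real_,
       false_positive_rate = if (n_det > 0) 1 - matched_det / n_det
                             else 0)
}

# Raster with every neuron firing once inside the first second.
full_sync_raster <- function(n = 25, duration = 30) {
  spike_raster(tibble::tibble(neuron_id = seq_len(n),
                              time = seq(0.1, 0.9, length.out = n)),
               n_neurons = n, duration = duration)
}
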