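# Ground-truth generators. Rasters are a union of per-neuron homogeneous
# Poisson background firing and network bursts occurring at Poisson times,
# each recruiting a random subset of neurons (without replacement) with
# Gaussian onset jitter. Fluorescence is synthesized by convolving onsets
# with a difference-of-exponentials calcium kernel plus white noise.

#' Network burst model
#'
#' Parameters of the synthetic raster generator: per-neuron background rate,
#' burst occurrence rate, per-burst participation (a fixed fraction or a
#' range sampled uniformly per burst) and Gaussian onset jitter.
#'
#' @param background_rate Background firing rate, spikes/s per neuron.
#' @param burst_rate Network-burst rate, bursts/s.
#' @param participation Fraction of neurons recruited per burst; either a
#'   single value or a length-2 range `c(lo, hi)` sampled uniformly per burst.
#' @param jitter_sd SD of per-neuron onset jitter within a burst, seconds.
#' @param n_assemblies Number of recruitment assemblies. With 1 (default)
#'   every burst recruits uniformly from the whole network; with `G > 1`
#'   neurons are split into `G` fixed assemblies and each burst recruits
#'   preferentially from one of them, emulating the microcircuit
#'   coactivations that give healthy networks their functional community
#'   structure.
#' @param assembly_weight Relative recruitment weight of non-members of the
#'   burst's assembly (members have weight 1).
#' @return A `burst_model` list.
#' @seealso [burst_preset()] for the stock control-like and PD-like settings.
#' @export
burst_model <- function(background_rate = 0.05, burst_rate = 0.08,
                        participation = c(0.1, 0.4), jitter_sd = 0.05,
                        n_assemblies = 1, assembly_weight = 0.15) {
  if (background_rate < 0 || burst_rate < 0 || jitter_sd < 0)
    abort("rates and jitter must be non-negative")
  if (length(participation) == 1) participation <- rep(participation, 2)
  if (length(participation) != 2 || any(participation < 0) ||
      any(participation > 1) || participation[1] > participation[2])
    abort("`participation` must be a fraction or increasing range in [0, 1]")
  if (n_assemblies < 1 || n_assemblies != round(n_assemblies))
    abort("`n_assemblies` must be a positive integer")
  if (assembly_weight <= 0 || assembly_weight > 1)
    abort("`assembly_weight` must lie in (0, 1]")
  structure(list(background_rate = background_rate, burst_rate = burst_rate,
                 participation = participation, jitter_sd = jitter_sd,
                 n_assemblies = as.integer(n_assemblies),
                 assembly_weight = assembly_weight),
            class = "burst_model")
}

#' Stock burst-model presets
#'
#' `"ctr_like"` emulates a healthy culture: frequent synchronous activations
#' of moderate size (10-40% of the network) on top of background firing.
#' `"pd_like"` emulates the two-state pathological dynamics: sparse
#' whole-network synchronous events (80-100% participation) separated by
#' quiescent intervals — between events the network is silent, the limiting
#' case of the strongly depressed background that makes nearly every
#' detected burst an extreme event.
#'
#' @param preset `"ctr_like"` or `"pd_like"`.
#' @return A [burst_model()].
#' @export
burst_preset <- function(preset = c("ctr_like", "pd_like")) {
  preset <- match.arg(preset)
  switch(preset,
    ctr_like = burst_model(background_rate = 0.05, burst_rate = 0.08,
                           participation = c(0.10, 0.40), jitter_sd = 0.05,
                           n_assemblies = 8),
    pd_like = burst_model(background_rate = 0, burst_rate = 0.02,
                          participation = c(0.80, 1.00), jitter_sd = 0.05)
  )
}

#' Calcium fluorescence kernel
#'
#' Forward model of a single calcium transient: a difference of exponentials
#' with fast rise and slow decay riding on a baseline,
#' `F(t) = F0 * (1 + sum_s A (1 - exp(-(t - t_s)/tau_rise))
#' exp(-(t - t_s)/tau_decay))` plus Gaussian noise of SD `noise_sd` (in the
#' same arbitrary units as `f0`).
#'
#' @param amplitude Transient amplitude `A` in DFF units (1 = 100% DFF before
#'   kernel normalization).
#' @param tau_rise,tau_decay Rise and decay time constants, seconds
#'   (`tau_decay > tau_rise > 0`).
#' @param f0 Baseline fluorescence, arbitrary units.
#' @param noise_sd Additive Gaussian noise SD, arbitrary units.
#' @return A `calcium_kernel` list.
#' @export
calcium_kernel <- function(amplitude = 1, tau_rise = 0.02, tau_decay = 0.8,
                           f0 = 100, noise_sd = 2) {
  if (!(tau_decay > tau_rise && tau_rise > 0))
    abort("need tau_decay > tau_rise > 0")
  if (f0 <= 0) abort("`f0` must be positive")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  structure(list(amplitude = amplitude, tau_rise = tau_rise,
                 tau_decay = tau_decay, f0 = f0, noise_sd = noise_sd),
            class = "calcium_kernel")
}

# Peak value (over t) of A*(1 - exp(-t/tr))*exp(-t/td), attained at
# t* = tr * log(1 + td/tr).
kernel_peak <- function(kernel) {
  tr <- kernel$tau_rise; td <- kernel$tau_decay
  tstar <- tr * log(1 + td / tr)
  kernel$amplitude * (1 - exp(-tstar / tr)) * exp(-tstar / td)
}

#' Generate a synthetic spike raster
#'
#' Background spikes are homogeneous Poisson per neuron; bursts occur at
#' Poisson times, each recruiting `ceiling(p * n)` distinct neurons (sampled
#' without replacement, participation `p` drawn from the model's range) whose
#' onsets are the burst time plus Gaussian jitter, clipped to the recording.
#'
#' @param n Number of neurons.
#' @param duration Recording length, seconds.
#' @param model A [burst_model()].
#' @param seed RNG seed.
#' @param labels Optional per-neuron labels passed to the raster.
#' @return A [spike_raster()]; attribute `"burst_times"` records the
#'   ground-truth burst onset times.
#' @export
gen_raster <- function(n, duration, model = burst_preset("ctr_like"),
                       seed = 1L, labels = NULL) {
  stopifnot(inherits(model, "burst_model"), n >= 1, duration > 0)
  with_seed(seed, {
    # background
    n_bg <- rpois(n, model$background_rate * duration)
    bg <- tibble(
      neuron_id = rep(seq_len(n), n_bg),
      time = runif(sum(n_bg), 0, duration)
    )
    # bursts
    n_burst <- rpois(1, model$burst_rate * duration)
    burst_times <- sort(runif(n_burst, 0, duration))
    ev <- vector("list", n_burst)
    assembly <- (seq_len(n) - 1L) %% model$n_assemblies + 1L
    for (b in seq_len(n_burst)) {
      p <- runif(1, model$participation[1], model$participation[2])
      k <- min(n, ceiling(p * n))
      if (k == 0) next
      if (model$n_assemblies > 1) {
        g <- sample.int(model$n_assemblies, 1)
        w <- ifelse(assembly == g, 1, model$assembly_weight)
        members <- sample.int(n, k, prob = w)
      } else {
        members <- sample.int(n, k)
      }
      t_b <- burst_times[b] + rnorm(k, 0, model$jitter_sd)
      keep <- t_b >= 0 & t_b < duration
      ev[[b]] <- tibble(neuron_id = members[keep], time = t_b[keep])
    }
    events <- dplyr::bind_rows(bg, ev)
    out <- spike_raster(events, n, duration, labels = labels)
    attr(out, "burst_times") <- burst_times
    out
  })
}

#' Synthesize calcium fluorescence from a spike raster
#'
#' Inverse of the spike-extraction stage: each onset adds one calcium kernel
#' transient to that neuron's trace, sampled on the frame grid of the given
#' rate, with independent Gaussian noise per frame.
#'
#' @param raster A [spike_raster()].
#' @param kernel A [calcium_kernel()].
#' @param rate Sampling rate, Hz.
#' @param seed RNG seed (noise only).
#' @param roi Optional ROI table for the recording geometry.
#' @return A [fluorescence_recording()].
#' @export
spikes_to_fluorescence <- function(raster, kernel = calcium_kernel(),
                                   rate = 20, seed = 1L, roi = NULL) {
  stopifnot(inherits(raster, "spike_raster"), inherits(kernel, "calcium_kernel"),
            rate > 0)
  n_frames <- round(raster$duration * rate)
  t_grid <- (seq_len(n_frames) - 1L) / rate
  traces <- matrix(0, n_frames, raster$n_neurons)
  ev <- raster$events
  for (i in seq_len(nrow(ev))) {
    ts <- ev$time[i]
    j <- ev$neuron_id[i]
    rel <- t_grid - ts
    idx <- rel >= 0
    traces[idx, j] <- traces[idx, j] +
      kernel$amplitude * (1 - exp(-rel[idx] / kernel$tau_rise)) *
      exp(-rel[idx] / kernel$tau_decay)
  }
  traces <- kernel$f0 * (1 + traces)
  if (kernel$noise_sd > 0) {
    traces <- traces + with_seed(seed,
      matrix(rnorm(length(traces), 0, kernel$noise_sd), nrow = n_frames))
  }
  if (is.null(roi)) roi <- roi_table(raster$n_neurons, seed = seed)
  fluorescence_recording(traces, rate, roi)
}

#' Two-node causal motif
#'
#' Oracle fixture for directed-connectivity inference: X fires Bernoulli per
#' bin; Y copies X with probability `p_drive` at delay `delay_bins` and
#' additionally fires independent noise spikes. The ground-truth direction is
#' X -> Y.
#'
#' @param n_bins Number of time bins.
#' @param p_drive Copy probability (0, 1].
#' @param delay_bins Copy delay in bins, 0 or 1.
#' @param seed RNG seed.
#' @param p_x Bernoulli rate of X per bin.
#' @param p_noise Independent firing rate of Y per bin.
#' @param bin Bin width in seconds (sets the raster time base).
#' @return A [spike_raster()] with neurons 1 = X, 2 = Y; attribute
#'   `"ground_truth"` is `c(source = 1, target = 2)`.
#' @export
gen_causal_motif <- function(n_bins, p_drive, delay_bins = 1L, seed = 1L,
                             p_x = 0.2, p_noise = 0.05, bin = 0.05) {
  if (p_drive < 0 || p_drive > 1) abort("`p_drive` must lie in [0, 1]")
  if (!delay_bins %in% c(0L, 1L)) abort("`delay_bins` must be 0 or 1")
  with_seed(seed, {
    x <- rbinom(n_bins, 1, p_x)
    copied <- rbinom(n_bins, 1, p_drive) * x
    y_drive <- integer(n_bins)
    if (delay_bins == 0L) {
      y_drive <- copied
    } else {
      y_drive[-1] <- copied[-n_bins]
    }
    y <- pmin(1L, y_drive + rbinom(n_bins, 1, p_noise))
    events <- dplyr::bind_rows(
      tibble(neuron_id = 1L, time = (which(x == 1) - 1) * bin),
      tibble(neuron_id = 2L, time = (which(y == 1) - 1) * bin)
    )
    out <- spike_raster(events, 2L, n_bins * bin)
    attr(out, "ground_truth") <- c(source = 1L, target = 2L)
    attr(out, "bin") <- bin
    out
  })
}
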