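# In silico dynamics: a reduced single-compartment Hodgkin-Huxley network
# with spike-triggered slow K adaptation (burst termination), exponential
# synapses routed through the structural adjacency (DA neurons synapse as
# excitatory), and independent Poisson trains of excitatory presynaptic
# potentials per neuron. Simulated rasters feed the analysis chain directly.

#' Neuron and synapse model parameters
#'
#' Defaults are tuned so that a default control network (see
#' [build_network()]) shows intense background activity combined with
#' recurrent coordinated bursting episodes. Membrane parameters are in
#' mV/ms/uF/mS per cm^2 conventions; times are seconds at the interface.
#'
#' @param cm Membrane capacitance, uF/cm^2.
#' @param g_leak,e_leak Leak conductance (mS/cm^2) and reversal (mV).
#' @param g_na,e_na,g_k,e_k Na/K maximal conductances and reversals.
#' @param phi Gating temperature factor.
#' @param adapt_increment Slow-K adaptation conductance added per spike,
#'   mS/cm^2.
#' @param tau_adapt Adaptation decay time constant, seconds.
#' @param tau_exc,tau_inh Synaptic conductance decay constants, seconds.
#' @param e_exc,e_inh Synaptic reversals, mV.
#' @param w_ee,w_ei Excitatory conductance increment per presynaptic spike
#'   onto excitatory/DA (`w_ee`) and inhibitory (`w_ei`) targets, mS/cm^2.
#' @param w_ie,w_ii Inhibitory increments onto excitatory/DA and inhibitory
#'   targets.
#' @param w_ext Conductance increment per external Poisson event, mS/cm^2.
#' @param nu_ext External Poisson rate per neuron, Hz.
#' @param v_thresh Spike-detection threshold, mV (upward crossing).
#' @param refractory Minimum inter-spike interval for detection, seconds.
#' @param tau_adapt_cv Per-neuron lognormal spread (CV) of the adaptation
#'   time constant; staggers burst-recovery clocks so that collective
#'   events recruit only the recovered fraction of the network.
#' @param e_leak_sd Per-neuron Gaussian spread of the leak reversal, mV
#'   (excitability heterogeneity).
#' @param dt Integration step, seconds (must be <= 1e-4).
#' @return A `neuron_params` list.
#' @export
neuron_params <- function(cm = 1, g_leak = 0.1, e_leak = -65,
                          g_na = 35, e_na = 55, g_k = 9, e_k = -90,
                          phi = 5,
                          adapt_increment = 2.5, tau_adapt = 5,
                          tau_exc = 0.005, tau_inh = 0.010,
                          e_exc = 0, e_inh = -80,
                          w_ee = 0.3, w_ei = 0.3,
                          w_ie = 0.2, w_ii = 0.05,
                          w_ext = 0.2, nu_ext = 2,
                          v_thresh = 0, refractory = 0.003,
                          tau_adapt_cv = 0.4, e_leak_sd = 1.5,
                          dt = 1e-4) {
  p <- as.list(environment())
  if (any(unlist(p[c("cm", "g_leak", "g_na", "g_k", "tau_adapt", "tau_exc",
                     "tau_inh", "refractory", "dt")]) <= 0))
    abort("capacitance, conductances and time constants must be positive")
  if (any(unlist(p[c("adapt_increment", "w_ee", "w_ei", "w_ie", "w_ii",
                     "w_ext", "nu_ext")]) < 0))
    abort("synaptic increments and rates must be non-negative")
  if (p$dt > 1e-4 + 1e-12) abort("`dt` must be <= 1e-4 s (0.1 ms)")
  structure(p, class = "neuron_params")
}

#' Simulate network dynamics
#'
#' Integrates the conductance-based model on the structural network with a
#' fixed-step Heun (RK2) scheme and records upward threshold crossings as
#' spikes. The returned raster carries the neurons' type labels so the
#' analysis chain can split subpopulations.
#'
#' @param network A `spatial_network` from [build_network()].
#' @param params A [neuron_params()] list.
#' @param duration Simulated time, seconds.
#' @param seed RNG seed (initial conditions and Poisson drive).
#' @param warmup Discarded initial transient, seconds. Neurons start from
#'   near-identical rest states, so the first event is an artificially
#'   synchronized whole-network burst; the warm-up lets adaptation and
#'   background activity settle before recording starts.
#' @return A [spike_raster()] with labels `excitatory`/`da`/`inhibitory`.
#' @export
simulate_network <- function(network, params = neuron_params(),
                             duration = 120, seed = 1L, warmup = 15) {
  stopifnot(inherits(network, "spatial_network"),
            inherits(params, "neuron_params"), duration > 0, warmup >= 0)
  type_code <- c(excitatory = 0L, da = 1L, inhibitory = 2L)
  types <- type_code[network$neurons$type]
  res <- with_seed(seed, simulate_hh_cpp(
    as.integer(network$edges$source), as.integer(network$edges$target),
    as.integer(types), unclass(params), duration + warmup,
    params$dt * 1000))
  events <- tibble(neuron_id = res$neuron, time = res$time - warmup)
  events <- events[events$time >= 0 & events$time < duration, , drop = FALSE]
  out <- spike_raster(events, nrow(network$neurons), duration,
                      labels = network$neurons$type)
  attr(out, "v_trace") <- res$v_trace
  attr(out, "v_dt") <- res$v_dt
  out
}

#' Pruning experiment matrix
#'
#' For each pruning fraction and realization: build a structural network,
#' prune the DA subpopulation, simulate, and run the dynamics analysis
#' (GNA, burst catalog). The non-pruned condition's pooled burst amplitudes
#' define the extreme-event reference, so its own ratio of extreme events is
#' near 0 by construction. Optionally infers effective connectivity and
#' degree CDFs per run.
#'
#' @param pruning_fractions Fractions of DA neurons pruned per condition.
#' @param realizations Independent build/simulate repeats per condition.
#' @param n Network size.
#' @param duration Simulated seconds per run.
#' @param mode Pruning mode (see [prune()]).
#' @param target_loss Target per-neuron connection loss.
#' @param params A [neuron_params()] list.
#' @param rate Analysis frame rate (Hz) for GNA/binarization.
#' @param connectivity Also compute GTE networks and degree CDFs.
#' @param min_bursts Burst filter for connectivity inference.
#' @param seed Master seed; per-run seeds are derived from it.
#' @return A list with `summary` (one row per condition x realization:
#'   `fraction`, `realization`, `mean_activity`, `n_bursts`, `background`,
#'   `r_ee`, and with connectivity `n_edges`, `density`, `n_communities`,
#'   `q`), `reference` (the control [build_reference()] object), `catalogs`,
#'   `rasters`, and (optionally) `cdfs` (per-run `degree_distribution`s).
#' @export
run_experiment <- function(pruning_fractions = c(0, 0.1, 0.3, 0.5),
                           realizations = 4, n = 300, duration = 120,
                           mode = "axon_shorten", target_loss = 0.8,
                           params = neuron_params(), rate = 20,
                           connectivity = FALSE, min_bursts = 10,
                           seed = 1L) {
  stopifnot(0 %in% pruning_fractions)
  conds <- length(pruning_fractions)
  rasters <- catalogs <- vector("list", conds * realizations)
  idx <- function(ci, r) (ci - 1L) * realizations + r
  for (r in seq_len(realizations)) {
    build_seed <- seed + 1013L * r
    net0 <- build_network(n = n, seed = build_seed)
    for (ci in seq_along(pruning_fractions)) {
      f <- pruning_fractions[ci]
      net <- if (f > 0)
        prune(net0, f, mode = mode, target_loss = target_loss,
              seed = build_seed + ci) else net0
      ras <- simulate_network(net, params, duration,
                              seed = seed + 131L * r + 7L * ci)
      rasters[[idx(ci, r)]] <- ras
      catalogs[[idx(ci, r)]] <-
        detect_bursts(compute_gna(ras, window = 1, rate = rate))
    }
  }
  ctrl_ci <- which(pruning_fractions == 0)[1]
  ref <- build_reference(catalogs[idx(ctrl_ci, seq_len(realizations))])
  rows <- vector("list", conds * realizations)
  cdfs <- if (connectivity) vector("list", conds * realizations) else NULL
  for (ci in seq_along(pruning_fractions)) {
    for (r in seq_len(realizations)) {
      i <- idx(ci, r)
      ras <- rasters[[i]]
      cat_i <- catalogs[[i]]
      r_ee <- if (nrow(cat_i) > 0) extreme_ratio(cat_i, ref) else NA_real_
      row <- tibble(fraction = pruning_fractions[ci], realization = r,
                    mean_activity = average_activity(ras),
                    n_bursts = nrow(cat_i),
                    background = attr(cat_i, "background"),
                    r_ee = r_ee)
      if (connectivity) {
        en <- tryCatch({
          en <- gte_matrix(ras, catalog = cat_i, rate = rate,
                           min_bursts = min_bursts,
                           seed = seed + 17L * i)
          suppressWarnings(threshold_network(en, 1))
        }, error = function(e) NULL)
        if (!is.null(en)) {
          cdfs[[i]] <- degree_cdf(en$adjacency, percent = TRUE)
          part <- tryCatch(detect_communities(en$adjacency, seed = seed),
                           error = function(e) NULL)
          row$n_edges <- sum(en$adjacency)
          row$density <- sum(en$adjacency) /
            (nrow(en$adjacency) * (nrow(en$adjacency) - 1))
          row$n_communities <- if (is.null(part)) NA_integer_ else
            attr(part, "n_communities")
          row$q <- if (is.null(part)) NA_real_ else attr(part, "q")
        } else {
          row$n_edges <- NA_integer_; row$density <- NA_real_
          row$n_communities <- NA_integer_; row$q <- NA_real_
        }
      }
      rows[[i]] <- row
    }
  }
  out <- list(summary = dplyr::bind_rows(rows), reference = ref,
              catalogs = catalogs, rasters = rasters)
  if (connectivity) out$cdfs <- cdfs
  out$conditions <- tibble(
    condition = seq_along(pruning_fractions),
    fraction = pruning_fractions)
  out
}
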