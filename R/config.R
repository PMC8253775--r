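#' Pipeline run configuration
#'
#' Collects every tunable parameter of the analysis chain in one validated
#' list. All stages read their defaults from here, so a single configuration
#' object (plus a seed) fully determines a run. Values mirror the recording
#' and analysis conditions of the assay the pipeline targets: 20 Hz imaging,
#' 1-s GNA window, mean + 2 SD iterative burst background removal, transfer
#' entropy at Markov order 2 with instant feedback on 50-ms bins, subsampling
#' to 340 neurons with a 10-burst minimum, a 55/25/20 excitatory/DA/inhibitory
#' split, and an 80% target connection loss under pruning.
#'
#' @param sampling_rate Imaging frame rate in Hz.
#' @param gna_window GNA sliding-window length in seconds.
#' @param burst_k_sd SD multiplier for iterative burst background removal.
#' @param extreme_k_sd SD multiplier above the pooled control mean defining an
#'   extreme event.
#' @param gte_threshold_sd SD multiplier over the pooled score distribution
#'   defining a significant effective connection (2.5 is the display variant).
#' @param markov_order Markov order of the transfer-entropy histories.
#' @param instant_feedback Include the same-bin source term in the transfer
#'   entropy source window.
#' @param gte_bin Bin width in seconds for raster binarization.
#' @param subsample Number of neurons scored for effective connectivity.
#' @param min_bursts Minimum number of network bursts a recording must show
#'   before connectivity inference is attempted.
#' @param baseline_percentile,baseline_window Running-percentile baseline for
#'   DFF (percent, seconds).
#' @param theta_high,theta_low,min_frames Schmitt-trigger thresholds (SD units
#'   of the rise-signal noise estimate) and minimum event duration in frames.
#' @param smooth_frames Trailing moving-average width (frames) of the rise
#'   signal the trigger runs on.
#' @param populations Named fractions of excitatory, DA and inhibitory neurons;
#'   must sum to 1.
#' @param field Field of view, c(width, height) in micrometres.
#' @param n_neurons Default simulated network size.
#' @param pruning_loss Target fraction of a pruned neuron's connections lost.
#' @param seed Default RNG seed for stochastic stages.
#' @param ... Additional named settings (kept verbatim).
#'
#' @return A named list of class `burstnet_config`.
#' @examples
#' cfg <- burstnet_config()
#' cfg$subsample
#' @export
burstnet_config <- function(sampling_rate = 20,
                            gna_window = 1,
                            burst_k_sd = 2,
                            extreme_k_sd = 2,
                            gte_threshold_sd = 1,
                            markov_order = 2,
                            instant_feedback = TRUE,
                            gte_bin = 0.05,
                            subsample = 340,
                            min_bursts = 10,
                            baseline_percentile = 10,
                            baseline_window = 30,
                            theta_high = 3.5,
                            theta_low = 1,
                            min_frames = 2,
                            smooth_frames = 4,
                            populations = c(excitatory = 0.55, da = 0.25,
                                            inhibitory = 0.20),
                            field = c(2800, 2100),
                            n_neurons = 300,
                            pruning_loss = 0.8,
                            seed = 1L,
                            ...) {
  cfg <- c(as.list(environment()), list(...))
  cfg$... <- NULL
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  pos <- c("sampling_rate", "gna_window", "gte_bin", "baseline_window")
  for (p in pos) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0)
      abort(sprintf("config field `%s` must be a positive number", p))
  }
  nonneg <- c("burst_k_sd", "extreme_k_sd", "gte_threshold_sd", "theta_low")
  for (p in nonneg) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0)
      abort(sprintf("config field `%s` must be >= 0", p))
  }
  if (cfg$theta_high <= cfg$theta_low)
    abort("`theta_high` must exceed `theta_low`")
  if (cfg$baseline_percentile <= 0 || cfg$baseline_percentile >= 50)
    abort("`baseline_percentile` must lie in (0, 50)")
  if (cfg$markov_order < 1 || cfg$markov_order != round(cfg$markov_order))
    abort("`markov_order` must be a positive integer")
  pops <- cfg$populations
  if (length(pops) != 3 || any(pops < 0) || abs(sum(pops) - 1) > 1e-8)
    abort("`populations` must be 3 non-negative fractions summing to 1")
  if (is.null(names(pops)) || !setequal(names(pops),
                                        c("excitatory", "da", "inhibitory")))
    names(pops) <- c("excitatory", "da", "inhibitory")
  cfg$populations <- pops
  if (cfg$pruning_loss <= 0 || cfg$pruning_loss > 1)
    abort("`pruning_loss` must lie in (0, 1]")
  if (length(cfg$field) != 2 || any(cfg$field <= 0))
    abort("`field` must be two positive lengths (um)")
  structure(cfg, class = "burstnet_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Missing fields are filled with the package defaults (see
#' [burstnet_config()]); unknown keys trigger a warning naming them but are
#' kept, so downstream stages can consume extensions.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `burstnet_config` list.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  defaults <- burstnet_config()
  known <- names(defaults)
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    warn(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  if (!is.null(raw$populations)) {
    raw$populations <- unlist(raw$populations)
  }
  if (!is.null(raw$field)) raw$field <- unlist(raw$field)
  cfg <- utils::modifyList(unclass(defaults), raw)
  validate_config(cfg)
}

#' @export
print.burstnet_config <- function(x, ...) {
  cat("<burstnet_config>\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm, paste(format(val), collapse = "/")))
  }
  invisible(x)
}

# Evaluate `expr` under a locally-set RNG seed, restoring the global state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}
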