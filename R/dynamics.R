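# Collective-dynamics statistics: average activity, the global network
# activity (GNA) time series, the network-burst catalog obtained by
# iterative background removal, and the ratio of extreme events against a
# pooled control reference.

#' Average neuronal activity
#'
#' Number of activations per neuron and minute:
#' `total events / n_neurons / (duration in minutes)`.
#'
#' @param raster A [spike_raster()].
#' @return A single number, spikes/neuron/min.
#' @export
average_activity <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  nrow(raster$events) / raster$n_neurons / (raster$duration / 60)
}

#' Global network activity (GNA)
#'
#' Fraction of active neurons that co-activate within a sliding window:
#' for each window `[t, t + window)` (stride of one frame), the number of
#' distinct neurons with at least one onset in the window, divided by the
#' number of neurons active anywhere in the recording. GNA is 0 for no
#' activity and 1 for a full-network activation.
#'
#' @param raster A [spike_raster()].
#' @param window Window length in seconds.
#' @param rate Frame rate defining the window grid (Hz).
#' @return A `gna_series`: tibble (`time`, `gna`) with attributes `window`,
#'   `rate` and `n_active`.
#' @export
compute_gna <- function(raster, window = 1, rate = 20) {
  stopifnot(inherits(raster, "spike_raster"), window > 0, rate > 0)
  act <- active_neurons(raster)
  n_active <- length(act)
  if (n_active == 0)
    abort("GNA undefined: no active neurons in the recording")
  w_frames <- max(1L, round(window * rate))
  n_frames <- max(1L, floor(raster$duration * rate))
  n_windows <- max(1L, n_frames - w_frames + 1L)
  # diff-array of window counts: an onset at frame f makes its neuron present
  # in windows [f - w + 1, f]; per neuron, overlapping presence intervals are
  # merged so each neuron counts once per window.
  delta <- numeric(n_windows + 1L)
  ev <- raster$events
  frames <- pmin(floor(ev$time * rate), n_frames - 1L)  # 0-based frames
  by_neuron <- split(frames, ev$neuron_id)
  for (f in by_neuron) {
    starts <- pmax(0L, sort(unique(f)) - w_frames + 1L)
    ends <- pmin(sort(unique(f)), n_windows - 1L)
    keep <- starts <= ends
    starts <- starts[keep]; ends <- ends[keep]
    if (length(starts) == 0) next
    # merge overlapping [start, end] intervals
    m_s <- starts[1]; m_e <- ends[1]
    for (i in seq_along(starts)[-1]) {
      if (starts[i] <= m_e + 1L) {
        m_e <- max(m_e, ends[i])
      } else {
        delta[m_s + 1L] <- delta[m_s + 1L] + 1
        delta[m_e + 2L] <- delta[m_e + 2L] - 1
        m_s <- starts[i]; m_e <- ends[i]
      }
    }
    delta[m_s + 1L] <- delta[m_s + 1L] + 1
    delta[m_e + 2L] <- delta[m_e + 2L] - 1
  }
  counts <- cumsum(delta[seq_len(n_windows)])
  out <- tibble(time = (seq_len(n_windows) - 1L) / rate,
                gna = counts / n_active)
  structure(out, window = window, rate = rate, n_active = n_active,
            class = c("gna_series", class(out)))
}

#' Detect network bursts by iterative background removal
#'
#' The background level is found by iterating: compute mean + `k_sd` * SD over
#' the retained samples, then drop samples above it, until a fixed point.
#' Strict local maxima of the original series above the final threshold,
#' separated by at least one window length (larger peaks win ties against
#' smaller neighbours; equal-amplitude ties go to the earlier peak), form the
#' burst catalog.
#'
#' @param gna A `gna_series` from [compute_gna()].
#' @param k_sd SD multiplier of the background threshold.
#' @return A `burst_catalog`: tibble (`time`, `amplitude`, `extreme`) with
#'   attributes `background`, `background_sd`, `threshold` and `window`.
#'   `extreme` is `NA` until a reference is applied.
#' @export
detect_bursts <- function(gna, k_sd = 2) {
  stopifnot(inherits(gna, "gna_series"))
  x <- gna$gna
  if (length(x) == 0) abort("empty GNA series")
  keep <- rep(TRUE, length(x))
  repeat {
    mu <- mean(x[keep]); sdv <- sd(x[keep])
    if (is.na(sdv)) sdv <- 0
    thr <- mu + k_sd * sdv
    new_keep <- x <= thr
    if (identical(new_keep, keep)) break
    if (!any(new_keep)) break  # degenerate: everything above threshold
    keep <- new_keep
  }
  background <- mean(x[keep])
  background_sd <- if (sum(keep) > 1) sd(x[keep]) else 0
  threshold <- background + k_sd * background_sd
  window_frames <- max(1L, round(attr(gna, "window") * attr(gna, "rate")))
  peaks <- local_peaks(x, threshold, min_sep = window_frames)
  out <- tibble(time = gna$time[peaks], amplitude = x[peaks],
                extreme = rep(NA, length(peaks)))
  structure(out, background = background, background_sd = background_sd,
            threshold = threshold, window = attr(gna, "window"),
            class = c("burst_catalog", class(out)))
}

# Strict local maxima above `thr` (plateaus contribute their first frame),
# thinned greedily by descending amplitude (ties: earlier time) so that kept
# peaks are >= min_sep frames apart.
local_peaks <- function(x, thr, min_sep) {
  n <- length(x)
  if (n < 2) return(integer(0))
  cand <- integer(0)
  i <- 1L
  while (i <= n) {
    # find plateau [i, j]
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L
    left_ok <- i == 1L || x[i - 1L] < x[i]
    right_ok <- j == n || x[j + 1L] < x[i]
    if (left_ok && right_ok && x[i] > thr && !(i == 1L && j == n))
      cand <- c(cand, i)
    i <- j + 1L
  }
  if (length(cand) == 0) return(integer(0))
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (p in ord) {
    if (all(abs(kept - p) >= min_sep)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Pooled control reference for extreme events
#'
#' Pools the burst peak amplitudes of one or more control catalogs and
#' records their mean (`a_ctr`) and standard deviation (`sd_ctr`). A burst is
#' an "extreme event" when its amplitude exceeds `a_ctr + k * sd_ctr`
#' (`k = 2` by default downstream).
#'
#' @param ctr_catalogs A `burst_catalog` or list of them.
#' @return An `extreme_reference` list: `a_ctr`, `sd_ctr`, `n_peaks`,
#'   `n_catalogs`.
#' @export
build_reference <- function(ctr_catalogs) {
  if (inherits(ctr_catalogs, "burst_catalog"))
    ctr_catalogs <- list(ctr_catalogs)
  stopifnot(length(ctr_catalogs) >= 1,
            all(vapply(ctr_catalogs, inherits, logical(1), "burst_catalog")))
  amps <- unlist(lapply(ctr_catalogs, function(cat) cat$amplitude))
  if (length(amps) == 0)
    abort("no burst peaks in any control catalog")
  structure(list(a_ctr = mean(amps),
                 sd_ctr = if (length(amps) > 1) sd(amps) else 0,
                 n_peaks = length(amps),
                 n_catalogs = length(ctr_catalogs)),
            class = "extreme_reference")
}

#' @export
print.extreme_reference <- function(x, ...) {
  cat(sprintf("<extreme_reference> A_CTR = %.4f, SD_CTR = %.4f (%d peaks, %d catalogs)\n",
              x$a_ctr, x$sd_ctr, x$n_peaks, x$n_catalogs))
  invisible(x)
}

#' Flag extreme events against a control reference
#'
#' @param catalog A `burst_catalog`.
#' @param reference An `extreme_reference` from [build_reference()].
#' @param k_sd SD multiplier over the pooled control mean. Alternatively
#'   `rule = "quantile95"` thresholds at the 95th percentile-equivalent
#'   `a_ctr + 1.645 * sd_ctr` of the control amplitude distribution.
#' @param rule `"mean_sd"` (default) or `"quantile95"`.
#' @return The catalog with its `extreme` column filled; attribute
#'   `"extreme_threshold"` records the cutoff used.
#' @export
flag_extremes <- function(catalog, reference, k_sd = 2,
                          rule = c("mean_sd", "quantile95")) {
  stopifnot(inherits(catalog, "burst_catalog"),
            inherits(reference, "extreme_reference"))
  rule <- match.arg(rule)
  thr <- switch(rule,
    mean_sd = reference$a_ctr + k_sd * reference$sd_ctr,
    quantile95 = reference$a_ctr + 1.645 * reference$sd_ctr)
  catalog$extreme <- catalog$amplitude > thr
  attr(catalog, "extreme_threshold") <- thr
  catalog
}

#' Ratio of extreme events
#'
#' Fraction of a recording's burst peaks whose amplitude exceeds the control
#' reference threshold `a_ctr + k_sd * sd_ctr`. Control-like recordings sit
#' near 0 by construction; recordings dominated by whole-network events
#' approach 1.
#'
#' @inheritParams flag_extremes
#' @return A number in `[0, 1]`.
#' @export
extreme_ratio <- function(catalog, reference, k_sd = 2,
                          rule = c("mean_sd", "quantile95")) {
  stopifnot(inherits(catalog, "burst_catalog"))
  if (nrow(catalog) == 0)
    abort("extreme ratio undefined: catalog has no burst peaks")
  catalog <- flag_extremes(catalog, reference, k_sd, rule)
  mean(catalog$extreme)
}

#' @export
glance.burst_catalog <- function(x, ...) {
  tibble(n_bursts = nrow(x),
         background = attr(x, "background"),
         background_sd = attr(x, "background_sd"),
         threshold = attr(x, "threshold"),
         mean_amplitude = if (nrow(x) > 0) mean(x$amplitude) else NA_real_,
         extreme_ratio = if (nrow(x) > 0 && !anyNA(x$extreme))
           mean(x$extreme) else NA_real_)
}

#' @export
tidy.burst_catalog <- function(x, ...) as_tibble(unclass(x))
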