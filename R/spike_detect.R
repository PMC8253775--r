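# DFF normalization and Schmitt-trigger onset inference. The baseline F0 is
# a running low percentile of the raw trace (rest-level proxy robust to
# transients); the trigger runs on the rise signal of the DFF trace with a
# robust (MAD) noise scale, so bursts do not inflate the noise estimate.

#' Normalize fluorescence to DFF
#'
#' Computes, per neuron, `DFF = 100 * (F - F0) / F0` (percent), with `F0` the
#' running `baseline_percentile`-th percentile of the raw trace over a
#' centred sliding window of `baseline_window` seconds.
#'
#' @param recording A [fluorescence_recording()].
#' @param baseline_percentile Percentile (in percent, 0-50 exclusive) used as
#'   the rest-level estimate.
#' @param baseline_window Sliding-window length in seconds; windows are
#'   truncated at the recording edges. `Inf` uses a single global percentile.
#' @return A `dff_trace` object: DFF matrix (frames x neurons, percent), the
#'   baseline matrix `f0`, and the sampling rate.
#' @export
compute_dff <- function(recording, baseline_percentile = 10,
                        baseline_window = 30) {
  stopifnot(inherits(recording, "fluorescence_recording"))
  if (baseline_percentile <= 0 || baseline_percentile >= 50)
    abort("`baseline_percentile` must lie in (0, 50)")
  tr <- recording$traces
  if (nrow(tr) == 0) abort("recording is empty")
  p <- baseline_percentile / 100
  f0 <- apply(tr, 2, running_percentile, p = p,
              half = if (is.infinite(baseline_window)) Inf else
                max(1L, round(baseline_window * recording$sampling_rate / 2)))
  f0 <- matrix(f0, nrow = nrow(tr))
  if (any(f0 <= 0))
    abort("non-positive baseline F0 (dead or negative trace)")
  dff <- 100 * (tr - f0) / f0
  structure(list(dff = dff, f0 = f0,
                 sampling_rate = recording$sampling_rate,
                 roi = recording$roi),
            class = "dff_trace")
}

# Running percentile over a centred window of `2*half + 1` frames (clipped at
# the edges); `half = Inf` gives the global percentile, recycled per frame.
# Evaluated on a strided grid (window/10) and linearly interpolated between
# grid points: the baseline varies on the window timescale, so this loses
# nothing while keeping long recordings cheap.
running_percentile <- function(x, p, half) {
  n <- length(x)
  if (is.infinite(half) || 2 * half + 1 >= n)
    return(rep(quantile(x, p, names = FALSE, type = 7), n))
  stride <- max(1L, half %/% 5L)
  grid <- unique(c(seq(1L, n, by = stride), n))
  vals <- vapply(grid, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    quantile(x[lo:hi], p, names = FALSE, type = 7)
  }, numeric(1))
  if (length(grid) == 1) return(rep(vals, n))
  stats::approx(grid, vals, xout = seq_len(n), rule = 2)$y
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("<dff_trace> %d frames x %d neurons @ %g Hz\n",
              nrow(x$dff), ncol(x$dff), x$sampling_rate))
  invisible(x)
}

# Robust per-neuron noise SD: MAD of the first difference of the DFF trace,
# rescaled to the SD of the underlying white noise (diff doubles the
# variance, hence the sqrt(2)).
noise_sd_dff <- function(dff_col) {
  d <- diff(dff_col)
  mad(d) / sqrt(2)
}

#' Infer spike onsets with a Schmitt trigger
#'
#' The two-threshold hysteresis runs on the rise signal of the trace — the
#' short-window increment of a lightly smoothed DFF — rather than on the
#' absolute DFF level. A calcium transient announces itself as a fast rise
#' (the arrowhead feature of the trace), so triggering on the rise is
#' insensitive to baseline offsets and, critically, resolves a spike that
#' lands on the slow decay shoulder of a previous transient, where any
#' absolute-level trigger is still "open". An event opens at the first
#' frame where the rise reaches `theta_high * sigma_noise`, closes when it
#' drops below `theta_low * sigma_noise`, and must last at least
#' `min_frames` frames; the onset time is the opening frame (corrected for
#' the smoothing lag) divided by the sampling rate. `sigma_noise` is the
#' robust SD of the rise signal (MAD).
#'
#' ROIs whose noise estimate exceeds `noise_ceiling` (DFF %) are discarded
#' (automatic stand-in for manual curation of non-neuronal signals); their
#' onsets are dropped but they keep their neuron id in the raster.
#'
#' @param dff A `dff_trace` from [compute_dff()].
#' @param theta_high,theta_low Opening/closing thresholds in SD units of the
#'   rise signal (`theta_high > theta_low >= 0`).
#' @param min_frames Minimum event length in frames.
#' @param smooth_frames Width of the trailing moving average applied before
#'   differencing; the rise at frame `i` is `xs[i] - xs[i - smooth_frames]`.
#' @param noise_ceiling Discard ROIs with `sigma_noise` above this value
#'   (DFF % per rise window; automatic stand-in for manual curation of
#'   non-neuronal ROIs).
#' @return A [spike_raster()]; attribute `"qc"` holds a per-neuron tibble
#'   (`neuron_id`, `sigma_noise`, `n_onsets`, `kept`).
#' @export
detect_onsets <- function(dff, theta_high = 3.5, theta_low = 1,
                          min_frames = 2, smooth_frames = 4,
                          noise_ceiling = Inf) {
  stopifnot(inherits(dff, "dff_trace"), smooth_frames >= 1)
  if (!(theta_high > theta_low && theta_low >= 0))
    abort("need theta_high > theta_low >= 0")
  n <- ncol(dff$dff)
  n_frames <- nrow(dff$dff)
  rate <- dff$sampling_rate
  events <- vector("list", n)
  qc <- tibble(neuron_id = seq_len(n), sigma_noise = NA_real_,
               n_onsets = 0L, kept = TRUE)
  # opening-frame correction for the smoothing + differencing lag
  lag <- max(1L, as.integer(round((smooth_frames + 1) / 2)))
  for (j in seq_len(n)) {
    x <- dff$dff[, j]
    d <- rise_signal(x, smooth_frames)
    sig <- mad(d)
    qc$sigma_noise[j] <- sig
    if (sig == 0) {
      if (diff(range(x)) > 0)
        abort(sprintf("degenerate noise estimate (sigma = 0) for neuron %d", j))
      next  # flat trace: no onsets
    }
    if (sig > noise_ceiling) {
      qc$kept[j] <- FALSE
      next
    }
    onsets <- schmitt_onsets(d, theta_high * sig, theta_low * sig, min_frames)
    onsets <- pmax(1L, onsets - lag)
    qc$n_onsets[j] <- length(onsets)
    if (length(onsets) > 0)
      events[[j]] <- tibble(neuron_id = j, time = (onsets - 1) / rate)
  }
  out <- spike_raster(dplyr::bind_rows(events), n, n_frames / rate)
  attr(out, "qc") <- qc
  out
}

# Rise signal: trailing moving average of width w, differenced over w
# frames. Captures the fast upstroke of a calcium transient while averaging
# frame-to-frame noise.
rise_signal <- function(x, w) {
  n <- length(x)
  if (w == 1) {
    d <- c(0, diff(x))
    return(d)
  }
  cs <- cumsum(x)
  xs <- x
  idx <- (w + 1):n
  xs[idx] <- (cs[idx] - cs[idx - w]) / w
  xs[1:w] <- cumsum(x[1:w]) / seq_len(w)
  d <- numeric(n)
  idx2 <- (w + 1):n
  d[idx2] <- xs[idx2] - xs[idx2 - w]
  d
}

# Two-threshold hysteresis sweep; returns 1-based opening frame indices.
schmitt_onsets <- function(x, hi, lo, min_frames) {
  schmitt_onsets_cpp(as.numeric(x), hi, lo, as.integer(min_frames))
}
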