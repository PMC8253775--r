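#' Spike raster
#'
#' The lingua franca of the pipeline: per-neuron spike-onset times over a
#' recording of known duration. Events are stored as a tibble
#' (`neuron_id`, `time`) sorted by neuron then time; silent neurons are
#' represented implicitly through `n_neurons`. Optional per-neuron labels
#' (e.g. `"th"`/`"non_th"` or `"excitatory"`/`"da"`/`"inhibitory"`) allow
#' subpopulation splits.
#'
#' Times are in seconds and must lie in `[0, duration)`; per-neuron times are
#' strictly increasing (exact duplicates are dropped at construction).
#'
#' @param events A data frame with integer `neuron_id` (1-based) and numeric
#'   `time` columns. May be empty.
#' @param n_neurons Number of neurons, including silent ones.
#' @param duration Recording duration in seconds.
#' @param labels Optional character vector of per-neuron labels,
#'   length `n_neurons`.
#'
#' @return An object of class `spike_raster`.
#' @examples
#' r <- spike_raster(tibble::tibble(neuron_id = c(1L, 2L), time = c(0.5, 1.2)),
#'                   n_neurons = 3, duration = 10)
#' glance(r)
#' @export
spike_raster <- function(events, n_neurons, duration, labels = NULL) {
  stopifnot(is.data.frame(events), n_neurons >= 1, duration > 0)
  events <- as_tibble(events)
  if (nrow(events) == 0) {
    events <- tibble(neuron_id = integer(), time = double())
  }
  if (!all(c("neuron_id", "time") %in% names(events)))
    abort("`events` needs columns `neuron_id` and `time`")
  events$neuron_id <- as.integer(events$neuron_id)
  events$time <- as.double(events$time)
  if (nrow(events) > 0) {
    if (anyNA(events$neuron_id) || anyNA(events$time))
      abort("events contain missing values")
    if (any(events$neuron_id < 1L | events$neuron_id > n_neurons))
      abort("unknown neuron ids in events")
    if (any(events$time < 0 | events$time >= duration))
      abort("event times must lie in [0, duration)")
    events <- dplyr::distinct(events, .data$neuron_id, .data$time)
    events <- dplyr::arrange(events, .data$neuron_id, .data$time)
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n_neurons)
      abort("`labels` must have length `n_neurons`")
  }
  structure(
    list(events = events,
         n_neurons = as.integer(n_neurons),
         duration = as.double(duration),
         labels = labels),
    class = "spike_raster"
  )
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d neurons, %.6g s, %d events\n",
              x$n_neurons, x$duration, nrow(x$events)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @rdname spike_raster
#' @param x A `spike_raster`.
#' @param ... Unused.
#' @export
as_tibble.spike_raster <- function(x, ...) x$events

#' Neurons with at least one onset
#' @param raster A [spike_raster()].
#' @return Integer vector of active neuron ids.
#' @export
active_neurons <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  sort(unique(raster$events$neuron_id))
}

#' @export
tidy.spike_raster <- function(x, ...) {
  out <- x$events
  if (!is.null(x$labels)) out$label <- x$labels[out$neuron_id]
  out
}

#' @export
glance.spike_raster <- function(x, ...) {
  tibble(
    n_neurons = x$n_neurons,
    n_active = length(active_neurons(x)),
    duration = x$duration,
    n_events = nrow(x$events),
    mean_activity = average_activity(x)
  )
}

#' Fluorescence recording
#'
#' Raw calcium fluorescence as a frames-by-neurons matrix with its sampling
#' rate and ROI geometry. Column `j` of `traces` corresponds to row `j` of the
#' ROI table.
#'
#' @param traces Numeric matrix, frames in rows, neurons in columns.
#' @param sampling_rate Frame rate in Hz.
#' @param roi Optional ROI table: a data frame with `roi_id`, `x`, `y`,
#'   `diameter` (micrometres). Defaults to a placeholder table with unit
#'   diameters at the origin replaced by `roi_table()` positions.
#'
#' @return An object of class `fluorescence_recording`.
#' @export
fluorescence_recording <- function(traces, sampling_rate, roi = NULL) {
  traces <- as.matrix(traces)
  if (!is.numeric(traces) || anyNA(traces))
    abort("`traces` must be a numeric matrix without missing values")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    abort("`sampling_rate` must be positive")
  n <- ncol(traces)
  if (is.null(roi)) {
    roi <- roi_table(n)
  }
  roi <- validate_roi(roi)
  if (nrow(roi) != n)
    abort(sprintf("ROI table has %d rows but traces have %d columns",
                  nrow(roi), n))
  colnames(traces) <- roi$roi_id
  structure(
    list(traces = traces, sampling_rate = as.double(sampling_rate), roi = roi),
    class = "fluorescence_recording"
  )
}

#' Build a simple ROI table
#'
#' Lays `n` ROIs on a jittered grid inside the field of view. Used as a
#' default geometry for synthetic recordings.
#'
#' @param n Number of ROIs.
#' @param field Field of view, c(width, height) in micrometres.
#' @param diameter ROI diameter in micrometres.
#' @param seed Optional seed for the jitter.
#' @return A tibble with columns `roi_id`, `x`, `y`, `diameter`.
#' @export
roi_table <- function(n, field = c(2800, 2100), diameter = 10, seed = NULL) {
  with_seed(seed, {
    ncol_grid <- ceiling(sqrt(n * field[1] / field[2]))
    nrow_grid <- ceiling(n / ncol_grid)
    idx <- seq_len(n) - 1L
    gx <- (idx %% ncol_grid + 0.5) / ncol_grid * field[1]
    gy <- (idx %/% ncol_grid + 0.5) / nrow_grid * field[2]
    jit <- min(field) * 0.01
    tibble(
      roi_id = seq_len(n),
      x = pmin(pmax(gx + runif(n, -jit, jit), 0), field[1]),
      y = pmin(pmax(gy + runif(n, -jit, jit), 0), field[2]),
      diameter = rep(as.double(diameter), n)
    )
  })
}

validate_roi <- function(roi) {
  roi <- as_tibble(roi)
  need <- c("roi_id", "x", "y")
  if (!all(need %in% names(roi)))
    abort("ROI table needs columns roi_id, x, y (and optionally diameter)")
  if (!("diameter" %in% names(roi))) roi$diameter <- 10
  if (anyDuplicated(roi$roi_id)) abort("`roi_id` must be unique")
  if (any(roi$diameter <= 0)) abort("ROI diameters must be positive")
  roi
}

#' @export
print.fluorescence_recording <- function(x, ...) {
  cat(sprintf(
    "<fluorescence_recording> %d frames x %d neurons @ %g Hz (%.6g s)\n",
    nrow(x$traces), ncol(x$traces), x$sampling_rate, rec_duration(x)))
  invisible(x)
}

rec_duration <- function(rec) nrow(rec$traces) / rec$sampling_rate

#' @export
as_tibble.fluorescence_recording <- function(x, ...) {
  n_frames <- nrow(x$traces)
  tibble(
    frame = rep(seq_len(n_frames) - 1L, times = ncol(x$traces)),
    time = rep((seq_len(n_frames) - 1L) / x$sampling_rate,
               times = ncol(x$traces)),
    roi_id = rep(x$roi$roi_id, each = n_frames),
    f = as.vector(x$traces)
  )
}
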