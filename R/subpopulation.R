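# Subpopulation splits: any labeled raster (TH+/non-TH reporters, or
# simulated excitatory/DA/inhibitory types) can be partitioned into layers
# that are analyzed with the same dynamics pipeline, each layer normalized
# by its own active-neuron count.

#' Split a raster by per-neuron label
#'
#' Partitions a labeled raster into per-label views sharing the parent's
#' time base. Each view is a full [spike_raster()] over that layer's neurons
#' (ids remapped to 1..n_layer; the original ids are kept in attribute
#' `"parent_ids"`), so every downstream statistic (GNA, bursts, extreme
#' ratio) runs per layer with the layer's own normalization.
#'
#' @param raster A [spike_raster()].
#' @param labels Per-neuron labels; defaults to the raster's own. A split
#'   requires at least one label value (binary splits are the common case).
#' @return A named list of [spike_raster()]s, one per label value, of class
#'   `labeled_split`.
#' @export
split_by_label <- function(raster, labels = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  if (is.null(labels)) labels <- raster$labels
  if (is.null(labels)) abort("raster has no labels and none were supplied")
  if (length(labels) != raster$n_neurons)
    abort("`labels` must have one entry per neuron")
  out <- lapply(split(seq_len(raster$n_neurons), labels), function(ids) {
    ev <- raster$events[raster$events$neuron_id %in% ids, , drop = FALSE]
    ev$neuron_id <- match(ev$neuron_id, ids)
    view <- spike_raster(ev, length(ids), raster$duration)
    attr(view, "parent_ids") <- ids
    view
  })
  structure(out, class = c("labeled_split", "list"))
}

#' One-row dynamics summary of a raster
#'
#' Convenience wrapper running the GNA/burst/extreme chain on one raster.
#'
#' @param raster A [spike_raster()].
#' @param rate Frame rate (Hz) for the GNA grid.
#' @param window GNA window, seconds.
#' @param k_sd Burst background SD multiplier.
#' @param reference Optional [build_reference()] object; without it the
#'   extreme ratio is `NA`.
#' @return A one-row tibble: `n_active`, `mean_activity`, `n_bursts`,
#'   `background`, `r_ee`.
#' @export
analyze_dynamics <- function(raster, rate = 20, window = 1, k_sd = 2,
                             reference = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  n_act <- length(active_neurons(raster))
  if (n_act == 0) {
    return(tibble(n_active = 0L, mean_activity = 0, n_bursts = NA_integer_,
                  background = NA_real_, r_ee = NA_real_))
  }
  cat_i <- detect_bursts(compute_gna(raster, window = window, rate = rate),
                         k_sd = k_sd)
  r_ee <- if (!is.null(reference) && nrow(cat_i) > 0)
    extreme_ratio(cat_i, reference) else NA_real_
  tibble(n_active = n_act,
         mean_activity = average_activity(raster),
         n_bursts = nrow(cat_i),
         background = attr(cat_i, "background"),
         r_ee = r_ee)
}

#' Per-layer dynamics of a labeled split
#'
#' Runs [analyze_dynamics()] on each layer. Extreme-event references are
#' layer-specific: `references` must be a named list matching the split's
#' layer names (each built from the same layer of control recordings), or
#' `NULL` to skip extreme ratios.
#'
#' @param split A `labeled_split` from [split_by_label()].
#' @param references Optional named list of [build_reference()] objects.
#' @inheritParams analyze_dynamics
#' @return A tibble with one row per layer (column `layer` first).
#' @export
layer_dynamics <- function(split, references = NULL, rate = 20, window = 1,
                           k_sd = 2) {
  stopifnot(inherits(split, "labeled_split"))
  rows <- lapply(names(split), function(nm) {
    ref <- if (!is.null(references)) references[[nm]] else NULL
    dplyr::bind_cols(tibble(layer = nm),
                     analyze_dynamics(split[[nm]], rate = rate,
                                      window = window, k_sd = k_sd,
                                      reference = ref))
  })
  dplyr::bind_rows(rows)
}
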