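# End-to-end orchestration: synthesize or load recordings, detect onsets,
# run the dynamics/connectivity/community analyses, and write every
# intermediate artifact plus a manifest into a run directory. Identical
# config + seed reproduce a run byte for byte.

#' Run the full analysis pipeline
#'
#' Each element of `inputs` is either a preset name (`"ctr_like"` /
#' `"pd_like"`, synthesized on the fly), a [spike_raster()], or a
#' [fluorescence_recording()] (sent through DFF + Schmitt-trigger
#' detection). Recordings named in `reference_group` (default: those whose
#' name starts with `"ctr"`) provide the pooled control burst amplitudes;
#' if none is available the extreme-event ratio is refused with an error.
#'
#' @param inputs Named list of presets, rasters or recordings.
#' @param outdir Run directory (created; must not already contain a
#'   manifest).
#' @param config A [burstnet_config()].
#' @param seed Master seed for synthesis, subsampling and community
#'   detection.
#' @param n,duration Size and length of synthesized preset recordings.
#' @param synth_fluorescence For preset inputs, synthesize calcium traces
#'   and re-detect onsets (full chain) instead of analyzing the
#'   ground-truth raster directly.
#' @param connectivity Run GTE + communities (needs the burst filter to
#'   pass).
#' @return Invisibly, the summary tibble (one row per recording: activity,
#'   burst count, extreme ratio, edge density, community count, Q); written
#'   with all artifacts under `outdir`.
#' @export
run_full <- function(inputs, outdir, config = burstnet_config(), seed = 1L,
                     n = 120, duration = 300, synth_fluorescence = FALSE,
                     connectivity = TRUE) {
  stopifnot(is.list(inputs), length(inputs) > 0)
  if (is.null(names(inputs)) || any(names(inputs) == ""))
    abort("`inputs` must be a named list")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  rate <- config$sampling_rate
  reference_group <- names(inputs)[startsWith(tolower(names(inputs)), "ctr")]

  rasters <- list()
  for (i in seq_along(inputs)) {
    nm <- names(inputs)[i]
    item <- inputs[[i]]
    item_seed <- seed + 211L * i
    if (is.character(item)) {
      ras <- gen_raster(n, duration, burst_preset(item), seed = item_seed)
      if (synth_fluorescence) {
        rec <- spikes_to_fluorescence(ras, calcium_kernel(), rate = rate,
                                      seed = item_seed)
        dff <- compute_dff(rec, config$baseline_percentile,
                           config$baseline_window)
        ras <- detect_onsets(dff, config$theta_high, config$theta_low,
                             config$min_frames, config$smooth_frames)
      }
    } else if (inherits(item, "fluorescence_recording")) {
      dff <- compute_dff(item, config$baseline_percentile,
                         config$baseline_window)
      ras <- detect_onsets(dff, config$theta_high, config$theta_low,
                           config$min_frames, config$smooth_frames)
    } else if (inherits(item, "spike_raster")) {
      ras <- item
    } else {
      abort(sprintf("input `%s`: unsupported type", nm))
    }
    rasters[[nm]] <- ras
    write_raster(ras, file.path(outdir, paste0(nm, "_raster.csv")))
  }

  gnas <- lapply(rasters, compute_gna, window = config$gna_window,
                 rate = rate)
  catalogs <- lapply(gnas, detect_bursts, k_sd = config$burst_k_sd)
  for (nm in names(catalogs)) {
    readr::write_csv(tidy(catalogs[[nm]]),
                     file.path(outdir, paste0(nm, "_bursts.csv")))
    readr::write_csv(as_tibble(unclass(gnas[[nm]])),
                     file.path(outdir, paste0(nm, "_gna.csv")))
  }
  ctr_catalogs <- catalogs[reference_group]
  ctr_catalogs <- ctr_catalogs[vapply(ctr_catalogs, nrow, integer(1)) > 0]
  ref <- if (length(ctr_catalogs) > 0) build_reference(ctr_catalogs) else NULL
  if (is.null(ref))
    abort(paste("no control (ctr*) recording with bursts available:",
                "extreme-event ratios refused without a reference"))

  rows <- vector("list", length(rasters))
  for (i in seq_along(rasters)) {
    nm <- names(rasters)[i]
    ras <- rasters[[nm]]
    cat_i <- catalogs[[nm]]
    row <- tibble(
      recording = nm,
      n_neurons = ras$n_neurons,
      n_active = length(active_neurons(ras)),
      mean_activity = average_activity(ras),
      n_bursts = nrow(cat_i),
      background = attr(cat_i, "background"),
      r_ee = if (nrow(cat_i) > 0) extreme_ratio(cat_i, ref, config$extreme_k_sd)
             else NA_real_
    )
    if (connectivity) {
      en <- tryCatch({
        en <- suppressWarnings(gte_matrix(
          ras, catalog = cat_i, bin = config$gte_bin,
          k = config$markov_order,
          instant_feedback = config$instant_feedback,
          subsample = config$subsample, min_bursts = config$min_bursts,
          rate = rate, seed = seed + 389L * i))
        threshold_network(en, config$gte_threshold_sd)
      }, error = function(e) e)
      if (inherits(en, "effective_network")) {
        write_adjacency(en$adjacency,
                        file.path(outdir, paste0(nm, "_adjacency.csv")),
                        format = "triplet")
        part <- detect_communities(en$adjacency, seed = seed)
        cdf <- degree_cdf(en$adjacency, percent = TRUE)
        readr::write_csv(as_tibble(unclass(cdf)),
                         file.path(outdir, paste0(nm, "_degree_cdf.csv")))
        nn <- nrow(en$adjacency)
        row$edge_density <- sum(en$adjacency) / (nn * (nn - 1))
        row$n_communities <- attr(part, "n_communities")
        row$q <- attr(part, "q")
      } else {
        row$edge_density <- NA_real_
        row$n_communities <- NA_integer_
        row$q <- NA_real_
        row$connectivity_note <- conditionMessage(en)
      }
    }
    rows[[i]] <- row
  }
  summary <- dplyr::bind_rows(rows)
  readr::write_csv(summary, file.path(outdir, "summary.csv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("burstnet")),
    seed = seed,
    reference_group = reference_group,
    inputs = names(inputs),
    config = unclass(config)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
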