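# Readers and writers for every artifact the pipeline touches. All on-disk
# formats are plain text: CSV for ROI tables, traces, event lists and
# adjacency matrices (dense or triplet), with a small commented header
# carrying metadata that the tabular body cannot (neuron count, duration,
# labels). Conventions: times in seconds, positions in um, frames 0-based,
# adjacency row -> column means source -> target.

#' Read a fluorescence recording from trace and ROI tables
#'
#' The trace file is a CSV of frames x ROIs whose column names are the
#' `roi_id`s of the ROI table; the ROI file has columns
#' `roi_id, x, y, diameter`.
#'
#' @param trace_path CSV of fluorescence traces (frames x ROIs).
#' @param roi_path CSV of ROI geometry.
#' @param sampling_rate Acquisition rate in Hz.
#' @return A [fluorescence_recording()].
#' @export
read_recording <- function(trace_path, roi_path, sampling_rate = 20) {
  roi <- validate_roi(readr::read_csv(roi_path, show_col_types = FALSE,
                                      comment = "#"))
  traces <- readr::read_csv(trace_path, show_col_types = FALSE, comment = "#")
  if (!all(vapply(traces, is.numeric, logical(1))))
    abort("trace table contains non-numeric cells")
  if (ncol(traces) != nrow(roi))
    abort(sprintf("trace table has %d columns but ROI table has %d rows",
                  ncol(traces), nrow(roi)))
  if (!identical(as.character(names(traces)), as.character(roi$roi_id)))
    abort("trace column labels do not match `roi_id`s")
  fluorescence_recording(as.matrix(traces), sampling_rate, roi)
}

#' @rdname read_recording
#' @param recording A [fluorescence_recording()].
#' @export
write_recording <- function(recording, trace_path, roi_path) {
  stopifnot(inherits(recording, "fluorescence_recording"))
  tr <- as.data.frame(recording$traces)
  names(tr) <- as.character(recording$roi$roi_id)
  readr::write_csv(tibble::as_tibble(tr), trace_path)
  readr::write_csv(recording$roi, roi_path)
  invisible(c(trace_path, roi_path))
}

#' Spike-raster event-list I/O
#'
#' The canonical on-disk form of a raster is a two-column CSV
#' (`neuron_id, time`) preceded by commented header lines carrying
#' `n_neurons`, `duration` and optional per-neuron labels. Write-then-read
#' round-trips events and metadata exactly; unsorted files are canonicalized
#' (sorted per neuron) on read.
#'
#' @param raster A [spike_raster()].
#' @param path File path.
#' @return `read_raster` returns a [spike_raster()]; `write_raster` returns
#'   `path` invisibly.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  hdr <- c(
    "# burstnet spike_raster v1",
    sprintf("# n_neurons: %d", raster$n_neurons),
    sprintf("# duration: %s", format(raster$duration, digits = 17))
  )
  if (!is.null(raster$labels))
    hdr <- c(hdr, sprintf("# labels: %s", paste(raster$labels, collapse = ",")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("neuron_id,time", con)
  if (nrow(raster$events) > 0) {
    writeLines(sprintf("%d,%s", raster$events$neuron_id,
                       format(raster$events$time, digits = 17,
                              scientific = FALSE, trim = TRUE)), con)
  }
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get_field <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    if (length(ln) == 0) return(NULL)
    sub(paste0("^# ", key, ":\\s*"), "", ln[1])
  }
  n_neurons <- get_field("n_neurons")
  duration <- get_field("duration")
  if (is.null(n_neurons) || is.null(duration))
    abort("raster file lacks n_neurons/duration header")
  labels <- get_field("labels")
  if (!is.null(labels)) labels <- strsplit(labels, ",", fixed = TRUE)[[1]]
  events <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                            col_types = "id")
  spike_raster(events, as.integer(n_neurons), as.double(duration),
               labels = labels)
}

#' Directed adjacency matrix I/O
#'
#' Square matrices (row = source, column = target) are written either dense
#' (a headerless CSV of numbers, plus a commented size line) or as triplets
#' (`source, target, value` for the nonzero entries). Both forms round-trip
#' losslessly and read back equal.
#'
#' @param mat A square numeric matrix.
#' @param path File path.
#' @param format `"dense"` or `"triplet"`; `read_adjacency` auto-detects.
#' @return `read_adjacency` returns the matrix; `write_adjacency` returns
#'   `path` invisibly.
#' @export
write_adjacency <- function(mat, path, format = c("dense", "triplet")) {
  format <- match.arg(format)
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) abort("adjacency must be square")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# burstnet adjacency %s v1", format),
               sprintf("# n: %d", nrow(mat))), con)
  if (format == "dense") {
    writeLines(apply(mat, 1, function(r)
      paste(format(r, digits = 17, trim = TRUE), collapse = ",")), con)
  } else {
    nz <- which(mat != 0, arr.ind = TRUE)
    writeLines("source,target,value", con)
    if (nrow(nz) > 0) {
      ord <- order(nz[, 1], nz[, 2])
      nz <- nz[ord, , drop = FALSE]
      writeLines(sprintf("%d,%d,%s", nz[, 1], nz[, 2],
                         format(mat[nz], digits = 17, trim = TRUE)), con)
    }
  }
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  if (length(hdr) == 0 || !grepl("burstnet adjacency", hdr[1]))
    abort("not a burstnet adjacency file")
  fmt <- if (grepl("triplet", hdr[1])) "triplet" else "dense"
  n <- as.integer(sub("^# n:\\s*", "", hdr[grepl("^# n:", hdr)][1]))
  body <- lines[!startsWith(lines, "#")]
  if (fmt == "dense") {
    vals <- lapply(body, function(l) as.double(strsplit(l, ",")[[1]]))
    mat <- do.call(rbind, vals)
    if (is.null(mat)) mat <- matrix(0, n, n)
    if (nrow(mat) != n || ncol(mat) != n)
      abort("dense adjacency body does not match declared size")
  } else {
    trip <- readr::read_csv(I(paste(body, collapse = "\n")),
                            show_col_types = FALSE, col_types = "iid")
    mat <- matrix(0, n, n)
    if (nrow(trip) > 0) mat[cbind(trip$source, trip$target)] <- trip$value
  }
  dimnames(mat) <- NULL
  mat
}
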