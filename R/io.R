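## On-disk formats.
## Spike tables: CSV (electrode_id,timestamp_s) + JSON sidecar "<path>.json"
## carrying layout, duration and metadata; timestamps printed with %.17g so
## doubles round-trip bit-exactly. Raw recordings: Feather (one column per
## electrode, lossless for doubles) + the same JSON sidecar scheme.

layoutToList <- function(layout) {
  list(
    n_modules = layout@nModules,
    pitch_um = layout@pitchUm,
    channel_length_um = layout@channelLengthUm,
    electrodes = layout@electrodes
  )
}

layoutFromList <- function(x) {
  need <- c("n_modules", "pitch_um", "channel_length_um", "electrodes")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("layout description is missing field(s): ", paste(miss, collapse = ", "))
  el <- as.data.frame(x$electrodes, stringsAsFactors = FALSE)
  el$module_id <- as.integer(el$module_id)
  el$channel_index <- suppressWarnings(as.integer(el$channel_index))
  el$position_um <- as.numeric(el$position_um)
  new("DeviceLayout",
    nModules = as.integer(x$n_modules),
    electrodes = el,
    pitchUm = as.numeric(x$pitch_um),
    channelLengthUm = as.numeric(x$channel_length_um)
  )
}

sidecarPath <- function(path) paste0(path, ".json")

writeSidecar <- function(path, kind, layout, metadata, extra = list()) {
  obj <- c(list(
    kind = kind,
    layout = layoutToList(layout),
    metadata = metadata
  ), extra)
  jsonlite::write_json(obj, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
}

readSidecar <- function(path, kind) {
  sp <- sidecarPath(path)
  if (!file.exists(sp))
    stop("missing sidecar file: ", sp)
  obj <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(obj$kind) || !identical(obj$kind, kind))
    stop("sidecar field 'kind' is '", obj$kind %||% "<absent>",
         "', expected '", kind, "'")
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write spike tables
#'
#' A \code{\linkS4class{SpikeTable}} is stored as a human-inspectable CSV
#' with columns \code{electrode_id,timestamp_s} (one row per spike, full
#' double precision) plus a JSON sidecar \code{<path>.json} holding the
#' device layout, recording duration and metadata. The round trip is
#' bit-exact.
#'
#' @param x a \code{\linkS4class{SpikeTable}}.
#' @param path CSV file path; the sidecar is written next to it.
#' @return \code{writeSpikeTable} returns \code{path} invisibly;
#'   \code{readSpikeTable} returns the reconstructed
#'   \code{\linkS4class{SpikeTable}}.
#' @examples
#' tab <- emptySpikeTable(buildDefaultLayout(), 10)
#' f <- tempfile(fileext = ".csv")
#' writeSpikeTable(tab, f)
#' identical(spikeTrains(readSpikeTable(f)), spikeTrains(tab))
#' @export
writeSpikeTable <- function(x, path) {
  stopifnot(is(x, "SpikeTable"))
  validObject(x)
  ids <- rep(names(x@spikes), vapply(x@spikes, length, integer(1)))
  ts <- unlist(x@spikes, use.names = FALSE)
  if (is.null(ts)) ts <- numeric(0)
  dt <- data.table::data.table(
    electrode_id = ids %||% character(0),
    timestamp_s = sprintf("%.17g", ts)
  )
  data.table::fwrite(dt, path, quote = FALSE)
  writeSidecar(path, "spike_table", x@layout, x@metadata,
               list(duration_s = x@durationS))
  invisible(path)
}

#' @rdname writeSpikeTable
#' @export
readSpikeTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  side <- readSidecar(path, "spike_table")
  layout <- layoutFromList(side$layout)
  dt <- data.table::fread(path)
  if (!all(c("electrode_id", "timestamp_s") %in% names(dt)))
    stop("malformed spike CSV: need columns electrode_id, timestamp_s, got: ",
         paste(names(dt), collapse = ", "))
  dt$electrode_id <- as.character(dt$electrode_id)
  dt$timestamp_s <- as.numeric(dt$timestamp_s)
  if (nrow(dt) && any(!is.finite(dt$timestamp_s)))
    stop("malformed spike CSV: non-finite values in field timestamp_s")
  known <- layout@electrodes$electrode_id
  bad <- setdiff(unique(dt$electrode_id), known)
  if (length(bad))
    stop("spike CSV field electrode_id contains ids absent from the layout: ",
         paste(bad, collapse = ", "))
  spikes <- stats::setNames(rep(list(numeric(0)), length(known)), known)
  if (nrow(dt)) {
    sp <- split(dt$timestamp_s, dt$electrode_id)
    for (id in names(sp)) spikes[[id]] <- sort(sp[[id]])
  }
  md <- side$metadata
  if (is.null(md) || (is.list(md) && !length(md))) md <- list()
  new("SpikeTable", spikes = spikes, layout = layout,
      durationS = as.numeric(side$duration_s), metadata = as.list(md))
}

#' Read and write raw recordings
#'
#' A \code{\linkS4class{Recording}} is stored as a Feather file (one column
#' of double-precision samples per electrode; lossless and compact) plus a
#' JSON sidecar \code{<path>.json} with sampling rate, layout and metadata.
#'
#' @param x a \code{\linkS4class{Recording}}.
#' @param path Feather file path.
#' @return \code{writeRecording} returns \code{path} invisibly;
#'   \code{readRecording} the reconstructed \code{\linkS4class{Recording}}.
#' @export
writeRecording <- function(x, path) {
  stopifnot(is(x, "Recording"))
  validObject(x)
  df <- as.data.frame(x@traces, check.names = FALSE, optional = TRUE)
  arrow::write_feather(df, path)
  writeSidecar(path, "recording", x@layout, x@metadata,
               list(sampling_rate_hz = x@samplingRateHz,
                    electrode_order = names(x@traces)))
  invisible(path)
}

#' @rdname writeRecording
#' @export
readRecording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  side <- readSidecar(path, "recording")
  layout <- layoutFromList(side$layout)
  df <- as.data.frame(arrow::read_feather(path))
  ord <- side$electrode_order
  if (!is.null(ord)) {
    miss <- setdiff(ord, names(df))
    if (length(miss))
      stop("recording file is missing electrode column(s): ",
           paste(miss, collapse = ", "))
    df <- df[, ord, drop = FALSE]
  }
  md <- side$metadata
  if (is.null(md) || (is.list(md) && !length(md))) md <- list()
  new("Recording",
    traces = as.list(df),
    samplingRateHz = as.numeric(side$sampling_rate_hz),
    layout = layout, metadata = as.list(md)
  )
}
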