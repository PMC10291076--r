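# Plain-text persistence: one CSV per recording (channels x samples, one
# row per channel) plus a JSON metadata sidecar with labels, layout and
# sampling rate.

layoutToList <- function(layout) {
  list(arrays = layout@arrays, map = layout@map,
       sourceChannels = attr(layout, "sourceChannels"))
}

layoutFromList <- function(x) {
  arrays <- as.data.frame(x$arrays)
  if (is.null(arrays$spacing)) arrays$spacing <- NA_real_
  lay <- new("ElectrodeLayout",
    arrays = arrays, map = as.data.frame(x$map))
  if (!is.null(x$sourceChannels))
    attr(lay, "sourceChannels") <- as.integer(x$sourceChannels)
  lay
}

#' Write / read one recording as CSV + JSON sidecar
#'
#' @param recording an [EmgRecording-class].
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return the path (write) or the recording (read).
#' @export
writeRecording <- function(recording, path) {
  utils::write.table(recording@signal, path, sep = ",", row.names = FALSE,
    col.names = FALSE)
  meta <- list(samplingRate = recording@samplingRate,
    subject = recording@subject, trial = recording@trial,
    gesture = recording@gesture, repetition = recording@repetition,
    layout = layoutToList(recording@layout))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
    na = "null"), paste0(path, ".json"))
  invisible(path)
}

#' @rdname writeRecording
#' @export
readRecording <- function(path) {
  sig <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(sig) <- NULL
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  new("EmgRecording", signal = sig, samplingRate = meta$samplingRate,
    subject = as.integer(meta$subject), trial = as.integer(meta$trial),
    gesture = as.integer(meta$gesture),
    repetition = as.integer(meta$repetition),
    layout = layoutFromList(meta$layout))
}

#' Write / read a dataset directory
#'
#' One CSV + sidecar per recording, named by its labels.
#'
#' @param dataset list of [EmgRecording-class].
#' @param dir directory (created if needed).
#' @return `dir` (write) or the list of recordings (read).
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in dataset)
    writeRecording(rec, file.path(dir, sprintf(
      "s%02d_t%02d_g%02d_r%02d.csv", rec@subject, rec@trial, rec@gesture,
      rec@repetition)))
  invisible(dir)
}

#' @rdname writeDataset
#' @export
readDataset <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  lapply(files, readRecording)
}

#' Export per-sample spike release rates as CSV
#'
#' @param samples a spike [SampleSet-class].
#' @param path CSV path.
#' @export
writeSrrCsv <- function(samples, path) {
  stopifnot(samples@kind == "spike")
  d <- samples@data
  srr <- apply(d, 3, sum) / (dim(d)[1] * dim(d)[2])
  utils::write.csv(cbind(samples@labels, srr = srr), path,
    row.names = FALSE)
  invisible(path)
}

#' Export feature samples as CSV
#'
#' One row per sample: labels followed by the flattened channels x 4
#' feature matrix (MAV, VAR, WL, ZC blocks).
#'
#' @param samples a feature [SampleSet-class].
#' @param path CSV path.
#' @export
writeFeatureCsv <- function(samples, path) {
  stopifnot(samples@kind == "feature")
  fm <- featureMatrix(samples)
  ch <- dim(samples@data)[1]
  colnames(fm) <- paste0(rep(c("mav", "var", "wl", "zc"), each = ch),
    "_ch", rep(seq_len(ch), 4))
  utils::write.csv(cbind(samples@labels, fm), path, row.names = FALSE)
  invisible(path)
}
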