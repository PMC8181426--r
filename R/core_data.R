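# On-disk container and class subsetting for EmgDataset objects.

#' Save an EmgDataset to a single-file container
#'
#' Validates the dataset, then serializes it to one self-describing file
#' that round-trips bit-exactly through \code{\link{loadEmgDataset}}.
#'
#' @param dataset an \linkS4class{EmgDataset}.
#' @param path file path to write.
#' @return Invisibly, \code{path}.
#' @export
saveEmgDataset <- function(dataset, path) {
  stopifnot(is(dataset, "EmgDataset"))
  validObject(dataset)
  payload <- list(
    format = "emgadapt-dataset",
    version = 1L,
    classNames = dataset@classNames,
    channelCount = dataset@channelCount,
    samplingRate = dataset@samplingRate,
    recordings = lapply(dataset@recordings, function(r) list(
      subjectId = r@subjectId,
      gestureId = r@gestureId,
      repetitionId = r@repetitionId,
      samplingRate = r@samplingRate,
      signal = r@signal))
  )
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  saveRDS(payload, con)
  invisible(path)
}

#' Load an EmgDataset container
#'
#' @param path file written by \code{\link{saveEmgDataset}}.
#' @return An \linkS4class{EmgDataset} satisfying all invariants.
#' @export
loadEmgDataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  payload <- readRDS(path)
  required <- c("format", "classNames", "channelCount", "samplingRate",
                "recordings")
  missing <- setdiff(required, names(payload))
  if (!is.list(payload) || length(missing))
    stop("malformed container: missing field(s) ",
         paste(missing, collapse = ", "))
  if (!identical(payload$format, "emgadapt-dataset"))
    stop("malformed container: field 'format' is not 'emgadapt-dataset'")
  recs <- lapply(payload$recordings, function(p) {
    rf <- setdiff(c("subjectId", "gestureId", "repetitionId",
                    "samplingRate", "signal"), names(p))
    if (length(rf))
      stop("malformed container: recording missing field(s) ",
           paste(rf, collapse = ", "))
    EmgRecording(p$signal, p$subjectId, p$gestureId, p$repetitionId,
                 p$samplingRate)
  })
  ds <- EmgDataset(recs, payload$classNames)
  validObject(ds)
  ds
}

#' Subset an EmgDataset to a set of gesture classes
#'
#' Keeps only recordings of the named classes and re-indexes gesture
#' labels densely (0, 1, ...) in the order of \code{keep}. Signals pass
#' through bit-exactly.
#'
#' @param dataset an \linkS4class{EmgDataset}.
#' @param keep character vector of class names to retain (subset of
#'   \code{classNames(dataset)}).
#' @return A new \linkS4class{EmgDataset} with \code{classNames = keep}.
#' @examples
#' cfg <- simConfig(nSubjects = 1, nGestures = 3, nRepetitions = 2,
#'                  nChannels = 2, durationS = 0.3, seed = 1)
#' ds <- generateDataset(cfg)
#' selectClasses(ds, classNames(ds)[c(1, 3)])
#' @export
selectClasses <- function(dataset, keep) {
  stopifnot(is(dataset, "EmgDataset"))
  unknown <- setdiff(keep, dataset@classNames)
  if (length(unknown))
    stop("unknown class name(s): ", paste(unknown, collapse = ", "))
  oldIdx <- match(keep, dataset@classNames) - 1L   # zero-based old labels
  recs <- list()
  for (r in dataset@recordings) {
    pos <- match(r@gestureId, oldIdx)
    if (!is.na(pos)) {
      r@gestureId <- pos - 1L
      recs[[length(recs) + 1L]] <- r
    }
  }
  ds <- EmgDataset(recs, keep)
  validObject(ds)
  ds
}

#' Export one recording as delimited text
#'
#' Writes one row per sample and one column per channel (tab-separated,
#' with a header of channel names) for interoperability with other tools.
#'
#' @param recording an \linkS4class{EmgRecording}.
#' @param path file path to write.
#' @return Invisibly, \code{path}.
#' @export
exportRecordingText <- function(recording, path) {
  stopifnot(is(recording, "EmgRecording"))
  m <- t(recording@signal)
  colnames(m) <- paste0("ch", seq_len(ncol(m)))
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
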