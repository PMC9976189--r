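# Bonn-style ASCII signal I/O: one amplitude sample per line.

.parseLabel <- function(label) {
  if (length(label) != 1L) stop("label must be a single value")
  if (is.na(label)) return(NA_integer_)
  if (is.character(label)) {
    lab <- switch(tolower(label),
                  ictal = , s = , "+1" = , "1" = 1L,
                  interictal = , f = , "-1" = -1L,
                  unknown = NA_integer_,
                  stop("unknown label '", label,
                       "'; use 'ictal', 'interictal', 'unknown' or +1/-1"))
    return(lab)
  }
  lab <- as.integer(label)
  if (!lab %in% c(-1L, 1L)) stop("numeric labels must be +1 or -1")
  lab
}

#' Read a Bonn-style ASCII signal file
#'
#' Bonn EEG records are distributed as plain text, one amplitude value per
#' line.  Blank lines and surrounding whitespace are ignored (tolerating
#' OS line-ending differences); any other non-numeric line is a parse
#' error reporting its line number.
#'
#' @param path path to the ASCII file.
#' @param label class label: \code{"ictal"}/\code{+1}, \code{"interictal"}/
#'   \code{-1} or \code{"unknown"}/\code{NA}.
#' @param samplingRate sampling rate in Hz; Bonn records were digitised at
#'   173.61 Hz.
#' @return an [EEGRecord-class]; \code{recordId} is the file name without
#'   extension.
#' @seealso [writeBonnAscii()], [loadDataset()]
#' @export
readBonnAscii <- function(path, label = NA, samplingRate = 173.61) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  keep <- nzchar(trimmed)
  if (!any(keep)) stop("empty input: '", path, "' contains no samples")
  vals <- suppressWarnings(as.numeric(trimmed[keep]))
  if (anyNA(vals)) {
    bad <- which(keep)[which(is.na(vals))[1L]]
    stop("parse error in '", path, "' at line ", bad, ": '",
         lines[bad], "' is not a number")
  }
  if (!all(is.finite(vals)))
    stop("non-finite sample value in '", path, "'")
  EEGRecord(vals, samplingRate = samplingRate, label = .parseLabel(label),
            recordId = sub("\\.[^.]*$", "", basename(path)))
}

#' Write an EEGRecord as Bonn-style ASCII
#'
#' One sample per line, serialised with 17 significant digits so a
#' read/write round trip reproduces the samples exactly.
#'
#' @param record an [EEGRecord-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeBonnAscii <- function(record, path) {
  stopifnot(is(record, "EEGRecord"))
  writeLines(sprintf("%.17g", record@samples), path)
  invisible(path)
}

#' Load a labelled dataset from per-class directories
#'
#' Reads every file in each class directory as a Bonn-style ASCII signal.
#' Record order is deterministic: classes in the fixed order ictal then
#' interictal, files sorted by name within a class.  Mixed record lengths
#' are permitted (decomposition and entropy are length-agnostic) but
#' trigger a warning.
#'
#' @param directories named character vector or list mapping class names
#'   (\code{"ictal"}, \code{"interictal"}) to directories of signal files.
#' @param samplingRate sampling rate applied to every record.
#' @param pattern optional regular expression filtering file names.
#' @return an [EEGDataset-class].
#' @export
loadDataset <- function(directories, samplingRate = 173.61, pattern = NULL) {
  dirs <- as.list(directories)
  if (is.null(names(dirs)) || !all(nzchar(names(dirs))))
    stop("directories must be named by class ('ictal', 'interictal')")
  bad <- setdiff(names(dirs), c("ictal", "interictal"))
  if (length(bad))
    stop("unknown class name(s): ", paste(bad, collapse = ", "))
  if (length(dirs) < 2L)
    warning("only one class provided; the dataset will be single-class")
  recs <- list()
  for (cls in intersect(c("ictal", "interictal"), names(dirs))) {
    d <- dirs[[cls]]
    if (!dir.exists(d)) stop("directory '", d, "' does not exist")
    files <- sort(list.files(d, pattern = pattern, full.names = TRUE))
    files <- files[!dir.exists(files)]
    if (length(files) == 0L)
      stop("directory '", d, "' contains no signal files")
    recs <- c(recs, lapply(files, readBonnAscii, label = cls,
                           samplingRate = samplingRate))
  }
  lens <- vapply(recs, function(r) length(r@samples), integer(1))
  if (length(unique(lens)) > 1L)
    warning("records have mixed lengths (", min(lens), "-", max(lens),
            " samples); this is permitted but unusual for Bonn-style data")
  EEGDataset(recs)
}

#' Read signals from a one-row-per-record CSV
#'
#' Alternative input dialect: first column \code{record_id}, second column
#' \code{label} (+1/-1), remaining columns the amplitude samples.
#'
#' @param path CSV file path.
#' @param samplingRate sampling rate applied to every record.
#' @return an [EEGDataset-class].
#' @export
readSignalCSV <- function(path, samplingRate = 173.61) {
  df <- read.csv(path, header = TRUE, check.names = FALSE)
  if (ncol(df) < 3L)
    stop("signal CSV needs record_id, label and at least one sample column")
  recs <- lapply(seq_len(nrow(df)), function(i) {
    vals <- as.numeric(df[i, -(1:2)])
    vals <- vals[!is.na(vals)]  # ragged rows padded with empty cells
    EEGRecord(vals, samplingRate = samplingRate,
              label = .parseLabel(df[[2L]][i]),
              recordId = as.character(df[[1L]][i]))
  })
  EEGDataset(recs)
}

#' Write a dataset as a tree of Bonn-style ASCII files
#'
#' Creates one subdirectory per class under \code{dir} and writes each
#' record as a one-sample-per-line text file, making synthetic data a
#' drop-in replacement for a downloaded Bonn-style directory layout.
#'
#' @param dataset an [EEGDataset-class].
#' @param dir output directory (created if missing).
#' @return named character vector of the class directories, invisibly.
#' @seealso [generateDataset()], [loadDataset()]
#' @export
writeDatasetAscii <- function(dataset, dir) {
  stopifnot(is(dataset, "EEGDataset"))
  labs <- classLabels(dataset)
  cls <- ifelse(is.na(labs), "unknown",
                ifelse(labs == 1L, "ictal", "interictal"))
  out <- character()
  for (cl in unique(cls)) {
    sub <- file.path(dir, cl)
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    out[cl] <- sub
  }
  for (i in seq_along(dataset@records)) {
    rec <- dataset@records[[i]]
    writeBonnAscii(rec, file.path(out[cls[i]],
                                  paste0(rec@recordId, ".txt")))
  }
  invisible(out)
}
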