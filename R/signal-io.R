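## Waveform CSV I/O. The instrument export convention: one amplitude value
## per line, and the binary class label ("1" intact, "0" slight crack)
## appended as the final line of the file. No header.

#' Read one per-seed waveform CSV file
#'
#' Parses a single-column CSV of amplitude values. When \code{labelled} is
#' TRUE (the dataset convention) the final line must be exactly 0 or 1 and
#' becomes the class label; all preceding lines are the amplitude sequence.
#' Scientific notation is accepted; NaN and infinities are rejected.
#'
#' @param path path to the CSV file.
#' @param labelled whether a trailing class label is expected (default TRUE).
#' @return An [UltrasoundRecord-class]; \code{sampleId} is the file stem.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeSignalCsv(ultrasoundRecord(c(0.1, -0.2, 0.3), label = 1), f)
#' readSignalCsv(f)
#' @seealso [writeSignalCsv()], [loadDataset()]
#' @export
readSignalCsv <- function(path, labelled = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- trimws(lines[keep])
  if (length(lines) == 0L) stop("format error in '", path, "': file is empty")
  vals <- suppressWarnings(as.numeric(lines))
  bad <- which(is.na(vals) | !is.finite(vals))
  if (length(bad))
    stop("format error in '", path, "': line ", lineNo[bad[1]],
         " does not parse as a finite number ('", lines[bad[1]], "')")
  stem <- sub("\\.[^.]*$", "", basename(path))
  if (labelled) {
    n <- length(vals)
    lab <- vals[n]
    if (!lab %in% c(0, 1))
      stop("label error in '", path, "': final line must be 0 or 1, got '",
           lines[n], "'")
    if (n < 2L)
      stop("format error in '", path, "': no amplitude values before label")
    ultrasoundRecord(vals[-n], label = as.integer(lab), sampleId = stem)
  } else {
    ultrasoundRecord(vals, label = NA, sampleId = stem)
  }
}

#' Write one waveform CSV file
#'
#' Inverse of [readSignalCsv()]: one amplitude per line at full precision
#' (17 significant digits, so the read-back reproduces the record exactly),
#' with the label appended as a final line when present.
#'
#' @param record an [UltrasoundRecord-class].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeSignalCsv <- function(record, path) {
  stopifnot(is(record, "UltrasoundRecord"))
  validObject(record)
  lines <- sprintf("%.17g", record@amplitudes)
  if (!is.na(record@label)) lines <- c(lines, as.character(record@label))
  tryCatch(writeLines(lines, path),
           error = function(e) stop("cannot write '", path, "': ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Load a directory of waveform CSV files
#'
#' Reads every \code{*.csv} file in a flat directory, in a deterministic
#' byte-wise (C-locale) lexicographic filename order that is independent of
#' the filesystem's enumeration order. All records must share one length L.
#'
#' @param directory dataset directory.
#' @param labelled passed to [readSignalCsv()] (default TRUE).
#' @return List of [UltrasoundRecord-class] objects.
#' @export
loadDataset <- function(directory, labelled = TRUE) {
  if (!dir.exists(directory)) stop("directory not found: ", directory)
  files <- list.files(directory, pattern = "\\.[cC][sS][vV]$",
                      full.names = TRUE)
  if (length(files) == 0L)
    stop("empty dataset: no CSV files in '", directory, "'")
  files <- files[order(basename(files), method = "radix")]
  records <- lapply(files, readSignalCsv, labelled = labelled)
  lens <- vapply(records, function(r) length(r@amplitudes), integer(1))
  if (length(unique(lens)) != 1L)
    stop("shape error: records have inconsistent lengths (",
         paste(sort(unique(lens)), collapse = ", "), ")")
  records
}
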