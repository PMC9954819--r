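# CHB-MIT style plain-text seizure annotation summaries.
#
# The dialect is line-oriented:
#
#   File Name: subj_01.edf
#   Number of Seizures in File: 1
#   Seizure 1 Start Time: 2996 seconds
#   Seizure 1 End Time: 3036 seconds
#
# Times are seconds from the start of the named file; intervals are
# half-open [onset, offset).

#' Parse a CHB-MIT style seizure annotation summary
#'
#' Extracts `Seizure ... Start Time` / `Seizure ... End Time` line pairs
#' (optionally restricted to one `File Name:` block) into a data.frame of
#' seizure intervals in seconds from record start, sorted by onset.
#'
#' @param path summary text file.
#' @param fileName optional EDF file name; when given, only the matching
#'   `File Name:` block is parsed.
#' @return data.frame with columns `onset_s`, `offset_s`, `label`
#'   (all `"ictal"`), sorted by onset; zero rows when the file declares no
#'   seizures.
#' @export
parseAnnotationSummary <- function(path, fileName = NULL) {
  if (!file.exists(path)) stop("cannot read annotation summary: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!is.null(fileName)) {
    starts <- grep("^\\s*File Name\\s*:", lines)
    if (length(starts)) {
      names_ <- trimws(sub("^\\s*File Name\\s*:", "", lines[starts]))
      hit <- which(names_ == fileName)
      if (length(hit) == 0)
        stop("file '", fileName, "' not found in summary ", path)
      from <- starts[hit[1]]
      to <- if (hit[1] < length(starts)) starts[hit[1] + 1] - 1 else length(lines)
      lines <- lines[from:to]
    }
  }
  startPat <- "^\\s*Seizure\\s*[0-9]*\\s*Start Time\\s*:\\s*([0-9.]+).*$"
  endPat <- "^\\s*Seizure\\s*[0-9]*\\s*End Time\\s*:\\s*([0-9.]+).*$"
  sLines <- grep(startPat, lines)
  eLines <- grep(endPat, lines)
  if (length(sLines) != length(eLines))
    stop("malformed summary: ", length(sLines), " start line(s) but ",
         length(eLines), " end line(s)")
  onset <- as.numeric(sub(startPat, "\\1", lines[sLines]))
  offset <- as.numeric(sub(endPat, "\\1", lines[eLines]))
  for (i in seq_along(onset)) {
    if (offset[i] <= onset[i])
      stop(sprintf(
        "malformed summary: seizure block %d ends at %g s, at or before its start %g s",
        i, offset[i], onset[i]))
  }
  ann <- data.frame(onset_s = onset, offset_s = offset,
                    label = rep("ictal", length(onset)),
                    stringsAsFactors = FALSE)
  declared <- grep("^\\s*Number of Seizures in File\\s*:", lines, value = TRUE)
  if (length(declared)) {
    ndecl <- sum(as.numeric(trimws(sub(".*:", "", declared))))
    if (ndecl != nrow(ann))
      warning("summary declares ", ndecl, " seizure(s) but lists ", nrow(ann))
  }
  ann <- ann[order(ann$onset_s), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Write a seizure annotation summary for one recording
#'
#' Emits the same dialect that [parseAnnotationSummary()] reads, so
#' synthetic cohorts exercise the real ingestion path.
#'
#' @param rec an [EEGRecording-class].
#' @param path output text file.
#' @param edfName file name to declare in the `File Name:` line.
#' @return `path`, invisibly.
#' @export
writeAnnotationSummary <- function(rec, path, edfName = basename(path)) {
  ann <- annotations(rec)
  lines <- c(sprintf("Data Sampling Rate: %g Hz", samplingRate(rec)), "",
             sprintf("File Name: %s", edfName),
             sprintf("Number of Seizures in File: %d", nrow(ann)))
  for (i in seq_len(nrow(ann))) {
    lines <- c(lines,
               sprintf("Seizure %d Start Time: %.6f seconds", i, ann$onset_s[i]),
               sprintf("Seizure %d End Time: %.6f seconds", i, ann$offset_s[i]))
  }
  writeLines(lines, path)
  invisible(path)
}
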