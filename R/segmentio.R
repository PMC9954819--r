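# Portable binary container for SegmentSet objects.
#
# Layout (little-endian): 10-byte magic "DEEPEEGSEG", int32 version,
# int32 dims (n, channels, samples), doubles fs and segment length,
# int32 normalisation flag (+ parameters when present), int32 labels,
# the segment tensor as doubles, and a length-prefixed JSON provenance
# string. Self-describing and versioned so incompatible files fail loudly
# rather than load garbage.

.SEG_MAGIC <- "DEEPEEGSEG"
.SEG_VERSION <- 1L

#' Save a SegmentSet to a versioned binary container
#'
#' @param segments a [SegmentSet-class].
#' @param path output path.
#' @param metadata optional named list of provenance fields stored as JSON.
#' @return `path`, invisibly.
#' @export
saveSegmentSet <- function(segments, path, metadata = list()) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(.SEG_MAGIC, con, eos = NULL, useBytes = TRUE)
  writeBin(.SEG_VERSION, con, size = 4, endian = "little")
  d <- dim(segmentTensor(segments))
  writeBin(as.integer(d), con, size = 4, endian = "little")
  writeBin(c(samplingRate(segments), segmentLength(segments)), con,
           size = 8, endian = "little")
  np <- normalizationParams(segments)
  if (is.null(np)) {
    writeBin(0L, con, size = 4, endian = "little")
  } else {
    writeBin(1L, con, size = 4, endian = "little")
    writeBin(length(np@mu), con, size = 4, endian = "little")
    writeBin(c(np@mu, np@sigma, np@globalMin, np@globalMax), con,
             size = 8, endian = "little")
  }
  writeBin(segmentLabels(segments), con, size = 4, endian = "little")
  writeBin(as.vector(segmentTensor(segments)), con, size = 8,
           endian = "little")
  meta <- as.character(jsonlite::toJSON(metadata, auto_unbox = TRUE))
  writeBin(nchar(meta, type = "bytes"), con, size = 4, endian = "little")
  writeChar(meta, con, eos = NULL, useBytes = TRUE)
  invisible(path)
}

#' Load a SegmentSet from its binary container
#'
#' @param path file written by [saveSegmentSet()].
#' @return A list with elements `segments` (the [SegmentSet-class], bitwise
#'   identical to what was saved) and `metadata` (the provenance list).
#' @export
loadSegmentSet <- function(path) {
  if (!file.exists(path)) stop("cannot read segment container: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  need <- function(x, n, what) {
    if (length(x) < n) stop("incompatible or truncated segment container (",
                            what, "): ", path)
    x
  }
  magic <- readChar(con, nchar(.SEG_MAGIC), useBytes = TRUE)
  if (!identical(magic, .SEG_MAGIC))
    stop("incompatible container: bad magic in ", path)
  version <- need(readBin(con, integer(), 1, size = 4, endian = "little"),
                  1, "version")
  if (version != .SEG_VERSION)
    stop("incompatible container version ", version, " (expected ",
         .SEG_VERSION, ") in ", path)
  d <- need(readBin(con, integer(), 3, size = 4, endian = "little"), 3, "dims")
  hdr <- need(readBin(con, double(), 2, size = 8, endian = "little"), 2, "rate")
  hasNorm <- need(readBin(con, integer(), 1, size = 4, endian = "little"),
                  1, "flag")
  np <- NULL
  if (hasNorm == 1L) {
    nc <- need(readBin(con, integer(), 1, size = 4, endian = "little"),
               1, "norm size")
    v <- need(readBin(con, double(), 2 * nc + 2, size = 8, endian = "little"),
              2 * nc + 2, "norm params")
    np <- new("NormalizationParams", mu = v[seq_len(nc)],
              sigma = v[nc + seq_len(nc)], globalMin = v[2 * nc + 1],
              globalMax = v[2 * nc + 2])
  }
  labels <- need(readBin(con, integer(), d[1], size = 4, endian = "little"),
                 d[1], "labels")
  tensor <- need(readBin(con, double(), prod(d), size = 8, endian = "little"),
                 prod(d), "tensor")
  dim(tensor) <- d
  mlen <- need(readBin(con, integer(), 1, size = 4, endian = "little"),
               1, "metadata length")
  meta <- readChar(con, mlen, useBytes = TRUE)
  if (is.na(nchar(meta)) || nchar(meta, type = "bytes") < mlen)
    stop("incompatible or truncated segment container (metadata): ", path)
  list(segments = .segmentSet(tensor, labels, hdr[1], hdr[2], np),
       metadata = jsonlite::fromJSON(meta))
}
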