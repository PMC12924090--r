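#' Retained volume indices for interleaved rest extraction
#'
#' Selects the volumes of a blocked task scan that count as rest, following
#' the interleaved-data approach: discard the first
#' \code{nDiscardScanStart} volumes of the scan's first rest block (signal
#' equilibration; this replaces, rather than adds to, the per-rest-block
#' discard), keep the first \code{nKeepTaskStart} volumes of every task block
#' (the haemodynamic response has not yet risen), and discard the first
#' \code{nDiscardRestStart} volumes of every non-initial rest block (waiting
#' for the task response to return to baseline). All other rest volumes are
#' kept; all other task volumes are dropped.
#'
#' Indices are 0-based (volume 0 = first acquired volume), matching the
#' convention of the extraction arithmetic and of the sidecar files.
#'
#' @param design a \linkS4class{BlockDesign} with contiguous rest/task blocks.
#' @param scheme an \linkS4class{ExtractionScheme}.
#' @return Strictly increasing integer vector of retained 0-based indices.
#' @examples
#' idx <- restVolumeIndices(makeBlockDesign(taskProtocol()), fairScheme())
#' length(idx)  # 72
#' @export
restVolumeIndices <- function(design, scheme) {
  stopifnot(is(design, "BlockDesign"), is(scheme, "ExtractionScheme"))
  validObject(scheme)
  labels <- designLabels(design)
  r <- rle(labels)
  starts0 <- cumsum(c(0L, r$lengths[-length(r$lengths)]))  # 0-based block starts
  restBlocks <- which(r$values == "rest")
  firstRest <- if (length(restBlocks)) restBlocks[1] else NA_integer_

  kept <- integer(0)
  for (b in seq_along(r$lengths)) {
    len <- r$lengths[b]
    s0 <- starts0[b]
    if (r$values[b] == "rest") {
      nd <- if (b == firstRest) scheme@nDiscardScanStart else scheme@nDiscardRestStart
      if (len < nd)
        stop(sprintf("block %d (rest, %d volumes) is shorter than its discard count %d",
                     b, len, nd))
      if (len > nd) kept <- c(kept, (s0 + nd):(s0 + len - 1L))
    } else {
      nk <- scheme@nKeepTaskStart
      if (len < nk)
        stop(sprintf("block %d (task, %d volumes) is shorter than its keep count %d",
                     b, len, nk))
      if (nk > 0L) kept <- c(kept, s0:(s0 + nk - 1L))
    }
  }
  kept <- sort(unique(as.integer(kept)))
  if (length(kept) == 0L) stop("extraction retained no volumes")
  kept
}

#' Extract volumes from a scan by index
#'
#' Returns a new scan whose volume k is the input's volume \code{indices[k]}.
#' The ORIGINAL acquisition times are preserved on the result, so downstream
#' code can detect the non-uniform temporal spacing of interleaved rest data
#' (frequency-domain operations refuse to run on such scans).
#'
#' @param scan a \linkS4class{BoldScan}.
#' @param indices strictly increasing 0-based volume indices.
#' @return A \linkS4class{BoldScan} with \code{length(indices)} volumes.
#' @export
extractVolumes <- function(scan, indices) {
  stopifnot(is(scan, "BoldScan"))
  nt <- dim(scan@data)[4]
  indices <- as.integer(indices)
  if (length(indices) == 0L) stop("indices must be non-empty")
  if (any(indices < 0L) || any(indices >= nt))
    stop(sprintf("volume index out of range [0, %d)", nt))
  if (any(diff(indices) <= 0)) stop("indices must be strictly increasing")
  BoldScan(scan@data[, , , indices + 1L, drop = FALSE], trS = scan@trS,
           affine = scan@affine, volumeTimesS = scan@volumeTimesS[indices + 1L])
}

#' Middle-segment subsampling of a continuous scan
#'
#' Keeps a contiguous segment of \code{n} volumes starting at 0-based index
#' \code{floor((T - n) / 2)} for a scan of T volumes, used to match the
#' continuous rest scan's length to the intermittent rest data.
#'
#' @param scan a \linkS4class{BoldScan}.
#' @param n target volume count (0 < n <= T).
#' @return A \linkS4class{BoldScan} of \code{n} volumes with original
#'   acquisition times preserved.
#' @examples
#' # 170-volume rest scan -> middle 72 volumes start at index 49
#' @export
middleSubsample <- function(scan, n) {
  stopifnot(is(scan, "BoldScan"))
  nt <- dim(scan@data)[4]
  n <- as.integer(n)
  if (n <= 0L) stop("n must be positive")
  if (n > nt) stop(sprintf("n (%d) exceeds the scan's %d volumes", n, nt))
  start0 <- (nt - n) %/% 2L
  extractVolumes(scan, start0:(start0 + n - 1L))
}

#' Write retained indices as a sidecar file
#'
#' @param indices 0-based retained volume indices.
#' @param path output path; format by extension (.json or plain text, one
#'   index per line).
#' @return Invisibly, \code{path}.
#' @export
writeIndexSidecar <- function(indices, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.integer(indices), path)
  } else {
    writeLines(as.character(as.integer(indices)), path)
  }
  invisible(path)
}
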