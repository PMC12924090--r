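#' Load a 4-D BOLD scan from a NIfTI-1 file
#'
#' Reads a 4-D NIfTI image and attaches the repetition time. Per-volume
#' acquisition times are initialised to \code{i * trS} for volume index i
#' (0-based, volume 0 = first acquired volume).
#'
#' @param path path to a readable NIfTI-1 (.nii / .nii.gz) file.
#' @param trS repetition time in seconds; if NULL, taken from the file header
#'   (pixdim of the 4th dimension) when positive.
#' @return A \linkS4class{BoldScan}.
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' saveScan(BoldScan(array(rnorm(8 * 8 * 6 * 10), c(8, 8, 6, 10)), trS = 3), f)
#' loadScan(f, trS = 3)
#' @export
loadScan <- function(path, trS = NULL) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop(sprintf("expected a 4-D image, got %d dimensions", length(d)))
  if (is.null(trS)) {
    pd <- RNifti::pixdim(img)
    if (length(pd) >= 4 && is.finite(pd[4]) && pd[4] > 0) trS <- pd[4]
    else stop("trS not given and not recoverable from the header")
  }
  aff <- structure(RNifti::xform(img), code = NULL)
  BoldScan(data = array(as.numeric(img), d), trS = trS,
           affine = matrix(as.numeric(aff), 4, 4),
           volumeTimesS = (seq_len(d[4]) - 1) * trS)
}

#' Write a BoldScan to a NIfTI-1 file
#'
#' Data are stored as float32 (the package computes in double internally);
#' the affine is written as the sform/qform and the TR as the temporal pixdim.
#'
#' @param scan a \linkS4class{BoldScan}.
#' @param path output path (.nii or .nii.gz); the parent directory must exist.
#' @return Invisibly, \code{path}.
#' @export
saveScan <- function(scan, path) {
  stopifnot(is(scan, "BoldScan"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(scan@data)
  RNifti::qform(img) <- structure(scan@affine, code = 2L)
  RNifti::sform(img) <- structure(scan@affine, code = 2L)
  vox <- sqrt(colSums(scan@affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- c(vox, scan@trS)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Write a 3-D volume (mask, label map, statistic map) as NIfTI
#'
#' @param vol 3-D array (logical arrays are written as 0/1 integers).
#' @param affine 4x4 voxel-to-mm matrix.
#' @param path output path.
#' @param datatype storage datatype passed to \code{RNifti::writeNifti}.
#' @return Invisibly, \code{path}.
#' @export
saveVolume <- function(vol, affine, path, datatype = "float") {
  if (is.logical(vol)) {
    vol <- array(as.integer(vol), dim(vol))
    datatype <- "int16"
  }
  img <- RNifti::asNifti(vol)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Temporal signal-to-noise ratio map
#'
#' For every in-mask voxel, the temporal mean divided by the temporal standard
#' deviation (n - 1 denominator). Voxels with zero temporal variance get tSNR
#' 0 by convention so QC maps stay finite; out-of-mask voxels are 0.
#'
#' @param scan a \linkS4class{BoldScan} with at least 2 volumes.
#' @param mask a \linkS4class{BrainMask} on the scan's spatial grid.
#' @return A 3-D array of tSNR values.
#' @export
computeTsnr <- function(scan, mask) {
  stopifnot(is(scan, "BoldScan"), is(mask, "BrainMask"))
  checkSameGrid(scan@data, mask@data, "scan and mask")
  nt <- dim(scan@data)[4]
  if (nt < 2L) stop("tSNR needs at least 2 volumes (temporal sd undefined)")
  m <- asVoxelMatrix(scan@data)
  inmask <- which(mask@data)
  mu <- rowMeans(m[inmask, , drop = FALSE])
  s2 <- rowSums((m[inmask, , drop = FALSE] - mu)^2) / (nt - 1)
  s <- sqrt(s2)
  tsnr <- ifelse(s > 0, mu / s, 0)
  out <- array(0, dim(mask@data))
  out[inmask] <- tsnr
  out
}

#' Per-axis motion summary
#'
#' Simple QC summary of six rigid-body motion parameters: per-axis mean,
#' absolute maximum and mean framewise (backward-difference) displacement.
#'
#' @param motion6 time x 6 matrix (3 translations, 3 rotations).
#' @return A data.frame with one row per parameter.
#' @export
motionSummary <- function(motion6) {
  motion6 <- as.matrix(motion6)
  if (ncol(motion6) != 6L) stop("expected 6 motion parameters")
  nm <- colnames(motion6)
  if (is.null(nm)) nm <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  fd <- abs(apply(motion6, 2, function(x) c(0, diff(x))))
  data.frame(parameter = nm,
             mean = colMeans(motion6),
             maxAbs = apply(abs(motion6), 2, max),
             meanAbsDelta = colMeans(fd),
             row.names = NULL)
}
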