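#' ROI mean time series
#'
#' Per ROI, the unweighted mean over member voxels at each time point.
#'
#' @param scan a \linkS4class{BoldScan}.
#' @param atlas a \linkS4class{RoiAtlas} on the scan grid.
#' @return ROI x time numeric matrix with ROI names as row names.
#' @export
roiTimeseries <- function(scan, atlas) {
  stopifnot(is(scan, "BoldScan"), is(atlas, "RoiAtlas"))
  checkSameGrid(scan@data, atlas@labelMap, "scan and atlas")
  K <- length(atlas@roiNames)
  m <- asVoxelMatrix(scan@data)
  lab <- as.integer(atlas@labelMap)
  out <- matrix(NA_real_, K, ncol(m), dimnames = list(atlas@roiNames, NULL))
  for (k in seq_len(K)) {
    vox <- which(lab == k)
    if (length(vox) == 0L) stop("ROI '", atlas@roiNames[k], "' is empty")
    out[k, ] <- colMeans(m[vox, , drop = FALSE])
  }
  out
}

#' Fisher-z ROI-to-ROI connectivity matrix
#'
#' Pairwise Pearson correlations of the ROI series, Fisher z-transformed with
#' |r| clipped at 1 - 1e-7 so the transform stays finite; the (undefined)
#' diagonal is stored as 0. Invariant under positive affine rescaling of any
#' ROI series.
#'
#' @param ts ROI x time matrix (>= 3 time points, no constant rows), e.g. from
#'   \code{\link{roiTimeseries}}.
#' @return A \linkS4class{ConnectivityMatrix}.
#' @export
fisherZMatrix <- function(ts) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 3L) stop("need at least 3 time points")
  if (nrow(ts) < 2L) stop("need at least 2 ROIs")
  sds <- apply(ts, 1, stats::sd)
  if (any(sds == 0))
    stop("constant ROI series: ",
         paste(rownames(ts)[sds == 0], collapse = ", "))
  r <- stats::cor(t(ts))
  z <- fisherZ(r, warnClip = FALSE)
  diag(z) <- 0
  labels <- rownames(ts)
  if (is.null(labels)) labels <- sprintf("ROI%d", seq_len(nrow(ts)))
  ConnectivityMatrix(z, labels)
}

#' Voxelwise seed-based Fisher-z connectivity map
#'
#' Correlates the seed ROI's mean time series with every in-mask voxel series
#' and Fisher z-transforms the result (same clipping as
#' \code{\link{fisherZMatrix}}). Out-of-mask voxels are 0.
#'
#' @param scan a \linkS4class{BoldScan}.
#' @param atlas a \linkS4class{RoiAtlas} containing the seed.
#' @param seed seed ROI name.
#' @param mask analysis \linkS4class{BrainMask}.
#' @return A \linkS4class{SeedMap}.
#' @export
seedMap <- function(scan, atlas, seed, mask) {
  stopifnot(is(scan, "BoldScan"), is(atlas, "RoiAtlas"), is(mask, "BrainMask"))
  checkSameGrid(scan@data, mask@data, "scan and mask")
  if (!seed %in% atlas@roiNames) stop("seed ROI '", seed, "' not in atlas")
  k <- match(seed, atlas@roiNames)
  vox <- which(as.integer(atlas@labelMap) == k)
  if (length(vox) == 0L) stop("seed ROI '", seed, "' is empty")
  s <- colMeans(asVoxelMatrix(scan@data)[vox, , drop = FALSE])
  if (stats::sd(s) == 0) stop("seed ROI '", seed, "' has a constant series")
  nt <- length(s)
  inmask <- which(mask@data)
  Y <- t(asVoxelMatrix(scan@data)[inmask, , drop = FALSE])   # time x voxels
  Yc <- sweep(Y, 2, colMeans(Y))
  sc <- s - mean(s)
  denom <- sqrt(sum(sc^2)) * sqrt(colSums(Yc^2))
  r <- as.numeric(crossprod(sc, Yc)) / ifelse(denom > 0, denom, Inf)
  z <- fisherZ(r)
  out <- array(0, dim(mask@data))
  out[inmask] <- z
  new("SeedMap", mapData = out, seedName = seed, affine = scan@affine)
}

#' Write a connectivity matrix as TSV
#'
#' @param cm a \linkS4class{ConnectivityMatrix}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeConnectivityTsv <- function(cm, path) {
  m <- cm@values
  utils::write.table(data.frame(roi = cm@roiLabels, m, check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
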