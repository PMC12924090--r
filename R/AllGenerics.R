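# Accessor generics. Slot access from user code should go through these.

#' @export
setGeneric("scanData", function(x) standardGeneric("scanData"))
#' @export
setGeneric("scanAffine", function(x) standardGeneric("scanAffine"))
#' @export
setGeneric("trS", function(x) standardGeneric("trS"))
#' @export
setGeneric("volumeTimes", function(x) standardGeneric("volumeTimes"))
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))
#' @export
setGeneric("maskData", function(x) standardGeneric("maskData"))
#' @export
setGeneric("designLabels", function(x) standardGeneric("designLabels"))
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))
#' @export
setGeneric("zValues", function(x) standardGeneric("zValues"))
#' @export
setGeneric("spatialMaps", function(x) standardGeneric("spatialMaps"))
#' @export
setGeneric("mixingMatrix", function(x) standardGeneric("mixingMatrix"))
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))
#' @export
setGeneric("significantClusters", function(x) standardGeneric("significantClusters"))
#' @export
setGeneric("dctHighpass", function(x, trS, cutoffHz = 0.01, ...)
  standardGeneric("dctHighpass"))

#' Accessors for imaging and result containers
#'
#' \code{scanData} returns the voxel array; \code{scanAffine} the 4x4 affine;
#' \code{trS} the repetition time; \code{volumeTimes} the per-volume
#' acquisition times; \code{nVolumes} the number of volumes; \code{maskData}
#' the logical mask array; \code{designLabels} the per-volume condition
#' labels; \code{labelMap} the integer label volume of an atlas;
#' \code{roiLabels} the ROI names; \code{zValues} the Fisher-z matrix;
#' \code{spatialMaps}/\code{mixingMatrix} the ICA factors;
#' \code{clusterTable} the candidate-cluster table and
#' \code{significantClusters} its FDR-surviving rows.
#'
#' @param x the object.
#' @return See the individual descriptions.
#' @name accessors
#' @aliases scanData scanAffine trS volumeTimes nVolumes maskData designLabels
#'   labelMap roiLabels zValues spatialMaps mixingMatrix clusterTable
#'   significantClusters
NULL

#' @rdname accessors
setMethod("scanData", "BoldScan", function(x) x@data)
#' @rdname accessors
setMethod("scanAffine", "BoldScan", function(x) x@affine)
#' @rdname accessors
setMethod("scanAffine", "BrainMask", function(x) x@affine)
#' @rdname accessors
setMethod("scanAffine", "RoiAtlas", function(x) x@affine)
#' @rdname accessors
setMethod("scanAffine", "SeedMap", function(x) x@affine)
#' @rdname accessors
setMethod("trS", "BoldScan", function(x) x@trS)
#' @rdname accessors
setMethod("trS", "ScanProtocol", function(x) x@trS)
#' @rdname accessors
setMethod("volumeTimes", "BoldScan", function(x) x@volumeTimesS)
#' @rdname accessors
setMethod("nVolumes", "BoldScan", function(x) dim(x@data)[4])
#' @rdname accessors
setMethod("nVolumes", "ScanProtocol", function(x) x@nVolumes)
#' @rdname accessors
setMethod("maskData", "BrainMask", function(x) x@data)
#' @rdname accessors
setMethod("designLabels", "BlockDesign", function(x) x@labels)
#' @rdname accessors
setMethod("labelMap", "RoiAtlas", function(x) x@labelMap)
#' @rdname accessors
setMethod("labelMap", "TemplateAtlas", function(x) x@labelMap)
#' @rdname accessors
setMethod("labelMap", "GroundTruth", function(x) x@networkMap)
#' @rdname accessors
setMethod("roiLabels", "RoiAtlas", function(x) x@roiNames)
#' @rdname accessors
setMethod("roiLabels", "ConnectivityMatrix", function(x) x@roiLabels)
#' @rdname accessors
setMethod("zValues", "ConnectivityMatrix", function(x) x@values)
#' @rdname accessors
setMethod("spatialMaps", "ICADecomposition", function(x) x@spatialMaps)
#' @rdname accessors
setMethod("mixingMatrix", "ICADecomposition", function(x) x@mixing)
#' @rdname accessors
setMethod("clusterTable", "GroupComparison", function(x) x@clusters)
#' @rdname accessors
setMethod("significantClusters", "GroupComparison", function(x)
  x@clusters[x@clusters$significant, , drop = FALSE])

setMethod("show", "BoldScan", function(object) {
  d <- dim(object@data)
  cat(sprintf("BoldScan: %d x %d x %d voxels, %d volumes, TR %.3g s\n",
              d[1], d[2], d[3], d[4], object@trS))
  tt <- object@volumeTimesS
  uniform <- d[4] < 2 || max(abs(diff(tt) - object@trS)) < 1e-9
  cat(sprintf("  acquisition times %.1f..%.1f s (%s sampling)\n",
              tt[1], tt[length(tt)],
              if (uniform) "uniform" else "non-uniform"))
})

setMethod("show", "BrainMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("BrainMask: %d x %d x %d, %d in-mask voxels\n",
              d[1], d[2], d[3], sum(object@data)))
})

setMethod("show", "BlockDesign", function(object) {
  r <- rle(object@labels)
  cat(sprintf("BlockDesign: %d volumes, %d blocks (%s)\n",
              length(object@labels), length(r$lengths),
              paste(sprintf("%s:%d", r$values, r$lengths), collapse = " ")))
})

setMethod("show", "ExtractionScheme", function(object) {
  cat(sprintf(paste0("ExtractionScheme: discard %d at scan start; keep first %d",
                     " of each task block; discard first %d of each non-initial",
                     " rest block\n"),
              object@nDiscardScanStart, object@nKeepTaskStart,
              object@nDiscardRestStart))
})

setMethod("show", "ICADecomposition", function(object) {
  cat(sprintf("ICADecomposition: %d components, %d time points, %d in-mask voxels (seed %d)\n",
              object@nComponents, nrow(object@mixing),
              ncol(object@spatialMaps), object@seed))
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult: component %d matches '%s' with r = %.3f (sign %+d)\n",
              object@component, object@network, object@r, as.integer(object@sign)))
})

setMethod("show", "RoiAtlas", function(object) {
  sizes <- tabulate(object@labelMap[object@labelMap > 0],
                    nbins = length(object@roiNames))
  cat(sprintf("RoiAtlas: %d ROIs (%s)\n", length(object@roiNames),
              paste(sprintf("%s:%d", object@roiNames, sizes), collapse = " ")))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix: %d ROIs, Fisher-z range [%.3f, %.3f]\n",
              length(object@roiLabels),
              min(object@values[upper.tri(object@values)]),
              max(object@values[upper.tri(object@values)])))
})

setMethod("show", "SimilarityResult", function(object) {
  cat(sprintf("SimilarityResult (%s): rho = %.3f, p = %.4g (%d permutations)\n",
              object@method, object@rho, object@p, object@nIter))
})

setMethod("show", "GroupComparison", function(object) {
  nsig <- sum(object@clusters$significant)
  cat(sprintf(paste0("GroupComparison: df = %d, %d candidate clusters, %d",
                     " significant at cluster FDR q = %.2g (voxel p < %.3g,",
                     " %d permutations)\n"),
              as.integer(object@df), nrow(object@clusters), nsig,
              object@clusterQ, object@voxelPThreshold, object@nPerm))
})
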