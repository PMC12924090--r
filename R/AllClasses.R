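#' @import methods
NULL

# ---------------------------------------------------------------------------
# Core imaging containers
# ---------------------------------------------------------------------------

#' BoldScan: a 4-D BOLD time series
#'
#' Container for a 4-D (x, y, z, t) BOLD voxel grid together with its
#' voxel-to-world affine, the repetition time, and the per-volume acquisition
#' times. Acquisition times are carried explicitly so that scans produced by
#' interleaved rest extraction (non-uniform temporal spacing) can be detected
#' downstream; frequency-domain operations refuse to run on them.
#'
#' @slot data numeric 4-D array (x, y, z, t) of signal values, arbitrary units.
#' @slot affine 4x4 voxel-to-mm map (NIfTI RAS+ convention).
#' @slot trS repetition time in seconds.
#' @slot volumeTimesS acquisition time of each volume in seconds, monotone
#'   increasing; for a freshly loaded scan this is \code{(0:(t-1)) * trS}
#'   (volume index 0 is the first acquired volume).
#' @export
setClass("BoldScan",
  representation(data = "array", affine = "matrix", trS = "numeric",
                 volumeTimesS = "numeric"))

setValidity("BoldScan", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be a 4-D array (x, y, z, t)")
  if (d[4] < 1L) return("t dimension must be >= 1")
  if (length(object@trS) != 1L || !is.finite(object@trS) || object@trS <= 0)
    return("trS must be a single positive number")
  if (!all(dim(object@affine) == c(4L, 4L)))
    return("affine must be a 4x4 matrix")
  if (abs(det(object@affine)) < .Machine$double.eps)
    return("affine must be invertible")
  if (length(object@volumeTimesS) != d[4])
    return("volumeTimesS length must equal the number of volumes")
  if (d[4] > 1L && any(diff(object@volumeTimesS) <= 0))
    return("volumeTimesS must be strictly increasing")
  TRUE
})

#' Construct a BoldScan
#'
#' @param data 4-D numeric array (x, y, z, t).
#' @param trS repetition time in seconds.
#' @param affine 4x4 voxel-to-mm matrix; default an RAS+ diagonal affine with
#'   \code{voxelSizeMm} spacing.
#' @param volumeTimesS per-volume acquisition times in seconds; defaults to
#'   \code{(0:(t-1)) * trS}.
#' @param voxelSizeMm isotropic voxel edge used to build the default affine.
#' @return A \linkS4class{BoldScan}.
#' @export
BoldScan <- function(data, trS, affine = NULL, volumeTimesS = NULL,
                     voxelSizeMm = 3) {
  if (is.null(affine)) affine <- diag(c(rep(voxelSizeMm, 3), 1))
  if (is.null(volumeTimesS)) {
    nt <- dim(data)[4]
    volumeTimesS <- (seq_len(nt) - 1) * trS
  }
  new("BoldScan", data = data, affine = affine, trS = trS,
      volumeTimesS = as.numeric(volumeTimesS))
}

#' BrainMask: a 3-D boolean voxel mask
#'
#' @slot data logical 3-D array on the same spatial grid as the scans it masks.
#' @slot affine 4x4 voxel-to-mm map.
#' @export
setClass("BrainMask", representation(data = "array", affine = "matrix"))

setValidity("BrainMask", function(object) {
  if (length(dim(object@data)) != 3L) return("mask data must be a 3-D array")
  if (!is.logical(object@data)) return("mask data must be logical")
  if (!any(object@data)) return("mask must contain at least one TRUE voxel")
  if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
  TRUE
})

#' Construct a BrainMask
#' @param data logical 3-D array.
#' @param affine 4x4 voxel-to-mm matrix.
#' @return A \linkS4class{BrainMask}.
#' @export
BrainMask <- function(data, affine = diag(c(3, 3, 3, 1))) {
  new("BrainMask", data = data, affine = affine)
}

# ---------------------------------------------------------------------------
# Acquisition protocol and block design
# ---------------------------------------------------------------------------

#' ScanProtocol: block-design acquisition timing
#'
#' Describes either a blocked task acquisition (alternating rest/task blocks)
#' or a continuous rest acquisition (\code{nBlockPairs = 0}, all volumes
#' labelled rest).
#'
#' @slot trS repetition time in seconds.
#' @slot nVolumes total volumes acquired.
#' @slot blockLenS block length in seconds (must be divisible by trS).
#' @slot nBlockPairs number of rest+task block pairs (0 for continuous rest).
#' @slot startsWith condition of the first block, "rest" or "task".
#' @export
setClass("ScanProtocol",
  representation(trS = "numeric", nVolumes = "integer", blockLenS = "numeric",
                 nBlockPairs = "integer", startsWith = "character"))

setValidity("ScanProtocol", function(object) {
  if (object@trS <= 0) return("trS must be positive")
  if (object@nVolumes < 1L) return("nVolumes must be >= 1")
  if (!object@startsWith %in% c("rest", "task"))
    return("startsWith must be 'rest' or 'task'")
  if (object@nBlockPairs > 0L) {
    if (abs(object@blockLenS %% object@trS) > 1e-9)
      return("blockLenS must be divisible by trS")
    expect <- 2L * object@nBlockPairs * as.integer(round(object@blockLenS / object@trS))
    if (object@nVolumes != expect)
      return(sprintf("nVolumes (%d) must equal 2 * nBlockPairs * blockLenS/trS (%d)",
                     object@nVolumes, expect))
  }
  TRUE
})

#' @rdname ScanProtocol-class
#' @param trS,nVolumes,blockLenS,nBlockPairs,startsWith see slots.
#' @export
ScanProtocol <- function(trS, nVolumes, blockLenS = 0, nBlockPairs = 0L,
                         startsWith = "rest") {
  new("ScanProtocol", trS = trS, nVolumes = as.integer(nVolumes),
      blockLenS = blockLenS, nBlockPairs = as.integer(nBlockPairs),
      startsWith = startsWith)
}

#' Blocked language-task acquisition protocol
#'
#' Ten 30-s rest blocks alternating with ten 30-s task blocks at TR 3 s,
#' starting with rest: 200 volumes in total.
#' @return A \linkS4class{ScanProtocol}.
#' @export
taskProtocol <- function() ScanProtocol(trS = 3, nVolumes = 200L, blockLenS = 30,
                                        nBlockPairs = 10L, startsWith = "rest")

#' Continuous resting-state acquisition protocol
#'
#' A continuous rest scan; the default is 8.5 minutes at TR 3 s, i.e. 170
#' volumes.
#' @param durationS scan duration in seconds.
#' @param trS repetition time in seconds.
#' @return A \linkS4class{ScanProtocol} with \code{nVolumes = floor(durationS/trS)}.
#' @export
restProtocol <- function(durationS = 8.5 * 60, trS = 3) {
  ScanProtocol(trS = trS, nVolumes = as.integer(floor(durationS / trS)),
               blockLenS = 0, nBlockPairs = 0L, startsWith = "rest")
}

#' BlockDesign: per-volume condition labels
#'
#' @slot labels character vector, one of "rest"/"task" per volume, organised
#'   in contiguous blocks.
#' @export
setClass("BlockDesign", representation(labels = "character"))

setValidity("BlockDesign", function(object) {
  if (length(object@labels) < 1L) return("labels must be non-empty")
  if (!all(object@labels %in% c("rest", "task")))
    return("labels must be 'rest' or 'task'")
  TRUE
})

#' @rdname BlockDesign-class
#' @param labels character vector of per-volume condition labels.
#' @export
BlockDesign <- function(labels) new("BlockDesign", labels = labels)

#' ExtractionScheme: interleaved rest-extraction counts
#'
#' All counts are expressed in volumes. The scan-start discard applies to the
#' scan's first rest block \emph{instead of} the per-rest-block discard.
#'
#' @slot nDiscardScanStart volumes discarded at the start of the scan (signal
#'   equilibration).
#' @slot nKeepTaskStart volumes kept at the start of each task block and
#'   counted as rest (the haemodynamic response has not yet risen).
#' @slot nDiscardRestStart volumes discarded at the start of each non-initial
#'   rest block (waiting for the task response to decay).
#' @export
setClass("ExtractionScheme",
  representation(nDiscardScanStart = "integer", nKeepTaskStart = "integer",
                 nDiscardRestStart = "integer"))

setValidity("ExtractionScheme", function(object) {
  v <- c(object@nDiscardScanStart, object@nKeepTaskStart, object@nDiscardRestStart)
  if (any(v < 0L)) return("all counts must be >= 0")
  TRUE
})

#' @rdname ExtractionScheme-class
#' @param nDiscardScanStart,nKeepTaskStart,nDiscardRestStart see slots.
#' @export
ExtractionScheme <- function(nDiscardScanStart, nKeepTaskStart, nDiscardRestStart) {
  new("ExtractionScheme",
      nDiscardScanStart = as.integer(nDiscardScanStart),
      nKeepTaskStart = as.integer(nKeepTaskStart),
      nDiscardRestStart = as.integer(nDiscardRestStart))
}

#' The "fair_tr3" interleaved extraction preset
#'
#' Discard 3 volumes (9 s) at scan start, keep the first 2 volumes of every
#' task block as rest, discard the first 5 volumes of every non-initial rest
#' block — the scheme for a TR of 3 s. Applied to the blocked protocol of
#' \code{\link{taskProtocol}} it retains exactly 72 of 200 volumes.
#' @return An \linkS4class{ExtractionScheme}.
#' @export
fairScheme <- function() ExtractionScheme(3L, 2L, 5L)

# ---------------------------------------------------------------------------
# Synthetic generator types
# ---------------------------------------------------------------------------

#' NetworkSpec: planted spatial network structure
#'
#' @slot gridShape integer 3-vector of voxel counts.
#' @slot voxelSizeMm isotropic voxel edge length in mm.
#' @slot rois data.frame with columns \code{name}, \code{x}, \code{y},
#'   \code{z} (1-based centre voxel), \code{radius} (voxels), \code{network},
#'   \code{loading} (signal amplitude of the network latent in that ROI).
#' @slot networkCovariance symmetric positive-definite covariance of the
#'   per-network latent time series; dimnames are network ids.
#' @slot taskNetworks networks whose ROIs receive task activation in task scans.
#' @export
setClass("NetworkSpec",
  representation(gridShape = "integer", voxelSizeMm = "numeric",
                 rois = "data.frame", networkCovariance = "matrix",
                 taskNetworks = "character"))

setValidity("NetworkSpec", function(object) {
  S <- object@networkCovariance
  if (is.null(rownames(S)) || !identical(rownames(S), colnames(S)))
    return("networkCovariance must have matching row/col network names")
  if (max(abs(S - t(S))) > 1e-10) return("networkCovariance must be symmetric")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return("networkCovariance must be positive definite")
  need <- c("name", "x", "y", "z", "radius", "network", "loading")
  if (!all(need %in% names(object@rois)))
    return(paste("rois must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(object@rois$name)) return("ROI names must be unique")
  if (!all(object@rois$network %in% rownames(S)))
    return("every ROI network must appear in networkCovariance")
  g <- object@gridShape
  r <- object@rois
  if (any(r$x - r$radius < 1 | r$x + r$radius > g[1] |
          r$y - r$radius < 1 | r$y + r$radius > g[2] |
          r$z - r$radius < 1 | r$z + r$radius > g[3]))
    return("ROI spheres must lie inside the grid")
  if (!all(object@taskNetworks %in% rownames(S)))
    return("taskNetworks must be network ids")
  TRUE
})

#' @rdname NetworkSpec-class
#' @param gridShape,voxelSizeMm,rois,networkCovariance,taskNetworks see slots.
#' @export
NetworkSpec <- function(gridShape, voxelSizeMm, rois, networkCovariance,
                        taskNetworks = character()) {
  new("NetworkSpec", gridShape = as.integer(gridShape),
      voxelSizeMm = voxelSizeMm, rois = rois,
      networkCovariance = networkCovariance, taskNetworks = taskNetworks)
}

#' NoiseModel: additive noise for synthetic BOLD
#'
#' White noise is generated as an AR(1) process per voxel with the innovation
#' variance scaled so the marginal standard deviation equals \code{whiteSd}.
#' Drift is a shared low-rank structure (linear trend + one cosine of period
#' 128 s, both scaled to unit temporal sd) with per-voxel Gaussian amplitudes
#' of total sd \code{driftAmp}.
#'
#' @slot whiteSd marginal sd of the stationary voxel noise (>= 0).
#' @slot driftAmp sd of the slow-drift contribution per voxel (>= 0).
#' @slot ar1Phi lag-1 autocorrelation, |phi| < 1.
#' @slot baseline mean signal level added to every voxel.
#' @export
setClass("NoiseModel",
  representation(whiteSd = "numeric", driftAmp = "numeric",
                 ar1Phi = "numeric", baseline = "numeric"))

setValidity("NoiseModel", function(object) {
  if (object@whiteSd < 0) return("whiteSd must be >= 0")
  if (object@driftAmp < 0) return("driftAmp must be >= 0")
  if (abs(object@ar1Phi) >= 1) return("|ar1Phi| must be < 1")
  TRUE
})

#' @rdname NoiseModel-class
#' @param whiteSd,driftAmp,ar1Phi,baseline see slots.
#' @export
NoiseModel <- function(whiteSd = 1, driftAmp = 1.2, ar1Phi = 0.3, baseline = 100) {
  new("NoiseModel", whiteSd = whiteSd, driftAmp = driftAmp, ar1Phi = ar1Phi,
      baseline = baseline)
}

#' GroundTruth: what the generator planted
#'
#' @slot networkMap 3-D integer grid; 0 outside ROIs, otherwise the index of
#'   the network (in \code{networks}) owning the voxel.
#' @slot roiMap 3-D integer grid; 0 outside ROIs, otherwise the ROI index.
#' @slot roiCorrelation true ROI-to-ROI correlation matrix in the noiseless
#'   limit (within-network entries 1, across-network entries the latent
#'   correlation).
#' @slot conditionLabels per-volume condition labels of the task scan.
#' @slot networks network ids in map order.
#' @slot roiNames ROI names in map order.
#' @slot roiNetworks network id of each ROI.
#' @slot seed generator seed.
#' @export
setClass("GroundTruth",
  representation(networkMap = "array", roiMap = "array",
                 roiCorrelation = "matrix", conditionLabels = "character",
                 networks = "character", roiNames = "character",
                 roiNetworks = "character", seed = "integer"))

# ---------------------------------------------------------------------------
# Denoising
# ---------------------------------------------------------------------------

#' ConfoundMatrix: named nuisance regressors
#'
#' @slot columns time x regressors numeric matrix with column names.
#' @slot sources per-column tag: "motion", "motion-derived", "compcor" or
#'   "drift-basis".
#' @export
setClass("ConfoundMatrix",
  representation(columns = "matrix", sources = "character"))

setValidity("ConfoundMatrix", function(object) {
  if (ncol(object@columns) < 1L) return("at least one regressor required")
  if (length(object@sources) != ncol(object@columns))
    return("sources must tag every column")
  if (!all(object@sources %in% c("motion", "motion-derived", "compcor", "drift-basis")))
    return("unknown source tag")
  if (anyDuplicated(t(object@columns)) > 0)
    return("duplicate regressor columns are not allowed")
  TRUE
})

#' @rdname ConfoundMatrix-class
#' @param columns,sources see slots.
#' @export
ConfoundMatrix <- function(columns, sources) {
  new("ConfoundMatrix", columns = columns, sources = sources)
}

# ---------------------------------------------------------------------------
# ICA / atlases
# ---------------------------------------------------------------------------

#' ICADecomposition: group spatial ICA result
#'
#' @slot spatialMaps component x in-mask-voxel matrix; each row z-scored over
#'   in-mask voxels (zero mean, unit sd).
#' @slot mixing time x component matrix such that \code{mixing \%*\% spatialMaps}
#'   reconstructs the (doubly centred) data up to the variance discarded by
#'   the PCA reduction.
#' @slot nComponents number of components.
#' @slot seed RNG seed used for the fixed-point iteration start.
#' @slot mask the analysis \linkS4class{BrainMask} defining the voxel order.
#' @export
setClass("ICADecomposition",
  representation(spatialMaps = "matrix", mixing = "matrix",
                 nComponents = "integer", seed = "integer", mask = "BrainMask"))

setValidity("ICADecomposition", function(object) {
  if (nrow(object@spatialMaps) != object@nComponents)
    return("spatialMaps must have nComponents rows")
  if (ncol(object@mixing) != object@nComponents)
    return("mixing must have nComponents columns")
  m <- rowMeans(object@spatialMaps)
  s <- apply(object@spatialMaps, 1, stats::sd)
  if (max(abs(m)) > 1e-6 || max(abs(s - 1)) > 1e-6)
    return("spatialMaps rows must be z-scored (zero mean, unit sd)")
  TRUE
})

#' TemplateAtlas: reference network label volume
#'
#' A Yeo-style label map on the analysis grid: integer labels with a named
#' lookup from network name to label value.
#'
#' @slot labelMap 3-D integer grid (0 = background).
#' @slot networks named integer vector mapping network name to label value.
#' @export
setClass("TemplateAtlas",
  representation(labelMap = "array", networks = "integer"))

setValidity("TemplateAtlas", function(object) {
  if (length(dim(object@labelMap)) != 3L) return("labelMap must be 3-D")
  if (is.null(names(object@networks))) return("networks must be named")
  TRUE
})

#' @rdname TemplateAtlas-class
#' @param labelMap,networks see slots.
#' @export
TemplateAtlas <- function(labelMap, networks) {
  new("TemplateAtlas", labelMap = labelMap,
      networks = structure(as.integer(networks), names = names(networks)))
}

#' MatchResult: best template match of an ICA component
#'
#' @slot component 1-based index of the best-matching component.
#' @slot r spatial Pearson correlation with the binary template after sign
#'   alignment (>= 0).
#' @slot sign sign flip applied to the component map (+1 or -1).
#' @slot network the template network matched against.
#' @export
setClass("MatchResult",
  representation(component = "integer", r = "numeric", sign = "numeric",
                 network = "character"))

setValidity("MatchResult", function(object) {
  if (object@r < 0) return("r must be >= 0 after sign alignment")
  if (!object@sign %in% c(-1, 1)) return("sign must be -1 or +1")
  if (object@component < 1L) return("component index must be >= 1")
  TRUE
})

#' RoiAtlas: labelled regions of interest
#'
#' @slot labelMap 3-D integer grid; 0 = background, 1..K = ROI ids assigned in
#'   descending size order.
#' @slot roiNames names of the K ROIs.
#' @slot affine 4x4 voxel-to-mm map.
#' @export
setClass("RoiAtlas",
  representation(labelMap = "array", roiNames = "character", affine = "matrix"))

setValidity("RoiAtlas", function(object) {
  if (length(dim(object@labelMap)) != 3L) return("labelMap must be 3-D")
  K <- length(object@roiNames)
  lab <- sort(unique(as.integer(object@labelMap)))
  lab <- lab[lab != 0L]
  if (!identical(lab, seq_len(K)))
    return("labelMap must use exactly the ids 1..K")
  TRUE
})

#' @rdname RoiAtlas-class
#' @param labelMap,roiNames,affine see slots.
#' @export
RoiAtlas <- function(labelMap, roiNames, affine = diag(c(3, 3, 3, 1))) {
  new("RoiAtlas", labelMap = labelMap, roiNames = roiNames, affine = affine)
}

# ---------------------------------------------------------------------------
# Connectivity
# ---------------------------------------------------------------------------

#' ConnectivityMatrix: symmetric Fisher-z ROI-to-ROI matrix
#'
#' @slot values K x K symmetric matrix of Fisher-z entries; the diagonal is
#'   undefined and stored as 0.
#' @slot roiLabels the K ROI names.
#' @export
setClass("ConnectivityMatrix",
  representation(values = "matrix", roiLabels = "character"))

setValidity("ConnectivityMatrix", function(object) {
  K <- length(object@roiLabels)
  if (K < 2L) return("at least two ROIs required")
  if (!all(dim(object@values) == c(K, K)))
    return("values must be K x K")
  if (max(abs(object@values - t(object@values))) > 1e-12)
    return("values must be symmetric")
  if (any(abs(diag(object@values)) > 0)) return("diagonal must be stored as 0")
  off <- object@values[upper.tri(object@values)]
  if (any(!is.finite(off))) return("off-diagonal entries must be finite")
  TRUE
})

#' @rdname ConnectivityMatrix-class
#' @param values,roiLabels see slots.
#' @export
ConnectivityMatrix <- function(values, roiLabels) {
  dimnames(values) <- list(roiLabels, roiLabels)
  new("ConnectivityMatrix", values = values, roiLabels = roiLabels)
}

#' SeedMap: voxelwise Fisher-z seed connectivity map
#'
#' @slot mapData 3-D grid of Fisher-z values (0 outside the mask).
#' @slot seedName name of the seed ROI.
#' @slot affine 4x4 voxel-to-mm map.
#' @export
setClass("SeedMap",
  representation(mapData = "array", seedName = "character", affine = "matrix"))

# ---------------------------------------------------------------------------
# Statistics results
# ---------------------------------------------------------------------------

#' SimilarityResult: matrix-similarity test outcome
#'
#' @slot rho Spearman correlation of the upper triangles.
#' @slot p one-sided p-value (similarity larger than the permutation null).
#' @slot nIter number of permutations evaluated (K! for the exact Mantel test).
#' @slot seed RNG seed (NA for the exact test).
#' @slot method "permutation", "mantel_exact" or "mantel_sampled".
#' @export
setClass("SimilarityResult",
  representation(rho = "numeric", p = "numeric", nIter = "integer",
                 seed = "integer", method = "character"))

setValidity("SimilarityResult", function(object) {
  if (object@rho < -1 - 1e-12 || object@rho > 1 + 1e-12)
    return("rho must lie in [-1, 1]")
  if (object@p <= 0 || object@p > 1) return("p must lie in (0, 1]")
  if (!object@method %in% c("permutation", "mantel_exact", "mantel_sampled"))
    return("unknown method")
  TRUE
})

#' GroupComparison: second-level seed-based group contrast
#'
#' @slot tMap 3-D two-sample t statistic grid.
#' @slot df degrees of freedom (nA + nB - 2).
#' @slot clusters data.frame with one row per candidate cluster: id, extent,
#'   peakT, peakX/peakY/peakZ (1-based voxel), pUnc, pFdr, sign
#'   ("A>B"/"B>A"), significant.
#' @slot members list of integer vectors of linear voxel indices per cluster.
#' @slot clusterMap 3-D integer grid labelling the candidate clusters.
#' @slot voxelPThreshold cluster-forming voxelwise two-sided p threshold.
#' @slot clusterQ FDR level for cluster-level correction.
#' @slot nPerm permutations used for the cluster-extent null.
#' @slot seed RNG seed of the permutation null.
#' @export
setClass("GroupComparison",
  representation(tMap = "array", df = "numeric", clusters = "data.frame",
                 members = "list", clusterMap = "array",
                 voxelPThreshold = "numeric", clusterQ = "numeric",
                 nPerm = "integer", seed = "integer"))

# ---------------------------------------------------------------------------
# Pipeline configuration
# ---------------------------------------------------------------------------

#' ValidationConfig: settings for the full two-arm validation
#'
#' Every tunable of the pipeline is collected here, with the protocol's
#' printed settings as defaults: extraction counts 3/2/5 volumes, 0.01 Hz
#' high-pass, 50% CompCor variance, 6 mm FWHM smoothing, 20 ICA components,
#' 5000 similarity permutations, voxelwise p < 0.001 cluster forming and
#' cluster FDR q = 0.05.
#'
#' @slot nPerGroup subjects per group in the synthetic cohort.
#' @slot effect planted seed-connectivity group difference (correlation units).
#' @slot cohortSeed master seed for subject simulation.
#' @slot scheme \linkS4class{ExtractionScheme} for the intermittent arm.
#' @slot cutoffHz high-pass cutoff in Hz.
#' @slot compcorVarThreshold cumulative variance fraction for CompCor.
#' @slot fwhmMm smoothing kernel FWHM in mm.
#' @slot nComponents ICA model order.
#' @slot icaSeed ICA seed (shared by both arms).
#' @slot zThresh component-map threshold for network masks.
#' @slot minRoiSize minimum ROI size in voxels.
#' @slot connectivity neighbourhood for connected components (6 or 26).
#' @slot nIter permutations for matrix-similarity testing.
#' @slot nPerm permutations for cluster-extent inference.
#' @slot statSeed seed for the statistical permutation streams.
#' @slot voxelP cluster-forming voxelwise p threshold.
#' @slot clusterQ cluster-level FDR level.
#' @slot subsampleRest if TRUE, the continuous-rest arm is subsampled to its
#'   middle segment of the intermittent arm's length before analysis.
#' @slot symmetryControl if TRUE, feed the continuous rest scan to BOTH arms
#'   (bypassing extraction); used as a pipeline self-check.
#' @export
setClass("ValidationConfig",
  representation(nPerGroup = "integer", effect = "numeric",
                 cohortSeed = "integer", scheme = "ExtractionScheme",
                 cutoffHz = "numeric", compcorVarThreshold = "numeric",
                 fwhmMm = "numeric", nComponents = "integer",
                 icaSeed = "integer", zThresh = "numeric",
                 minRoiSize = "integer", connectivity = "integer",
                 nIter = "integer", nPerm = "integer", statSeed = "integer",
                 voxelP = "numeric", clusterQ = "numeric",
                 subsampleRest = "logical", symmetryControl = "logical"))

#' @rdname ValidationConfig-class
#' @param nPerGroup,effect,cohortSeed,scheme,cutoffHz,compcorVarThreshold,fwhmMm,nComponents,icaSeed,zThresh,minRoiSize,connectivity,nIter,nPerm,statSeed,voxelP,clusterQ,subsampleRest,symmetryControl see slots.
#' @export
validationConfig <- function(nPerGroup = 6L, effect = 0.3, cohortSeed = 20260101L,
                             scheme = fairScheme(), cutoffHz = 0.01,
                             compcorVarThreshold = 0.5, fwhmMm = 6,
                             nComponents = 20L, icaSeed = 11L, zThresh = 2,
                             minRoiSize = 5L, connectivity = 26L, nIter = 5000L,
                             nPerm = 1000L, statSeed = 12L, voxelP = 0.001,
                             clusterQ = 0.05, subsampleRest = FALSE,
                             symmetryControl = FALSE) {
  new("ValidationConfig", nPerGroup = as.integer(nPerGroup), effect = effect,
      cohortSeed = as.integer(cohortSeed), scheme = scheme, cutoffHz = cutoffHz,
      compcorVarThreshold = compcorVarThreshold, fwhmMm = fwhmMm,
      nComponents = as.integer(nComponents), icaSeed = as.integer(icaSeed),
      zThresh = zThresh, minRoiSize = as.integer(minRoiSize),
      connectivity = as.integer(connectivity), nIter = as.integer(nIter),
      nPerm = as.integer(nPerm), statSeed = as.integer(statSeed),
      voxelP = voxelP, clusterQ = clusterQ, subsampleRest = subsampleRest,
      symmetryControl = symmetryControl)
}
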