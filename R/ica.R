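#' Temporal concatenation of subjects for group ICA
#'
#' Extracts each subject's in-mask time x voxel matrix, removes the voxelwise
#' temporal mean, scales the subject's block to unit total variance (the sum
#' of per-voxel temporal variances equals 1), and stacks the blocks along
#' time. This per-subject variance normalization stops high-variance subjects
#' from dominating the group decomposition.
#'
#' @param scans list of \linkS4class{BoldScan}s on a common grid, each with at
#'   least 10 volumes.
#' @param mask analysis \linkS4class{BrainMask}.
#' @return time x in-mask-voxel matrix (rows = stacked subject volumes).
#' @export
concatSubjects <- function(scans, mask) {
  stopifnot(length(scans) >= 1L, is(mask, "BrainMask"))
  inmask <- which(mask@data)
  blocks <- lapply(scans, function(s) {
    stopifnot(is(s, "BoldScan"))
    checkSameGrid(s@data, mask@data, "scan and mask")
    if (dim(s@data)[4] < 10L) stop("each subject needs at least 10 volumes")
    Y <- t(asVoxelMatrix(s@data)[inmask, , drop = FALSE])
    Y <- sweep(Y, 2, colMeans(Y))
    tot <- sum(colSums(Y^2) / (nrow(Y) - 1))
    if (tot == 0) stop("subject has zero in-mask variance")
    Y / sqrt(tot)
  })
  do.call(rbind, blocks)
}

# symmetric decorrelation W <- (W W^T)^{-1/2} W
symDecorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, .Machine$double.eps)),
                     nrow(W)) %*% t(e$vectors) %*% W
}

#' Group spatial ICA by PCA whitening and fixed-point iteration
#'
#' Reduces the (doubly centred) data to \code{nComponents} principal
#' components and unmixes the spatial dimension with the symmetric fixed-point
#' algorithm under the logcosh contrast. Component maps are z-scored over
#' in-mask voxels and sign-flipped so their skewness is non-negative; the
#' mixing matrix is rescaled so that \code{mixing \%*\% spatialMaps}
#' reconstructs the centred data up to the variance discarded by the PCA
#' reduction. Results are reproducible from the seed.
#'
#' @param data time x voxel matrix (rows >= nComponents), e.g. from
#'   \code{\link{concatSubjects}}.
#' @param nComponents model order (default 20). A model order far above the
#'   data's effective rank leaves whitened directions with no independent
#'   non-Gaussian structure, for which the fixed-point iteration has no
#'   attractor; the restart loop then exhausts itself and errors.
#' @param seed integer seed for the iteration start; restart r uses seed + r.
#' @param mask the \linkS4class{BrainMask} defining the voxel order.
#' @param maxIter maximum fixed-point iterations per restart.
#' @param tol convergence tolerance on the unmixing update.
#' @param restarts random re-initialisations attempted before giving up.
#' @return An \linkS4class{ICADecomposition}.
#' @export
spatialIca <- function(data, nComponents = 20, seed, mask, maxIter = 2000L,
                       tol = 1e-4, restarts = 5L) {
  nComponents <- as.integer(nComponents)
  if (nrow(data) < nComponents)
    stop(sprintf("need at least %d rows for %d components", nComponents,
                 nComponents))
  V <- ncol(data)
  # double centring: voxelwise temporal means and per-timepoint spatial means
  X <- sweep(data, 2, colMeans(data))
  X <- X - rowMeans(X)

  # PCA whitening via the temporal Gram matrix
  G <- tcrossprod(X) / V
  e <- eigen(G, symmetric = TRUE)
  lam <- e$values[seq_len(nComponents)]
  if (min(lam) <= 0) stop("data rank is below the requested component count")
  U <- e$vectors[, seq_len(nComponents), drop = FALSE]
  Z <- diag(1 / sqrt(lam), nComponents) %*% t(U) %*% X   # components x voxels

  converged <- FALSE
  delta <- Inf
  totalIter <- 0L
  for (r in seq_len(max(1L, as.integer(restarts)))) {
    set.seed(as.integer(seed) + r - 1L)
    W <- symDecorrelate(matrix(stats::rnorm(nComponents^2), nComponents))
    for (it in seq_len(maxIter)) {
      WZ <- W %*% Z
      gz <- tanh(WZ)
      W1 <- gz %*% t(Z) / V - diag(rowMeans(1 - gz^2), nComponents) %*% W
      W1 <- symDecorrelate(W1)
      delta <- max(abs(1 - abs(diag(W1 %*% t(W)))))
      W <- W1
      totalIter <- totalIter + 1L
      if (delta < tol) { converged <- TRUE; break }
    }
    if (converged) break
  }
  if (!converged)
    stop(sprintf(paste0("fixed-point ICA did not converge within %d iterations",
                        " (%d restarts, last update %.2e); the model order",
                        " likely exceeds the data's non-Gaussian rank"),
                 totalIter, restarts, delta))

  S <- W %*% Z                                  # components x voxels
  # sign convention: non-negative skewness
  sk <- rowMeans(S^3)
  flip <- ifelse(sk < 0, -1, 1)
  S <- S * flip
  # z-score maps; fold scale into the mixing matrix
  mu <- rowMeans(S)
  sdev <- sqrt(rowMeans(S^2) - mu^2) * sqrt(V / (V - 1))
  S <- (S - mu) / sdev
  # mixing for the whitened reconstruction: X ~ U diag(sqrt(lam)) W^T (S*sd+mu)
  M <- U %*% diag(sqrt(lam), nComponents) %*% t(W * flip)
  M <- M * rep(sdev, each = nrow(M))
  new("ICADecomposition", spatialMaps = S, mixing = M,
      nComponents = nComponents, seed = as.integer(seed), mask = mask)
}

#' Embed a component map into the 3-D grid
#'
#' @param decomp an \linkS4class{ICADecomposition}.
#' @param component 1-based component index.
#' @param sign optional sign flip (+1/-1) to apply.
#' @return 3-D array with the z-scored map on in-mask voxels, 0 elsewhere.
#' @export
componentVolume <- function(decomp, component, sign = 1) {
  stopifnot(is(decomp, "ICADecomposition"))
  m <- decomp@mask@data
  out <- array(0, dim(m))
  out[which(m)] <- sign * decomp@spatialMaps[component, ]
  out
}

#' Best-matching component for a template network
#'
#' Computes the Pearson correlation between each component map and the binary
#' template of the requested network over in-mask voxels, flips signs so the
#' correlation is non-negative, and returns the best match (ties broken by the
#' lower component index). Matching is invariant to component sign flips and
#' reordering.
#'
#' @param decomp an \linkS4class{ICADecomposition}.
#' @param template a \linkS4class{TemplateAtlas} on the analysis grid.
#' @param network template network name.
#' @return A \linkS4class{MatchResult}.
#' @export
matchToTemplate <- function(decomp, template, network) {
  stopifnot(is(decomp, "ICADecomposition"), is(template, "TemplateAtlas"))
  if (!network %in% names(template@networks))
    stop("unknown template network: ", network)
  checkSameGrid(template@labelMap, decomp@mask@data, "template and mask")
  inmask <- which(decomp@mask@data)
  tvec <- as.numeric(template@labelMap[inmask] == template@networks[[network]])
  if (sum(tvec) == 0) stop("template network '", network, "' is empty in the mask")
  r <- as.numeric(stats::cor(t(decomp@spatialMaps), tvec))
  best <- which.max(abs(r))  # which.max returns the first (lowest) index on ties
  new("MatchResult", component = as.integer(best), r = abs(r[best]),
      sign = if (r[best] < 0) -1 else 1, network = network)
}

#' Threshold a z-scored map into a mask
#'
#' @param map 3-D z-scored map (e.g. from \code{\link{componentVolume}}).
#' @param zThresh threshold; voxels with value > zThresh are kept (default 2).
#' @return A logical 3-D array (an empty selection is legal here; consumers
#'   such as \code{\link{intersectAndLabel}} raise the error). Wrap in
#'   \code{\link{BrainMask}} when a non-empty mask object is needed.
#' @export
thresholdMap <- function(map, zThresh = 2) {
  map > zThresh
}

#' Intersect two network masks and label spatially distinct ROIs
#'
#' Voxelwise AND of the two masks, connected-component labelling under the
#' stated neighbourhood, removal of components smaller than \code{minSize},
#' and id assignment in descending size order.
#'
#' @param maskA,maskB \linkS4class{BrainMask}s (or logical arrays) on a common
#'   grid.
#' @param minSize minimum ROI size in voxels (default 5).
#' @param connectivity 26 (default) or 6.
#' @return A \linkS4class{RoiAtlas} with ROIs named "ROI1".."ROIK".
#' @export
intersectAndLabel <- function(maskA, maskB, minSize = 5, connectivity = 26) {
  a <- if (is(maskA, "BrainMask")) maskA@data else maskA
  b <- if (is(maskB, "BrainMask")) maskB@data else maskB
  checkSameGrid(a, b, "masks")
  aff <- if (is(maskA, "BrainMask")) maskA@affine else diag(c(3, 3, 3, 1))
  inter <- a & b
  if (!any(inter)) stop("the intersection of the two masks is empty")
  lab <- labelComponents(inter, as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= minSize)
  if (length(keep) == 0L)
    stop("no intersection component reaches the minimum ROI size")
  out <- array(0L, dim(lab))
  for (j in seq_along(keep)) out[lab == keep[j]] <- j  # keep is size-ordered
  RoiAtlas(out, sprintf("ROI%d", seq_along(keep)), affine = aff)
}
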