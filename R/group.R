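# Second-level seed-based group comparison: voxelwise pooled-variance two-sample
# t-test on Fisher-z seed maps, cluster forming at a voxelwise two-sided p
# threshold, and cluster-level correction by a group-label permutation null of
# maximum cluster extents with Benjamini-Hochberg FDR across observed clusters.

seedMapArray <- function(x) if (is(x, "SeedMap")) x@mapData else x

stackMaps <- function(maps) {
  arrs <- lapply(maps, seedMapArray)
  d <- dim(arrs[[1]])
  for (a in arrs) checkSameGrid(a, arrs[[1]], "seed maps")
  list(mat = vapply(arrs, as.numeric, numeric(prod(d))), dim = d)
}

pooledT <- function(mat, isA, warnZero = FALSE) {
  nA <- sum(isA); nB <- sum(!isA)
  mA <- rowMeans(mat[, isA, drop = FALSE])
  mB <- rowMeans(mat[, !isA, drop = FALSE])
  vA <- rowSums((mat[, isA, drop = FALSE] - mA)^2)
  vB <- rowSums((mat[, !isA, drop = FALSE] - mB)^2)
  df <- nA + nB - 2
  sp2 <- (vA + vB) / df
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  zero <- se == 0
  if (warnZero && any(zero))
    warning(sum(zero), " voxels with zero pooled variance; t set to 0 there")
  t <- numeric(length(se))
  t[!zero] <- (mA[!zero] - mB[!zero]) / se[!zero]
  list(t = t, df = df)
}

#' Voxelwise two-sample t-test on seed maps
#'
#' Pooled-variance two-sample t statistic per voxel, df = nA + nB - 2. Voxels
#' with zero pooled variance get t = 0 with a warning. Swapping the group
#' labels negates the map exactly.
#'
#' @param mapsA,mapsB lists of \linkS4class{SeedMap}s (or 3-D arrays), >= 2
#'   per group, on a common grid.
#' @return List with \code{tMap} (3-D array) and \code{df}.
#' @export
voxelTtest <- function(mapsA, mapsB) {
  if (length(mapsA) < 2L || length(mapsB) < 2L)
    stop("need at least 2 maps per group")
  st <- stackMaps(c(mapsA, mapsB))
  isA <- c(rep(TRUE, length(mapsA)), rep(FALSE, length(mapsB)))
  res <- pooledT(st$mat, isA, warnZero = TRUE)
  list(tMap = array(res$t, st$dim), df = res$df)
}

clusterize <- function(tvec, dm, tcrit, connectivity) {
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- array(sgn * tvec > tcrit, dm)
    if (!any(supra)) next
    lab <- labelComponents(supra, connectivity)
    for (k in seq_len(max(lab))) {
      mem <- which(lab == k)
      peak <- mem[which.max(abs(tvec[mem]))]
      out[[length(out) + 1L]] <- list(
        members = mem, extent = length(mem),
        peakT = tvec[peak], peak = arrayInd(peak, dm)[1, ],
        sign = if (sgn > 0) "A>B" else "B>A")
    }
  }
  out
}

#' Form candidate clusters from a t map
#'
#' Thresholds |t| at the two-sided critical value for \code{voxelP} at the
#' given df and labels connected components separately for positive and
#' negative excursions. An empty result is allowed.
#'
#' @param tMap 3-D t statistic array (e.g. from \code{\link{voxelTtest}}).
#' @param df degrees of freedom (>= 2).
#' @param voxelP voxelwise two-sided cluster-forming p threshold (default 0.001).
#' @param connectivity 26 (default) or 6.
#' @return List of candidate clusters (members, extent, peakT, peak, sign).
#' @export
formClusters <- function(tMap, df, voxelP = 0.001, connectivity = 26) {
  if (df < 2) stop("df must be >= 2")
  tcrit <- stats::qt(1 - voxelP / 2, df)
  clusterize(as.numeric(tMap), dim(tMap), tcrit, as.integer(connectivity))
}

#' Benjamini-Hochberg rejection flags
#'
#' Step-up FDR control at level q over a vector of p-values.
#'
#' @param pvals p-values in (0, 1].
#' @param q FDR level.
#' @return Logical rejection flags (empty input gives an empty vector).
#' @export
fdrBh <- function(pvals, q) {
  if (length(pvals) == 0L) return(logical(0))
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Permutation cluster-extent inference
#'
#' Builds a null distribution of the maximum cluster extent by shuffling the
#' group labels \code{nPerm} times and re-running the voxelwise t-test and
#' cluster forming. Each observed cluster's uncorrected p-value is
#' \code{(1 + #\{max null extent >= observed extent\}) / (1 + nPerm)};
#' Benjamini-Hochberg FDR is then applied across the observed clusters at
#' level \code{clusterQ}. This nonparametric cluster null replaces parametric
#' random-field cluster p-values, which rely on smoothness estimates that are
#' brittle on small grids; permutation is exact under group exchangeability.
#'
#' @param candidates clusters from \code{\link{formClusters}} computed on the
#'   same maps.
#' @param mapsA,mapsB the two groups' seed maps.
#' @param nPerm permutations (default 1000; < 100 triggers a granularity
#'   warning).
#' @param clusterQ cluster-level FDR (default 0.05).
#' @param seed integer RNG seed.
#' @param voxelP,connectivity must match the values used in
#'   \code{\link{formClusters}}.
#' @return A \linkS4class{GroupComparison}.
#' @export
clusterInference <- function(candidates, mapsA, mapsB, nPerm = 1000,
                             clusterQ = 0.05, seed, voxelP = 0.001,
                             connectivity = 26) {
  nPerm <- as.integer(nPerm)
  if (nPerm < 100L) warning("nPerm < 100 gives coarse p-value granularity")
  st <- stackMaps(c(mapsA, mapsB))
  nA <- length(mapsA); nB <- length(mapsB)
  isA <- c(rep(TRUE, nA), rep(FALSE, nB))
  obs <- pooledT(st$mat, isA)
  df <- obs$df
  tcrit <- stats::qt(1 - voxelP / 2, df)
  connectivity <- as.integer(connectivity)

  emptyTable <- data.frame(id = integer(0), extent = integer(0),
                           peakT = numeric(0), peakX = integer(0),
                           peakY = integer(0), peakZ = integer(0),
                           pUnc = numeric(0), pFdr = numeric(0),
                           sign = character(0), significant = logical(0))
  if (length(candidates) == 0L) {
    return(new("GroupComparison", tMap = array(obs$t, st$dim), df = df,
               clusters = emptyTable, members = list(),
               clusterMap = array(0L, st$dim), voxelPThreshold = voxelP,
               clusterQ = clusterQ, nPerm = nPerm, seed = as.integer(seed)))
  }

  set.seed(as.integer(seed))
  nullMax <- integer(nPerm)
  for (i in seq_len(nPerm)) {
    permA <- logical(nA + nB)
    permA[sample.int(nA + nB, nA)] <- TRUE
    tp <- pooledT(st$mat, permA)$t
    cl <- clusterize(tp, st$dim, tcrit, connectivity)
    nullMax[i] <- if (length(cl)) max(vapply(cl, `[[`, integer(1), "extent")) else 0L
  }

  ext <- vapply(candidates, `[[`, integer(1), "extent")
  pUnc <- vapply(ext, function(e) (1 + sum(nullMax >= e)) / (1 + nPerm), numeric(1))
  pFdr <- stats::p.adjust(pUnc, method = "BH")
  sig <- pFdr < clusterQ
  peaks <- t(vapply(candidates, `[[`, integer(3), "peak"))
  tab <- data.frame(id = seq_along(candidates), extent = ext,
                    peakT = vapply(candidates, `[[`, numeric(1), "peakT"),
                    peakX = peaks[, 1], peakY = peaks[, 2], peakZ = peaks[, 3],
                    pUnc = pUnc, pFdr = pFdr,
                    sign = vapply(candidates, `[[`, character(1), "sign"),
                    significant = sig)
  cmap <- array(0L, st$dim)
  members <- lapply(candidates, `[[`, "members")
  for (j in seq_along(members)) cmap[members[[j]]] <- j
  new("GroupComparison", tMap = array(obs$t, st$dim), df = df, clusters = tab,
      members = members, clusterMap = cmap, voxelPThreshold = voxelP,
      clusterQ = clusterQ, nPerm = nPerm, seed = as.integer(seed))
}

#' Write a cluster table as TSV
#'
#' @param gc a \linkS4class{GroupComparison}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeClusterTsv <- function(gc, path) {
  utils::write.table(gc@clusters, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
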