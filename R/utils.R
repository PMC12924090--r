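# Internal helpers shared across modules.

# Linear indices of voxels inside a sphere (1-based centre, radius in voxels).
sphereIndices <- function(gridShape, center, radius) {
  r <- ceiling(radius)
  xs <- max(1, center[1] - r):min(gridShape[1], center[1] + r)
  ys <- max(1, center[2] - r):min(gridShape[2], center[2] + r)
  zs <- max(1, center[3] - r):min(gridShape[3], center[3] + r)
  g <- expand.grid(x = xs, y = ys, z = zs)
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  g <- g[d2 <= radius^2, , drop = FALSE]
  as.integer(g$x + (g$y - 1L) * gridShape[1] +
               (g$z - 1L) * gridShape[1] * gridShape[2])
}

# Neighbourhood offsets for 6- or 26-connectivity.
neighbourOffsets <- function(connectivity) {
  stopifnot(connectivity %in% c(6L, 26L))
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  if (connectivity == 6L) g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) == 1, ]
  as.matrix(g)
}

# Connected-component labelling of a logical 3-D array under 6- or
# 26-connectivity. Returns an integer array: 0 background, components numbered
# 1..n in descending size order (ties broken by smallest member linear index).
labelComponents <- function(mask, connectivity = 26L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  dm <- dim(mask)
  out <- array(0L, dm)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) return(out)

  pos <- integer(prod(dm))           # voxel linear index -> node id
  pos[idx] <- seq_len(n)
  co <- arrayInd(idx, dm)

  # union-find
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  off <- neighbourOffsets(as.integer(connectivity))
  # only "forward" offsets to visit each pair once
  fwd <- off[off[, 3] > 0 | (off[, 3] == 0 & off[, 2] > 0) |
               (off[, 3] == 0 & off[, 2] == 0 & off[, 1] > 0), , drop = FALSE]
  for (k in seq_len(nrow(fwd))) {
    nx <- co[, 1] + fwd[k, 1]; ny <- co[, 2] + fwd[k, 2]; nz <- co[, 3] + fwd[k, 3]
    ok <- nx >= 1L & nx <= dm[1] & ny >= 1L & ny <= dm[2] & nz >= 1L & nz <= dm[3]
    if (!any(ok)) next
    nlin <- nx[ok] + (ny[ok] - 1L) * dm[1] + (nz[ok] - 1L) * dm[1] * dm[2]
    nid <- pos[nlin]
    from <- which(ok)[nid > 0L]
    to <- nid[nid > 0L]
    for (e in seq_along(from)) {
      ra <- findRoot(from[e]); rb <- findRoot(to[e])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), findRoot, integer(1))
  comp <- match(root, sort(unique(root)))
  sizes <- tabulate(comp)
  # order: descending size, then first appearance (smallest linear index)
  firstIdx <- vapply(seq_along(sizes), function(c) min(idx[comp == c]), integer(1))
  ord <- order(-sizes, firstIdx)
  relabel <- integer(length(sizes))
  relabel[ord] <- seq_along(sizes)
  out[idx] <- relabel[comp]
  out
}

# Reproducible per-subject seed stream: subject k's seed depends only on the
# master seed and k, not on how many subjects are drawn.
subjectSeed <- function(masterSeed, k) {
  stopifnot(k >= 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(masterSeed)
  sample.int(2147483646L, k)[k]
}

# TRUE if a scan's acquisition times are uniformly spaced at its TR.
isUniformlySampled <- function(scan) {
  tt <- scan@volumeTimesS
  length(tt) < 2L || max(abs(diff(tt) - scan@trS)) < 1e-6 * scan@trS
}

# Fisher z with the documented clipping of |r| at 1 - 1e-7.
fisherZ <- function(r, warnClip = FALSE) {
  clip <- 1 - 1e-7
  if (warnClip && any(abs(r) > clip, na.rm = TRUE))
    warning("correlations at +/-1 clipped to +/-(1 - 1e-7) before atanh")
  atanh(pmin(pmax(r, -clip), clip))
}

# voxel -> linear index helpers for 3-D grids
asVoxelMatrix <- function(arr4d) {
  d <- dim(arr4d)
  matrix(arr4d, nrow = prod(d[1:3]), ncol = d[4])
}

checkSameGrid <- function(a, b, what = "objects") {
  da <- if (length(dim(a)) == 4L) dim(a)[1:3] else dim(a)
  db <- if (length(dim(b)) == 4L) dim(b)[1:3] else dim(b)
  if (!all(da == db))
    stop(sprintf("%s are not on the same spatial grid (%s vs %s)", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  invisible(TRUE)
}

# Dice coefficient of two logical arrays / index sets.
diceOverlap <- function(a, b) {
  ia <- if (is.logical(a)) which(a) else as.integer(a)
  ib <- if (is.logical(b)) which(b) else as.integer(b)
  if (length(ia) == 0L && length(ib) == 0L) return(NA_real_)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}
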