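#' FWHM to Gaussian sigma in voxel units
#'
#' @param fwhmMm kernel full width at half maximum in mm.
#' @param voxelSizeMm voxel edge length in mm along the axis.
#' @return sigma in voxels: \code{fwhmMm / (2 * sqrt(2 * log(2)) * voxelSizeMm)}.
#' @examples
#' fwhmToSigma(6, 3)  # ~0.8493
#' @export
fwhmToSigma <- function(fwhmMm, voxelSizeMm) {
  fwhmMm / (2 * sqrt(2 * log(2)) * voxelSizeMm)
}

# Discrete-cosine high-pass basis: all DCT-II regressors with period >= 1/cutoff,
# i.e. k = 1 .. floor(2 * N * trS * cutoffHz).
dctBasis <- function(n, trS, cutoffHz) {
  K <- floor(2 * n * trS * cutoffHz)
  if (K < 1L) return(matrix(numeric(0), n, 0))
  i <- seq_len(n) - 1L
  sapply(seq_len(K), function(k) cos(pi * k * (2 * i + 1) / (2 * n)))
}

#' High-pass filtering by discrete-cosine basis regression
#'
#' Removes low-frequency content below \code{cutoffHz} by regressing out a
#' discrete-cosine basis spanning all periods >= 1/cutoff (together with the
#' mean), the construction that merges cleanly with confound regression in a
#' single least-squares fit. Requires uniform temporal sampling: scans
#' produced by interleaved rest extraction are refused — filter BEFORE
#' extraction.
#'
#' @param x time x channels numeric matrix, or a \linkS4class{BoldScan}.
#' @param trS repetition time in seconds (taken from the scan when x is a
#'   \linkS4class{BoldScan}).
#' @param cutoffHz high-pass cutoff in Hz; must be below the Nyquist frequency.
#' @param ... unused.
#' @return Filtered object of the same type and shape (mean removed).
#' @export
setMethod("dctHighpass", "matrix", function(x, trS, cutoffHz = 0.01, ...) {
  if (cutoffHz >= 1 / (2 * trS))
    stop("cutoff must be below the Nyquist frequency 1/(2 trS)")
  n <- nrow(x)
  X <- cbind(1, dctBasis(n, trS, cutoffHz))
  x - X %*% qr.solve(X, x)
})

#' @rdname dctHighpass-matrix-method
#' @param x a \linkS4class{BoldScan}.
#' @export
setMethod("dctHighpass", "BoldScan", function(x, trS, cutoffHz = 0.01, ...) {
  if (!isUniformlySampled(x))
    stop("scan has non-uniform acquisition times; apply the high-pass filter ",
         "BEFORE rest extraction")
  m <- t(asVoxelMatrix(x@data))            # time x voxels
  f <- dctHighpass(m, trS = x@trS, cutoffHz = cutoffHz)
  BoldScan(array(t(f), dim(x@data)), trS = x@trS, affine = x@affine,
           volumeTimesS = x@volumeTimesS)
})

#' CompCor nuisance components from noise-tissue signal
#'
#' Principal components of the column-demeaned noise-voxel matrix; the number
#' of components k is the smallest count whose cumulative explained variance
#' reaches \code{varThreshold}. Components are orthonormal over time.
#'
#' @param noiseTs time x noise-voxels matrix (>= 2 voxels, >= 3 time points).
#' @param varThreshold cumulative explained-variance fraction (default 0.5).
#' @return time x k matrix of component time series, with attribute
#'   \code{"explainedVariance"} (cumulative fraction per retained component).
#' @export
compcorComponents <- function(noiseTs, varThreshold = 0.5) {
  noiseTs <- as.matrix(noiseTs)
  if (ncol(noiseTs) < 2L) stop("need at least 2 noise voxels")
  if (nrow(noiseTs) < 3L) stop("need at least 3 time points")
  X <- sweep(noiseTs, 2, colMeans(noiseTs))
  if (max(abs(X)) == 0) stop("noise matrix is degenerate (all columns constant)")
  sv <- svd(X, nu = min(dim(X)), nv = 0)
  ev <- sv$d^2
  ev <- ev[ev > max(ev) * 1e-12]
  cumvar <- cumsum(ev) / sum(ev)
  k <- which(cumvar >= varThreshold)[1]
  out <- sv$u[, seq_len(k), drop = FALSE]
  colnames(out) <- sprintf("compcor_%02d", seq_len(k))
  attr(out, "explainedVariance") <- cumvar[seq_len(k)]
  out
}

#' Friston 24-parameter motion expansion
#'
#' Expands six rigid-body motion parameters into the 24-regressor set:
#' the parameters, their backward-difference derivatives (first row 0), the
#' squared parameters and the squared derivatives.
#'
#' @param motion6 time x 6 matrix (fMRIPrep naming: trans_x..rot_z).
#' @return time x 24 matrix with fMRIPrep-style column names.
#' @export
motionExpansion <- function(motion6) {
  motion6 <- as.matrix(motion6)
  if (ncol(motion6) != 6L)
    stop(sprintf("expected exactly 6 motion parameters, got %d", ncol(motion6)))
  nm <- colnames(motion6)
  if (is.null(nm)) nm <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  d <- rbind(0, diff(motion6))
  out <- cbind(motion6, d, motion6^2, d^2)
  colnames(out) <- c(nm, paste0(nm, "_derivative1"), paste0(nm, "_power2"),
                     paste0(nm, "_derivative1_power2"))
  out
}

#' Confound regression with optional z-standardization
#'
#' Per in-mask voxel, the ordinary-least-squares residual against an intercept
#' plus the confound columns; residuals are orthogonal to every confound. A
#' rank-deficient design is handled by the pseudoinverse with a warning. With
#' \code{standardize = TRUE} each voxel series is scaled to unit sample
#' variance (zero-variance voxels stay zero), so the output is demeaned and
#' z-standardized. Out-of-mask voxels are set to 0.
#'
#' @param scan a \linkS4class{BoldScan}.
#' @param mask a \linkS4class{BrainMask} on the scan grid.
#' @param confounds a \linkS4class{ConfoundMatrix} (or time x p matrix) with
#'   as many rows as the scan has volumes.
#' @param standardize scale residual voxel series to unit variance.
#' @return A denoised \linkS4class{BoldScan}.
#' @export
regressConfounds <- function(scan, mask, confounds, standardize = TRUE) {
  stopifnot(is(scan, "BoldScan"), is(mask, "BrainMask"))
  checkSameGrid(scan@data, mask@data, "scan and mask")
  C <- if (is(confounds, "ConfoundMatrix")) confounds@columns else as.matrix(confounds)
  nt <- dim(scan@data)[4]
  if (nrow(C) != nt)
    stop(sprintf("confounds have %d rows but the scan has %d volumes", nrow(C), nt))
  X <- cbind(intercept = 1, C)
  qrX <- qr(X)
  inmask <- which(mask@data)
  Y <- t(asVoxelMatrix(scan@data)[inmask, , drop = FALSE])  # time x voxels
  if (qrX$rank < ncol(X)) {
    warning("rank-deficient confound design; using the pseudoinverse")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) %*% Y / sv$d[pos])
    R <- Y - X %*% beta
  } else {
    R <- qr.resid(qrX, Y)
  }
  if (standardize) {
    s <- sqrt(colSums(R^2) / (nt - 1))
    nz <- s > 0
    R[, nz] <- sweep(R[, nz, drop = FALSE], 2, s[nz], "/")
  }
  out <- matrix(0, prod(dim(scan@data)[1:3]), nt)
  out[inmask, ] <- t(R)
  BoldScan(array(out, dim(scan@data)), trS = scan@trS, affine = scan@affine,
           volumeTimesS = scan@volumeTimesS)
}

# 1-D Gaussian kernel matrix; each output row renormalized to unit weight so
# constants are preserved exactly (truncation at the grid edge loses no mass)
gaussKernelMatrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- ceiling(4 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    lo <- max(1, j - r); hi <- min(n, j + r)
    K[lo:hi, j] <- k[(lo:hi) - j + r + 1]
  }
  K / rowSums(K)
}

#' Volumewise Gaussian smoothing
#'
#' Convolves each volume with a separable Gaussian of
#' \code{sigma = fwhmMm / (2 sqrt(2 ln 2) voxelSize)} voxels per axis (voxel
#' sizes derived from the affine; anisotropic grids supported). The discrete
#' kernel has unit mass and is renormalized where it is truncated at the grid
#' edge, so constant volumes pass through unchanged and an interior impulse
#' keeps its total mass.
#'
#' @param scan a \linkS4class{BoldScan}.
#' @param fwhmMm kernel FWHM in mm (> 0).
#' @return The smoothed \linkS4class{BoldScan}.
#' @export
smoothGaussian <- function(scan, fwhmMm = 6) {
  stopifnot(is(scan, "BoldScan"))
  if (fwhmMm <= 0) stop("fwhmMm must be positive")
  vox <- sqrt(colSums(scan@affine[1:3, 1:3]^2))
  d <- dim(scan@data)
  arr <- scan@data
  for (ax in 1:3) {
    sigma <- fwhmToSigma(fwhmMm, vox[ax])
    K <- gaussKernelMatrix(d[ax], sigma)
    perm <- c(ax, setdiff(1:4, ax))
    a <- aperm(arr, perm)
    dm <- dim(a)
    a <- K %*% matrix(a, nrow = dm[1])
    dim(a) <- dm
    arr <- aperm(a, order(perm))
  }
  BoldScan(arr, trS = scan@trS, affine = scan@affine,
           volumeTimesS = scan@volumeTimesS)
}

#' One-stop denoising of a full (uniformly sampled) scan
#'
#' Runs the denoising model in a single pass: one OLS against an intercept,
#' the discrete-cosine high-pass basis and the supplied nuisance regressors
#' (CompCor components, motion expansion, ...), with z-standardization, then
#' Gaussian smoothing. Runs on the full continuous series — apply rest
#' extraction afterwards.
#'
#' @param scan a uniformly sampled \linkS4class{BoldScan}.
#' @param mask analysis \linkS4class{BrainMask}.
#' @param confounds optional time x p matrix or \linkS4class{ConfoundMatrix}
#'   of nuisance regressors (beyond the DCT basis).
#' @param cutoffHz high-pass cutoff (default 0.01 Hz); NULL to skip.
#' @param standardize z-standardize residual voxel series (default TRUE).
#' @param fwhmMm smoothing FWHM in mm (default 6); NULL to skip smoothing.
#' @return The denoised \linkS4class{BoldScan}.
#' @export
denoiseScan <- function(scan, mask, confounds = NULL, cutoffHz = 0.01,
                        standardize = TRUE, fwhmMm = 6) {
  if (!isUniformlySampled(scan))
    stop("scan has non-uniform acquisition times; denoise BEFORE extraction")
  nt <- dim(scan@data)[4]
  X <- matrix(numeric(0), nt, 0)
  if (!is.null(cutoffHz)) {
    if (cutoffHz >= 1 / (2 * scan@trS))
      stop("cutoff must be below the Nyquist frequency")
    X <- cbind(X, dctBasis(nt, scan@trS, cutoffHz))
  }
  if (!is.null(confounds)) {
    C <- if (is(confounds, "ConfoundMatrix")) confounds@columns else as.matrix(confounds)
    X <- cbind(X, C)
  }
  out <- regressConfounds(scan, mask, X, standardize = standardize)
  if (!is.null(fwhmMm)) out <- smoothGaussian(out, fwhmMm)
  out
}

#' Read / write confounds as TSV
#'
#' fMRIPrep-style tab-separated confound files with a header line.
#'
#' @param path TSV path.
#' @return For \code{readConfoundsTsv}, a numeric matrix with column names.
#' @export
readConfoundsTsv <- function(path) {
  as.matrix(utils::read.delim(path, check.names = FALSE))
}

#' @rdname readConfoundsTsv
#' @param x numeric matrix (or ConfoundMatrix) to write.
#' @export
writeConfoundsTsv <- function(x, path) {
  m <- if (is(x, "ConfoundMatrix")) x@columns else as.matrix(x)
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
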