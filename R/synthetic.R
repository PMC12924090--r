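#' Per-volume condition labels for a block protocol
#'
#' Expands a \linkS4class{ScanProtocol} into per-volume "rest"/"task" labels:
#' blocks of \code{blockLenS / trS} consecutive volumes, alternating starting
#' with \code{startsWith}. A protocol with \code{nBlockPairs = 0} (continuous
#' rest) yields all-"rest" labels.
#'
#' @param protocol a \linkS4class{ScanProtocol}.
#' @return A \linkS4class{BlockDesign} of length \code{nVolumes(protocol)}.
#' @examples
#' design <- makeBlockDesign(taskProtocol())
#' table(designLabels(design))  # 100 rest, 100 task
#' @export
makeBlockDesign <- function(protocol) {
  stopifnot(is(protocol, "ScanProtocol"))
  validObject(protocol)
  if (protocol@nBlockPairs == 0L)
    return(BlockDesign(rep("rest", protocol@nVolumes)))
  if (abs(protocol@blockLenS %% protocol@trS) > 1e-9)
    stop("block length is not divisible by the repetition time")
  perBlock <- as.integer(round(protocol@blockLenS / protocol@trS))
  first <- protocol@startsWith
  second <- if (first == "rest") "task" else "rest"
  labels <- rep(rep(c(first, second), protocol@nBlockPairs), each = perBlock)
  BlockDesign(labels)
}

#' Canonical double-gamma haemodynamic response function
#'
#' The conventional canonical shape: a gamma density peaking ~5 s after the
#' event minus a later undershoot gamma (undershoot delay 16, peak/undershoot
#' ratio 6), normalized to unit peak. Zero at t = 0 and decaying to zero for
#' large t.
#'
#' @param t time in seconds since the event (>= 0, vectorised).
#' @param peakDelay shape of the response gamma (rate 1), default 6.
#' @param undershootDelay shape of the undershoot gamma (rate 1), default 16.
#' @param ratio response/undershoot amplitude ratio, default 6.
#' @return Response amplitude(s), unit peak.
#' @export
canonicalHrf <- function(t, peakDelay = 6, undershootDelay = 16, ratio = 6) {
  if (any(t < 0)) stop("t must be >= 0")
  raw <- function(x) stats::dgamma(x, shape = peakDelay, rate = 1) -
    stats::dgamma(x, shape = undershootDelay, rate = 1) / ratio
  peak <- stats::optimize(raw, c(0, 32), maximum = TRUE, tol = 1e-10)$objective
  raw(t) / peak
}

# --- default study fixtures -------------------------------------------------

#' Default planted network specification
#'
#' A 24 x 24 x 18 voxel grid at 3 mm isotropic with ten spherical ROIs
#' (radius 2 voxels) organised in four networks: a DMN-like network of five
#' regions (mpfc, pcc, lAG, rAG, pcu), an SMN-like network of three regions
#' (psmc, lIAC, rIAC) and left/right hippocampus-like single-ROI networks
#' used as seeds. ROI loadings within a network are deliberately
#' heterogeneous so the true within-network correlation structure has
#' distinct, rankable entries. The task activates the SMN-like network.
#'
#' @return A \linkS4class{NetworkSpec}.
#' @export
defaultNetworkSpec <- function() {
  rois <- data.frame(
    name = c("mpfc", "pcc", "lAG", "rAG", "pcu",
             "psmc", "lIAC", "rIAC", "lhpc", "rhpc"),
    x = c(12, 12,  5, 19, 12,  12,  5, 19,  6, 18),
    y = c(20,  4,  8,  8, 12,  16, 16, 16,  4,  4),
    z = c( 9,  9, 13, 13,  4,  15,  5,  5,  5,  5),
    radius = 2,
    network = c(rep("dmn", 5), rep("smn", 3), "lhpc", "rhpc"),
    loading = c(1.3, 1.0, 0.75, 0.5, 0.3,
                1.3, 0.55, 0.3, 1.0, 1.0),
    stringsAsFactors = FALSE)
  nets <- c("dmn", "smn", "lhpc", "rhpc")
  S <- diag(4)
  dimnames(S) <- list(nets, nets)
  S["dmn", "smn"] <- S["smn", "dmn"] <- 0.15
  S["dmn", "lhpc"] <- S["lhpc", "dmn"] <- 0.35
  S["dmn", "rhpc"] <- S["rhpc", "dmn"] <- 0.35
  S["smn", "lhpc"] <- S["lhpc", "smn"] <- 0.10
  S["smn", "rhpc"] <- S["rhpc", "smn"] <- 0.10
  S["lhpc", "rhpc"] <- S["rhpc", "lhpc"] <- 0.30
  NetworkSpec(gridShape = c(24L, 24L, 18L), voxelSizeMm = 3, rois = rois,
              networkCovariance = S, taskNetworks = "smn")
}

# ROI/network label maps for a NetworkSpec
specLabelMaps <- function(spec) {
  nets <- rownames(spec@networkCovariance)
  roiMap <- array(0L, spec@gridShape)
  netMap <- array(0L, spec@gridShape)
  for (i in seq_len(nrow(spec@rois))) {
    r <- spec@rois[i, ]
    vox <- sphereIndices(spec@gridShape, c(r$x, r$y, r$z), r$radius)
    if (any(roiMap[vox] != 0L)) stop("ROI spheres overlap: ", r$name)
    roiMap[vox] <- i
    netMap[vox] <- match(r$network, nets)
  }
  list(roiMap = roiMap, networkMap = netMap, networks = nets)
}

#' Ground-truth template atlas of a network specification
#'
#' The planted network label map packaged as a \linkS4class{TemplateAtlas},
#' playing the role the reference network atlas plays for real data.
#'
#' @param spec a \linkS4class{NetworkSpec}.
#' @return A \linkS4class{TemplateAtlas}.
#' @export
specTemplateAtlas <- function(spec) {
  maps <- specLabelMaps(spec)
  TemplateAtlas(maps$networkMap,
                structure(seq_along(maps$networks), names = maps$networks))
}

#' Ground-truth ROI atlas of a network specification
#'
#' @param spec a \linkS4class{NetworkSpec}.
#' @return A \linkS4class{RoiAtlas} with the planted spheres as ROIs.
#' @export
specRoiAtlas <- function(spec) {
  maps <- specLabelMaps(spec)
  RoiAtlas(maps$roiMap, spec@rois$name,
           affine = diag(c(rep(spec@voxelSizeMm, 3), 1)))
}

# Simulate one scan (internal): latent network series + ROI loadings +
# optional task activation + AR(1) noise + low-rank drift + baseline.
simulateScan <- function(spec, protocol, noise, task = FALSE, taskAmplitude = 1) {
  nT <- protocol@nVolumes
  nets <- rownames(spec@networkCovariance)
  K <- length(nets)
  V <- prod(spec@gridShape)

  Lchol <- tryCatch(chol(spec@networkCovariance),
                    error = function(e) stop("networkCovariance is not positive definite"))
  latent <- matrix(stats::rnorm(nT * K), nT, K) %*% Lchol
  colnames(latent) <- nets

  # AR(1) noise with marginal sd = whiteSd
  dat <- matrix(0, nT, V)
  if (noise@whiteSd > 0) {
    innovSd <- noise@whiteSd * sqrt(1 - noise@ar1Phi^2)
    eps <- matrix(stats::rnorm(nT * V, sd = innovSd), nT, V)
    dat[1, ] <- eps[1, ] / sqrt(1 - noise@ar1Phi^2)
    if (nT > 1) for (t in 2:nT) dat[t, ] <- noise@ar1Phi * dat[t - 1, ] + eps[t, ]
  }

  # low-rank drift: shared linear + cosine (period 128 s) shapes, per-voxel
  # Gaussian amplitudes
  if (noise@driftAmp > 0) {
    tt <- (seq_len(nT) - 1) * protocol@trS
    lin <- scale(tt)[, 1]
    cosb <- cos(2 * pi * tt / 128)
    cosb <- (cosb - mean(cosb)) / stats::sd(cosb)
    amp <- matrix(stats::rnorm(2 * V, sd = noise@driftAmp / sqrt(2)), 2, V)
    dat <- dat + cbind(lin, cosb) %*% amp
  }

  # planted signal
  design <- makeBlockDesign(protocol)
  taskReg <- NULL
  if (task && length(spec@taskNetworks) > 0) {
    box <- as.numeric(designLabels(design) == "task")
    h <- canonicalHrf(seq(0, 32, by = protocol@trS))
    taskReg <- stats::convolve(box, rev(h), type = "open")[seq_len(nT)]
  }
  for (i in seq_len(nrow(spec@rois))) {
    r <- spec@rois[i, ]
    vox <- sphereIndices(spec@gridShape, c(r$x, r$y, r$z), r$radius)
    sig <- r$loading * latent[, r$network]
    if (!is.null(taskReg) && r$network %in% spec@taskNetworks)
      sig <- sig + taskAmplitude * r$loading * taskReg
    dat[, vox] <- dat[, vox] + sig
  }

  dat <- dat + noise@baseline
  arr <- array(t(dat), c(spec@gridShape, nT))
  BoldScan(arr, trS = protocol@trS,
           affine = diag(c(rep(spec@voxelSizeMm, 3), 1)))
}

#' Simulate one subject's paired acquisitions
#'
#' Generates a blocked task scan and a continuous rest scan for one subject.
#' Each network has a latent time series drawn with the specified network
#' covariance; ROI voxels receive \code{loading * latent}, task scans
#' additionally receive the block design convolved with the canonical HRF in
#' the task networks, and every voxel receives AR(1) noise, low-rank drift
#' and the baseline. The same seed reproduces the scans bit-identically.
#'
#' @param spec a \linkS4class{NetworkSpec}.
#' @param taskProtocol,restProtocol \linkS4class{ScanProtocol}s for the two
#'   acquisitions (defaults: the blocked 200-volume task protocol and the
#'   8.5-min, 170-volume continuous rest protocol).
#' @param noise a \linkS4class{NoiseModel}.
#' @param seed integer seed.
#' @param taskAmplitude scale of the task activation added to task-network
#'   ROIs (multiplied by the ROI loading).
#' @return A list with elements \code{task} (\linkS4class{BoldScan}),
#'   \code{rest} (\linkS4class{BoldScan}) and \code{truth}
#'   (\linkS4class{GroundTruth}).
#' @export
simulateSubject <- function(spec, taskProtocol = interRest::taskProtocol(),
                            restProtocol = interRest::restProtocol(),
                            noise = NoiseModel(), seed, taskAmplitude = 1) {
  stopifnot(is(spec, "NetworkSpec"), is(noise, "NoiseModel"))
  validObject(spec); validObject(noise)
  set.seed(as.integer(seed))
  taskScan <- simulateScan(spec, taskProtocol, noise, task = TRUE,
                           taskAmplitude = taskAmplitude)
  restScan <- simulateScan(spec, restProtocol, noise, task = FALSE)

  maps <- specLabelMaps(spec)
  nets <- maps$networks
  R <- stats::cov2cor(spec@networkCovariance)
  ni <- match(spec@rois$network, nets)
  roiCor <- R[ni, ni, drop = FALSE]
  diag(roiCor) <- 1
  dimnames(roiCor) <- list(spec@rois$name, spec@rois$name)
  truth <- new("GroundTruth", networkMap = maps$networkMap,
               roiMap = maps$roiMap, roiCorrelation = roiCor,
               conditionLabels = designLabels(makeBlockDesign(taskProtocol)),
               networks = nets, roiNames = spec@rois$name,
               roiNetworks = spec@rois$network, seed = as.integer(seed))
  list(task = taskScan, rest = restScan, truth = truth)
}

#' Simulate a two-group cohort with a planted connectivity difference
#'
#' Group A subjects are generated from \code{spec}; group B subjects from a
#' copy whose network covariance entry for the designated \code{pair} of
#' networks is shifted by \code{effect} (correlation units). Subject k is
#' reproducible from the master seed independently of the cohort size.
#'
#' @param nPerGroup subjects per group (>= 2).
#' @param spec a \linkS4class{NetworkSpec}.
#' @param effect covariance shift applied to \code{pair} in group B; must keep
#'   the covariance positive definite.
#' @param seed master integer seed.
#' @param pair character 2-vector of network ids whose coupling differs
#'   between groups.
#' @param taskProtocol,restProtocol,noise,taskAmplitude passed to
#'   \code{\link{simulateSubject}}.
#' @return A list with \code{subjects} (each: id, group, task, rest),
#'   \code{truthA}, \code{truthB}, \code{specA}, \code{specB}, \code{pair},
#'   \code{effect}, \code{seed}.
#' @export
simulateCohort <- function(nPerGroup, spec = defaultNetworkSpec(), effect = 0,
                           seed, pair = c("lhpc", "rhpc"),
                           taskProtocol = interRest::taskProtocol(),
                           restProtocol = interRest::restProtocol(),
                           noise = NoiseModel(), taskAmplitude = 1) {
  if (nPerGroup < 2L) stop("nPerGroup must be >= 2")
  stopifnot(length(pair) == 2L, all(pair %in% rownames(spec@networkCovariance)))
  specB <- spec
  S <- specB@networkCovariance
  S[pair[1], pair[2]] <- S[pair[1], pair[2]] + effect
  S[pair[2], pair[1]] <- S[pair[1], pair[2]]
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("effect pushes the group-B covariance outside the positive-definite cone")
  specB@networkCovariance <- S

  subjects <- vector("list", 2L * nPerGroup)
  truthA <- truthB <- NULL
  for (k in seq_len(2L * nPerGroup)) {
    grp <- if (k <= nPerGroup) "A" else "B"
    sk <- subjectSeed(seed, k)
    sub <- simulateSubject(if (grp == "A") spec else specB,
                           taskProtocol = taskProtocol,
                           restProtocol = restProtocol, noise = noise,
                           seed = sk, taskAmplitude = taskAmplitude)
    if (grp == "A" && is.null(truthA)) truthA <- sub$truth
    if (grp == "B" && is.null(truthB)) truthB <- sub$truth
    subjects[[k]] <- list(id = sprintf("sub-%02d", k), group = grp,
                          task = sub$task, rest = sub$rest)
  }
  list(subjects = subjects, truthA = truthA, truthB = truthB,
       specA = spec, specB = specB, pair = pair, effect = effect,
       seed = as.integer(seed))
}

#' Write a demo cohort to a directory
#'
#' Writes each subject's task and rest scans as NIfTI, the ground-truth
#' network and ROI label maps as NIfTI, and a YAML sidecar with the network
#' covariance, group labels and seeds.
#'
#' @param cohort result of \code{\link{simulateCohort}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aff <- diag(c(rep(cohort$specA@voxelSizeMm, 3), 1))
  for (s in cohort$subjects) {
    saveScan(s$task, file.path(dir, paste0(s$id, "_task.nii.gz")))
    saveScan(s$rest, file.path(dir, paste0(s$id, "_rest.nii.gz")))
  }
  tr <- cohort$truthA
  saveVolume(array(as.numeric(tr@networkMap), dim(tr@networkMap)), aff,
             file.path(dir, "truth_networks.nii.gz"), datatype = "int16")
  saveVolume(array(as.numeric(tr@roiMap), dim(tr@roiMap)), aff,
             file.path(dir, "truth_rois.nii.gz"), datatype = "int16")
  side <- list(
    seed = cohort$seed, effect = cohort$effect, pair = as.list(cohort$pair),
    networks = as.list(tr@networks), roiNames = as.list(tr@roiNames),
    groups = lapply(cohort$subjects, function(s) list(id = s$id, group = s$group)),
    networkCovarianceA = apply(cohort$specA@networkCovariance, 1, as.list),
    networkCovarianceB = apply(cohort$specB@networkCovariance, 1, as.list))
  yaml::write_yaml(side, file.path(dir, "cohort.yaml"))
  invisible(dir)
}
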