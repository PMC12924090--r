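# Full two-arm validation: synthetic cohort -> denoise -> rest extraction /
# continuous rest -> group ICA + template matching -> intersection ROIs ->
# within-network connectivity + similarity tests -> seed-based group inference.

# voxels safely outside the planted ROIs: the complement of the ROI union
# eroded by one voxel (26-neighbourhood), the synthetic stand-in for the
# white-matter/CSF noise tissue CompCor draws from
noiseVoxelMask <- function(roiMap) {
  dm <- dim(roiMap)
  roi <- roiMap > 0
  dil <- roi
  off <- neighbourOffsets(26L)
  co <- arrayInd(which(roi), dm)
  for (k in seq_len(nrow(off))) {
    nx <- co[, 1] + off[k, 1]; ny <- co[, 2] + off[k, 2]; nz <- co[, 3] + off[k, 3]
    ok <- nx >= 1 & nx <= dm[1] & ny >= 1 & ny <= dm[2] & nz >= 1 & nz <= dm[3]
    dil[cbind(nx[ok], ny[ok], nz[ok])] <- TRUE
  }
  !dil
}

# CompCor + DCT + regression + smoothing for one scan
denoiseWithCompcor <- function(scan, mask, noiseVox, cutoffHz, varThreshold,
                               fwhmMm) {
  noiseTs <- t(asVoxelMatrix(scan@data)[noiseVox, , drop = FALSE])
  cc <- compcorComponents(noiseTs, varThreshold = varThreshold)
  denoiseScan(scan, mask, confounds = cc, cutoffHz = cutoffHz,
              standardize = TRUE, fwhmMm = fwhmMm)
}

armSimilarity <- function(cmA, cmB, nIter, seed) {
  K <- length(roiLabels(cmA))
  if (K <= 4L) mantelExact(cmA, cmB)
  else permutationSimilarity(cmA, cmB, nIter = nIter, seed = seed)
}

groupMeanZ <- function(scans, atlas) {
  zs <- lapply(scans, function(s) zValues(fisherZMatrix(roiTimeseries(s, atlas))))
  m <- Reduce(`+`, zs) / length(zs)
  diag(m) <- 0
  ConnectivityMatrix((m + t(m)) / 2, roiLabels = rownames(zs[[1]]))
}

similarityAsList <- function(sim) {
  list(rho = sim@rho, p = sim@p, method = sim@method, nIter = sim@nIter,
       seed = if (is.na(sim@seed)) NULL else sim@seed)
}

configAsList <- function(config) {
  list(nPerGroup = config@nPerGroup, effect = config@effect,
       cohortSeed = config@cohortSeed,
       scheme = list(nDiscardScanStart = config@scheme@nDiscardScanStart,
                     nKeepTaskStart = config@scheme@nKeepTaskStart,
                     nDiscardRestStart = config@scheme@nDiscardRestStart),
       cutoffHz = config@cutoffHz,
       compcorVarThreshold = config@compcorVarThreshold,
       fwhmMm = config@fwhmMm, nComponents = config@nComponents,
       icaSeed = config@icaSeed, zThresh = config@zThresh,
       minRoiSize = config@minRoiSize, connectivity = config@connectivity,
       nIter = config@nIter, nPerm = config@nPerm, statSeed = config@statSeed,
       voxelP = config@voxelP, clusterQ = config@clusterQ,
       subsampleRest = config@subsampleRest,
       symmetryControl = config@symmetryControl)
}

clustersAsList <- function(gc) {
  tab <- clusterTable(gc)
  list(df = gc@df, nPerm = gc@nPerm,
       nCandidates = nrow(tab), nSignificant = sum(tab$significant),
       clusters = if (nrow(tab)) lapply(seq_len(nrow(tab)), function(i)
         as.list(tab[i, , drop = FALSE])) else list())
}

#' Run the full intermittent-vs-continuous validation
#'
#' Generates (or reuses) a synthetic cohort, denoises every scan (CompCor
#' components from non-ROI tissue + discrete-cosine high-pass in one OLS,
#' z-standardization, Gaussian smoothing), builds the intermittent arm by
#' interleaved rest extraction of the task scans and the continuous arm from
#' the rest scans, then compares the two arms at three levels: ICA-derived
#' network topography against the planted template, within-network Fisher-z
#' connectivity over the arms' intersection ROIs, and seed-based group
#' comparisons with permutation cluster-extent inference for both hippocampal
#' seeds. Fully reproducible from the configuration's seeds.
#'
#' @param config a \linkS4class{ValidationConfig}.
#' @param outDir output directory for the report, resolved configuration,
#'   tables and maps (created if needed).
#' @param spec the planted \linkS4class{NetworkSpec} (default
#'   \code{\link{defaultNetworkSpec}}).
#' @param noise the \linkS4class{NoiseModel}.
#' @param cohort optionally, a precomputed \code{\link{simulateCohort}} result
#'   consistent with \code{config} (skips simulation).
#' @param networks template networks to analyse (default DMN- and SMN-like).
#' @param seeds seed ROI names for group inference (default both hippocampi).
#' @return The validation report (a nested list, also written as
#'   \code{report.json}), invisibly carrying the stage objects in
#'   \code{attr(, "objects")}.
#' @export
runValidation <- function(config = validationConfig(), outDir = tempfile("interrest_"),
                          spec = defaultNetworkSpec(), noise = NoiseModel(),
                          cohort = NULL, networks = c("dmn", "smn"),
                          seeds = c("lhpc", "rhpc")) {
  stopifnot(is(config, "ValidationConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run.log")
  logCon <- file(logPath, open = "wt")
  on.exit(close(logCon), add = TRUE)
  t0 <- proc.time()[3]
  stage <- function(msg) writeLines(sprintf("[%8.1fs] %s", proc.time()[3] - t0, msg),
                                    logCon)
  withClipLog <- function(expr) withCallingHandlers(expr, warning = function(w) {
    stage(paste("warning:", conditionMessage(w)))
    invokeRestart("muffleWarning")
  })

  stage("simulating cohort")
  if (is.null(cohort))
    cohort <- simulateCohort(config@nPerGroup, spec = spec,
                             effect = config@effect, seed = config@cohortSeed,
                             noise = noise)
  truth <- cohort$truthA
  aff <- diag(c(rep(spec@voxelSizeMm, 3), 1))
  mask <- BrainMask(array(TRUE, spec@gridShape), affine = aff)
  noiseVox <- which(noiseVoxelMask(truth@roiMap))

  stage("denoising")
  denTask <- denRest <- vector("list", length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    denTask[[i]] <- withClipLog(denoiseWithCompcor(
      s$task, mask, noiseVox, config@cutoffHz, config@compcorVarThreshold,
      config@fwhmMm))
    denRest[[i]] <- withClipLog(denoiseWithCompcor(
      s$rest, mask, noiseVox, config@cutoffHz, config@compcorVarThreshold,
      config@fwhmMm))
  }
  groups <- vapply(cohort$subjects, `[[`, character(1), "group")

  stage("rest extraction")
  design <- BlockDesign(truth@conditionLabels)
  idx <- restVolumeIndices(design, config@scheme)
  writeIndexSidecar(idx, file.path(outDir, "retained_indices.json"))
  if (config@symmetryControl) {
    armInt <- denRest
  } else {
    armInt <- lapply(denTask, extractVolumes, indices = idx)
  }
  armRest <- denRest
  if (config@subsampleRest && !config@symmetryControl)
    armRest <- lapply(armRest, middleSubsample,
                      n = nVolumes(armInt[[1]]))

  stage("group spatial ICA (intermittent arm)")
  icaInt <- spatialIca(concatSubjects(armInt, mask), config@nComponents,
                       seed = config@icaSeed, mask = mask)
  stage("group spatial ICA (continuous arm)")
  icaRest <- spatialIca(concatSubjects(armRest, mask), config@nComponents,
                        seed = config@icaSeed, mask = mask)

  stage("template matching + intersection ROIs")
  template <- specTemplateAtlas(spec)
  inmaskN <- sum(mask@data)
  matchTab <- list()
  topo <- list()
  roiAtlases <- list()
  withinNet <- list()
  for (net in networks) {
    mInt <- matchToTemplate(icaInt, template, net)
    mRest <- matchToTemplate(icaRest, template, net)
    volInt <- componentVolume(icaInt, mInt@component, mInt@sign)
    volRest <- componentVolume(icaRest, mRest@component, mRest@sign)
    rBetween <- as.numeric(stats::cor(volInt[which(mask@data)],
                                      volRest[which(mask@data)]))
    # identical arms give rBetween = 1 exactly; nudge inside the open interval
    # the dependent-correlation test is defined on
    clamp <- function(r) max(min(r, 1 - 1e-9), -1 + 1e-9)
    pDiff <- compareDependentCorrelations(clamp(mInt@r), clamp(mRest@r),
                                          clamp(rBetween), nEff = inmaskN / 10)
    atlasNet <- intersectAndLabel(thresholdMap(volInt, config@zThresh),
                                  thresholdMap(volRest, config@zThresh),
                                  minSize = config@minRoiSize,
                                  connectivity = config@connectivity)
    atlasNet@affine <- aff
    roiAtlases[[net]] <- atlasNet
    saveVolume(array(as.numeric(labelMap(atlasNet)), dim(labelMap(atlasNet))),
               aff, file.path(outDir, sprintf("intersection_%s.nii.gz", net)),
               datatype = "int16")
    matchTab[[net]] <- list(
      intermittent = list(component = mInt@component, r = mInt@r, sign = mInt@sign),
      rest = list(component = mRest@component, r = mRest@r, sign = mRest@sign))
    topo[[net]] <- list(betweenArmR = rBetween,
                        templateCorrelationDifferenceP = as.numeric(pDiff))

    cmInt <- groupMeanZ(armInt, atlasNet)
    cmRest <- groupMeanZ(armRest, atlasNet)
    writeConnectivityTsv(cmInt, file.path(outDir, sprintf("connectivity_%s_intermittent.tsv", net)))
    writeConnectivityTsv(cmRest, file.path(outDir, sprintf("connectivity_%s_rest.tsv", net)))
    sim <- armSimilarity(cmInt, cmRest, nIter = config@nIter,
                         seed = config@statSeed + match(net, networks))
    withinNet[[net]] <- c(list(nRois = length(roiLabels(cmInt)),
                               spearmanRho = spearmanUppertri(cmInt, cmRest)),
                          similarityAsList(sim))
  }

  stage("seed-based group inference")
  atlasGT <- specRoiAtlas(spec)
  isA <- groups == "A"
  groupResults <- list()
  diceBetweenArms <- list()
  arms <- list(intermittent = armInt, rest = armRest)
  for (sname in seeds) {
    perArm <- list()
    sigVox <- list()
    for (an in names(arms)) {
      maps <- lapply(arms[[an]], seedMap, atlas = atlasGT, seed = sname, mask = mask)
      tt <- withClipLog(voxelTtest(maps[isA], maps[!isA]))
      cand <- formClusters(tt$tMap, tt$df, voxelP = config@voxelP,
                           connectivity = config@connectivity)
      fit <- clusterInference(cand, maps[isA], maps[!isA], nPerm = config@nPerm,
                             clusterQ = config@clusterQ,
                             seed = config@statSeed + 100 + match(sname, seeds) * 10 +
                               match(an, names(arms)),
                             voxelP = config@voxelP,
                             connectivity = config@connectivity)
      writeClusterTsv(fit, file.path(outDir, sprintf("clusters_%s_%s.tsv", sname, an)))
      saveVolume(fit@tMap, aff, file.path(outDir, sprintf("tmap_%s_%s.nii.gz", sname, an)))
      perArm[[an]] <- clustersAsList(fit)
      sigIdx <- unlist(fit@members[clusterTable(fit)$significant], use.names = FALSE)
      sigVox[[an]] <- if (is.null(sigIdx)) integer(0) else sigIdx
    }
    groupResults[[sname]] <- perArm
    diceBetweenArms[[sname]] <- diceOverlap(sigVox$intermittent, sigVox$rest)
  }

  stage("writing report")
  cfgPath <- file.path(outDir, "config.yaml")
  yaml::write_yaml(configAsList(config), cfgPath)
  report <- list(
    templateMatch = matchTab,
    topography = topo,
    intersectionRoiCount = lapply(roiAtlases, function(a) length(roiLabels(a))),
    withinNetwork = withinNet,
    groupInference = groupResults,
    diceSignificantClusters = diceBetweenArms,
    provenance = list(configHash = unname(tools::md5sum(cfgPath)),
                      cohortSeed = config@cohortSeed,
                      icaSeed = config@icaSeed, statSeed = config@statSeed,
                      nSubjects = length(cohort$subjects),
                      retainedVolumes = length(idx),
                      package = as.character(utils::packageVersion("interRest"))))
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  stage("done")
  attr(report, "objects") <- list(cohort = cohort, icaIntermittent = icaInt,
                                  icaRest = icaRest, roiAtlases = roiAtlases,
                                  mask = mask, outDir = outDir)
  invisible(report)
}
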