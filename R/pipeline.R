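# End-to-end condition runners enforcing the FWE wiring rule, the split-half
# reliability study and the cohort-level reliability + prediction experiment.

#' Build a tract definition from phantom ground truth
#'
#' Inclusion ROIs are slabs at the two ends of a phantom bundle (ordered
#' start to end); other bundles' cores become exclusion ROIs.
#'
#' @param truth phantom truth list from \code{\link{buildPhantom}}
#' @param bundleIdx which bundle (default 1)
#' @param slabVox slab thickness in voxels (default 2)
#' @param name,abbreviation labels (default from the tract vocabulary)
#' @return a \linkS4class{TractDefinition}
#' @export
phantomTractDefinition <- function(truth, bundleIdx = 1L, slabVox = 2L,
                                   name = "Right Anterior Thalamic",
                                   abbreviation = "ATR_R") {
  member <- truth$bundleMembership[, , , bundleIdx]
  d3 <- dim(member)
  spec <- truth$spec$bundles[[bundleIdx]]
  axis <- which.max(abs(spec$end - spec$start))
  lo <- min(spec$start[axis], spec$end[axis])
  hi <- max(spec$start[axis], spec$end[axis])
  slab <- function(from, to) {
    m <- array(FALSE, d3)
    idx <- which(member)
    cc <- arrayInd(idx, d3)
    sel <- cc[, axis] >= from & cc[, axis] <= to
    m[idx[sel]] <- TRUE
    m
  }
  include <- list(slab(lo, lo + slabVox - 1), slab(hi - slabVox + 1, hi))
  exclude <- list()
  nb <- dim(truth$bundleMembership)[4]
  for (k in setdiff(seq_len(nb), bundleIdx)) {
    other <- truth$bundleMembership[, , , k] & !member
    if (any(other)) exclude[[length(exclude) + 1]] <- other
  }
  new("TractDefinition", name = name, abbreviation = abbreviation,
      include = include, exclude = exclude)
}

#' Run one pipeline condition on a diffusion volume
#'
#' \code{condition = "fwe"}: the free-water model is fitted (multi- or
#' single-shell depending on the shell count), the corrected signal feeds
#' response estimation, CSD, the FA stopping map and tractography, while the
#' DTI/DKI metric maps sampled into tract profiles are computed from the
#' ORIGINAL signal. \code{condition = "original"}: every stage consumes the
#' original signal and no corrected volume is created. The returned
#' provenance records the signal source of every stage; a wiring violation
#' raises an error.
#'
#' @param dwi a \linkS4class{DWIVolume} with a white-matter mask
#' @param condition "original" or "fwe"
#' @param tracts list of \linkS4class{TractDefinition}s
#' @param seed tracking seed
#' @param seedsPerVoxel,stepMm,maxAngleDeg,stopThreshold tracking parameters
#' @param faThreshold response-function FA selection threshold
#' @param nNodes profile length (default 100)
#' @param metrics metric names to profile; default depends on the shell
#'   count: multi-shell \code{c("dki_awf","dki_fa","dki_md","dki_mk")},
#'   single-shell \code{c("dti_fa","dti_md")}
#' @return list with bundles, density maps, long-format profiles, the SH and
#'   discretized fODF fields, metric maps, the free-water fit (fwe only) and
#'   a provenance table
#' @export
runCondition <- function(dwi, condition = c("original", "fwe"),
                         tracts, seed = 1L, seedsPerVoxel = 8L, stepMm = 0.9,
                         maxAngleDeg = 30, stopThreshold = 0.2,
                         faThreshold = 0.7, nNodes = 100L, metrics = NULL) {
  condition <- match.arg(condition)
  wm <- dwi@wmMask
  if (is.null(wm)) stop("runCondition requires a white-matter mask")
  nShells <- length(setdiff(unique(dwi@gtab@shellIds), 0L))
  mode <- if (nShells >= 2) "multi-shell" else "single-shell"
  prov <- list()
  note <- function(stage, source) {
    prov[[length(prov) + 1]] <<- data.frame(stage = stage, source = source,
                                            condition = condition)
  }

  fwFit <- NULL
  if (condition == "fwe") {
    fwFit <- if (mode == "multi-shell") fitFwdtiMultishell(dwi, mask = wm)
             else fitFwdtiSingleshell(dwi, mask = wm)
    trackDwi <- eliminateFreeWater(dwi, fwFit)
    note("free-water-fit", "original")
    note("tracking-signal", "fwe-corrected")
  } else {
    trackDwi <- dwi
    note("tracking-signal", "original")
  }

  ## tissue metrics ALWAYS from the original signal
  if (is.null(metrics))
    metrics <- if (mode == "multi-shell")
      c("dki_awf", "dki_fa", "dki_md", "dki_mk") else c("dti_fa", "dti_md")
  metricMaps <- list()
  if (any(startsWith(metrics, "dki"))) {
    kfit <- fitDki(dwi, mask = wm)
    ks <- dkiScalars(kfit)
    metricMaps$dki_fa <- ks$fa; metricMaps$dki_md <- ks$md
    metricMaps$dki_mk <- ks$mk
    if ("dki_awf" %in% metrics) metricMaps$dki_awf <- wmtiAwf(kfit)
  }
  if (any(startsWith(metrics, "dti"))) {
    dfit <- fitDti(dwi, mask = wm)
    ds <- dtiScalars(dfit)
    metricMaps$dti_fa <- ds$fa; metricMaps$dti_md <- ds$md
  }
  metricMaps <- metricMaps[metrics]
  note("metric-maps", "original")

  ## fODF + tracking from the (possibly corrected) tracking signal
  response <- estimateResponse(trackDwi, faThreshold = faThreshold, mask = wm)
  sh <- fitCsd(trackDwi, response, mask = wm)
  odf <- discretizeFodf(sh)
  stopFit <- fitDti(trackDwi, mask = wm)
  stopMap <- dtiScalars(stopFit)$fa
  note("fodf", if (condition == "fwe") "fwe-corrected" else "original")
  sls <- trackProbabilistic(odf, wm, dwi@affine,
                            seedsPerVoxel = seedsPerVoxel, stepMm = stepMm,
                            maxAngleDeg = maxAngleDeg, stopMap = stopMap,
                            stopThreshold = stopThreshold, seed = seed)
  d3 <- dim(wm)
  bundles <- list(); densityMaps <- list(); profRows <- list()
  for (tr in tracts) {
    b <- selectBundle(sls, tr, dwi@affine)
    b <- if (nStreamlines(b) >= 3) cleanBundle(b, nNodes = nNodes) else b
    bundles[[tr@abbreviation]] <- b
    densityMaps[[tr@abbreviation]] <-
      tractDensityMap(b, d3, dwi@affine, normalize = TRUE)
    for (me in names(metricMaps)) {
      p <- suppressWarnings(
        computeTractProfile(b, metricMaps[[me]], dwi@affine,
                            nNodes = nNodes, tract = tr@abbreviation,
                            metric = me))
      profRows[[length(profRows) + 1]] <-
        data.frame(tract = tr@abbreviation, metric = me,
                   node = seq_len(nNodes), value = p@values)
    }
  }
  provenance <- do.call(rbind, prov)
  ## wiring self-check: in the fwe condition metric maps must be original
  if (condition == "fwe" &&
      provenance$source[provenance$stage == "metric-maps"] != "original")
    stop("wiring violation: metric maps derived from corrected signal")
  list(condition = condition, mode = mode, fwFit = fwFit, response = response,
       sh = sh, odf = odf, streamlines = sls, bundles = bundles,
       densityMaps = densityMaps,
       profiles = do.call(rbind, profRows) %||% data.frame(),
       metricMaps = metricMaps, provenance = provenance)
}

#' Split-half reliability study for one subject
#'
#' Runs the pipeline on both halves under both conditions and computes the
#' three reliability statistics: per-voxel fODF explained variance
#' (stratified by the supplied masks), per-tract weighted Dice between the
#' halves' density maps, and per-tract/metric ICC(2,1) over profile nodes.
#'
#' @param split a \linkS4class{SplitHalfPair}
#' @param tracts list of \linkS4class{TractDefinition}s
#' @param strata named list of 3D logical masks (e.g. wmh, nawm)
#' @param conditions conditions to run (default both)
#' @param seed tracking seed for half A
#' @param seedB tracking seed for half B (default \code{seed + 1}; pass
#'   \code{seed} to make the two pipeline runs seed-identical)
#' @param ... passed to \code{\link{runCondition}}
#' @return a \linkS4class{ReliabilityReport}
#' @export
reliabilityStudy <- function(split, tracts, strata,
                             conditions = c("original", "fwe"),
                             seed = 1L, seedB = seed + 1L, ...) {
  if (!length(conditions)) stop("at least one condition required")
  voxelRows <- list(); diceRows <- list(); iccRows <- list()
  for (cond in conditions) {
    ra <- runCondition(split@halfA, cond, tracts, seed = seed, ...)
    rb <- runCondition(split@halfB, cond, tracts, seed = seedB, ...)
    r2 <- fodfReliabilityMap(ra$odf, rb$odf)
    for (st in names(strata)) {
      vals <- r2[strata[[st]] & !is.na(r2)]
      vals <- vals[!is.nan(vals)]
      voxelRows[[length(voxelRows) + 1]] <-
        data.frame(condition = cond, stratum = st,
                   meanR2 = mean(vals), nVoxels = length(vals))
    }
    for (ab in names(ra$bundles)) {
      diceRows[[length(diceRows) + 1]] <-
        data.frame(condition = cond, tract = ab,
                   wdice = weightedDice(ra$densityMaps[[ab]],
                                        rb$densityMaps[[ab]]))
      for (me in unique(ra$profiles$metric)) {
        pa <- ra$profiles$value[ra$profiles$tract == ab &
                                ra$profiles$metric == me]
        pb <- rb$profiles$value[rb$profiles$tract == ab &
                                rb$profiles$metric == me]
        ok <- !is.na(pa) & !is.na(pb)
        icc <- if (sum(ok) >= 3) icc21(cbind(pa[ok], pb[ok])) else NaN
        iccRows[[length(iccRows) + 1]] <-
          data.frame(condition = cond, tract = ab, metric = me, icc = icc)
      }
    }
  }
  voxel <- do.call(rbind, voxelRows)
  summ <- data.frame()
  if (all(c("original", "fwe") %in% conditions)) {
    for (st in unique(voxel$stratum)) {
      rf <- voxel$meanR2[voxel$condition == "fwe" & voxel$stratum == st]
      ro <- voxel$meanR2[voxel$condition == "original" & voxel$stratum == st]
      summ <- rbind(summ, data.frame(statistic = "fodf_r2_pct_increase",
                                     stratum = st,
                                     value = percentIncrease(rf, ro)))
    }
  }
  new("ReliabilityReport", voxel = voxel,
      dice = do.call(rbind, diceRows), icc = do.call(rbind, iccRows),
      summary = summ)
}

#' Cohort-scale reliability and prediction experiment on synthetic subjects
#'
#' Simulates \code{nSubjects} phantoms whose ordinal severity score (range
#' 2..6) determines the along-bundle extent of a free-water-contaminated
#' lesion (f = \code{lesionF}); each subject carries its own simulation,
#' split and tracking seed. Per subject, a split-half reliability study is
#' run under both conditions; at the cohort level, full-data tract profiles
#' feed the cross-validated ordinal prediction separately per condition.
#'
#' @param nSubjects number of subjects (default 20)
#' @param seed master seed; subject seeds derive from it
#' @param spec an \code{\link{acquisitionSpec}} (default: the reference
#'   26 b=0 + 32/64/128-direction multi-shell scheme)
#' @param shellMode "multi" (default) analyses the full multi-shell data;
#'   "single" first subsamples to the b = 1000 shell, exercising the
#'   single-shell fitter and DTI metric set
#' @param lesionF lesion free-water fraction (default 0.5)
#' @param snr Rician SNR (default 30)
#' @param gridShape phantom grid (default c(12, 10, 6))
#' @param bundleRadius bundle cylinder radius in mm (default 4.5)
#' @param seedsPerVoxel tracking seeds per voxel
#' @param nFoldsMax outer CV folds cap (reduced to the smallest class size)
#' @param nRepeats CV repetitions for the prediction stage
#' @param verbose print per-subject progress
#' @return list with \code{reliability} (tidy per-subject data.frames:
#'   voxel, dice, icc), \code{summary} (cohort means with SEM and Wilcoxon
#'   signed-rank p-values), \code{prediction} (per-condition
#'   \linkS4class{PredictionReport}s), \code{aucComparison} (per-cut DeLong
#'   results) and \code{scores}
#' @export
runReliabilityExperiment <- function(nSubjects = 20L, seed = 1L,
                                     spec = acquisitionSpec(),
                                     shellMode = c("multi", "single"),
                                     lesionF = 0.5, snr = 30,
                                     gridShape = c(12, 11, 7),
                                     bundleRadius = 3.6,
                                     seedsPerVoxel = 8L, nFoldsMax = 5L,
                                     nRepeats = 5L, verbose = FALSE) {
  shellMode <- match.arg(shellMode)
  gtab <- makeGradientTable(spec, seed = 1000L)
  scores <- rep_len(2:6, nSubjects)
  voxelAll <- list(); diceAll <- list(); iccAll <- list()
  profilesByCond <- list(original = list(), fwe = list())
  for (s in seq_len(nSubjects)) {
    subjSeed <- seed * 1000L + s
    subject <- sprintf("sub-%03d", s)
    ## focal periventricular-style lesion: off-centre box occupying one side
    ## of the bundle cross-section, along-tract extent growing with the score
    frac <- 0.15 + 0.12 * (scores[s] - 2)
    xlo <- round(gridShape[1] * (0.5 - frac / 2)); xhi <- round(gridShape[1] * (0.5 + frac / 2))
    ps <- phantomSpec(gridShape = gridShape,
                      bundles = list(defaultBundle(gridShape,
                                                   radius = bundleRadius)),
                      lesions = list(list(min = c(xlo, 1, 1),
                                          max = c(xhi, ceiling(gridShape[2] / 2),
                                                  gridShape[3]),
                                          f = lesionF)),
                      snr = snr, seed = subjSeed)
    ph <- buildPhantom(ps, gtab)
    if (shellMode == "single")
      ph$dwi <- subsampleSingleShell(ph$dwi, 1000)
    tracts <- list(phantomTractDefinition(ph$truth))
    split <- splitHalf(ph$dwi, seed = subjSeed + 1L, parentId = subject)
    rel <- reliabilityStudy(split, tracts,
                            strata = list(wmh = ph$truth$wmhMask,
                                          nawm = ph$truth$nawmMask),
                            seed = subjSeed + 2L,
                            seedsPerVoxel = seedsPerVoxel)
    voxelAll[[s]] <- cbind(subject = subject, rel@voxel)
    diceAll[[s]] <- cbind(subject = subject, rel@dice)
    iccAll[[s]] <- cbind(subject = subject, rel@icc)
    for (cond in c("original", "fwe")) {
      full <- runCondition(ph$dwi, cond, tracts, seed = subjSeed + 3L,
                           seedsPerVoxel = seedsPerVoxel)
      profilesByCond[[cond]][[s]] <- cbind(subject = subject, full$profiles)
    }
    if (verbose) message(sprintf("subject %d/%d done", s, nSubjects))
  }
  voxel <- do.call(rbind, voxelAll)
  dice <- do.call(rbind, diceAll)
  icc <- do.call(rbind, iccAll)

  ## cohort summaries: subject-level FWE - original differences with SEM
  summ <- list()
  for (st in unique(voxel$stratum)) {
    pick <- function(cond) voxel$meanR2[voxel$stratum == st &
                                        voxel$condition == cond]
    pi <- percentIncrease(pick("fwe"), pick("original"))
    pi <- pi[is.finite(pi)]
    wt <- suppressWarnings(wilcox.test(pi, mu = 0, alternative = "greater"))
    summ[[length(summ) + 1]] <-
      data.frame(statistic = "fodf_r2_pct_increase", stratum = st,
                 mean = mean(pi), sem = sd(pi) / sqrt(length(pi)),
                 p = wt$p.value)
  }
  dDice <- dice$wdice[dice$condition == "fwe"] -
           dice$wdice[dice$condition == "original"]
  dDice <- dDice[is.finite(dDice)]
  wtD <- suppressWarnings(wilcox.test(dDice, mu = 0, alternative = "greater"))
  summ[[length(summ) + 1]] <-
    data.frame(statistic = "wdice_fwe_minus_original", stratum = "tract",
               mean = mean(dDice), sem = sd(dDice) / sqrt(length(dDice)),
               p = wtD$p.value)
  summary <- do.call(rbind, summ)

  ## cohort prediction per condition
  scoreTab <- data.frame(subject = sprintf("sub-%03d", seq_len(nSubjects)),
                         score = scores)
  nFolds <- min(nFoldsMax, min(table(scores)))
  prediction <- list(); decision <- list()
  for (cond in c("original", "fwe")) {
    prof <- do.call(rbind, profilesByCond[[cond]])
    prof$value[!is.finite(prof$value)] <- mean(prof$value[is.finite(prof$value)])
    fm <- assembleFeatures(prof)
    repRes <- crossvalPredict(fm, scoreTab$score[match(fm$subjects,
                                                    scoreTab$subject)],
                           nFolds = nFolds, nRepeats = nRepeats,
                           seed = seed + 17L)
    prediction[[cond]] <- repRes
  }
  ## per-cut DeLong comparison of the two conditions' pooled decision scores
  aucCmp <- list()
  classes <- sort(unique(scores))
  probCols <- paste0("p", classes)
  pooled <- lapply(prediction, function(rep) {
    agg <- aggregate(rep@predictions[probCols],
                     by = list(subject = rep@predictions$subject), FUN = mean)
    agg$truth <- rep@predictions$truth[match(agg$subject,
                                             rep@predictions$subject)]
    agg
  })
  for (c0 in classes[-length(classes)]) {
    hiCols <- paste0("p", classes[classes > c0])
    lab <- pooled$fwe$truth > c0
    if (!any(lab) || all(lab)) next
    d1 <- rowSums(as.matrix(pooled$fwe[hiCols]))
    d2 <- rowSums(as.matrix(pooled$original[hiCols]))
    dt <- delongTest(lab, d1, d2)
    aucCmp[[length(aucCmp) + 1]] <-
      data.frame(cut = sprintf("<=%g vs >%g", c0, c0),
                 aucFwe = dt$auc1, aucOriginal = dt$auc2,
                 delta = dt$delta, z = dt$z, p = dt$p)
  }
  list(reliability = list(voxel = voxel, dice = dice, icc = icc),
       summary = summary, prediction = prediction,
       aucComparison = do.call(rbind, aucCmp), scores = scoreTab)
}
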