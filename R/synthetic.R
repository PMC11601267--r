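# Synthetic phantoms and cohorts: bi-tensor voxels with Rician noise, lesion
# regions with elevated free water, and ordinal severity scores tied to
# lesion burden. Defaults emulate the reference acquisition: 26 b=0 volumes
# and shells at b = 500/1000/2500 s/mm^2 with 32/64/128 directions.

#' Acquisition specification
#' @param shells list of c(bvalue, nDirections) pairs
#' @param nB0 number of b=0 volumes, interleaved evenly
#' @return an \code{AcquisitionSpec} list
#' @export
acquisitionSpec <- function(shells = list(c(500, 32), c(1000, 64), c(2500, 128)),
                            nB0 = 26) {
  stopifnot(all(vapply(shells, function(s) s[2] > 0, logical(1))))
  structure(list(shells = shells, nB0 = as.integer(nB0),
                 directionScheme = "electrostatic-repulsion"),
            class = "AcquisitionSpec")
}

#' Build a gradient table from an acquisition specification
#'
#' Per-shell direction sets come from electrostatic repulsion (deterministic
#' given the seed); b=0 volumes are interleaved evenly among the weighted
#' volumes, mirroring scanner practice.
#'
#' @param spec an \code{\link{acquisitionSpec}}
#' @param seed integer seed for the repulsion initialization
#' @return a \linkS4class{GradientTable}
#' @export
makeGradientTable <- function(spec, seed = 42L) {
  bv <- numeric(0); dirs <- NULL
  for (k in seq_along(spec$shells)) {
    s <- spec$shells[[k]]
    d <- repulsionDirections(s[2], seed = seed + k)
    bv <- c(bv, rep(s[1], s[2]))
    dirs <- rbind(dirs, d)
  }
  nw <- length(bv)
  n <- nw + spec$nB0
  b0Slots <- unique(round(seq(1, n, length.out = spec$nB0)))
  # rounding can collide for extreme specs; fall back to first free slots
  while (length(b0Slots) < spec$nB0)
    b0Slots <- union(b0Slots, setdiff(seq_len(n), b0Slots)[1])
  bvals <- numeric(n); bvecs <- matrix(0, 3, n)
  w <- setdiff(seq_len(n), sort(b0Slots))
  bvals[w] <- bv
  bvecs[, w] <- t(dirs)
  gradientTable(bvals, bvecs)
}

#' Bi-tensor mixture signal with optional Rician noise
#'
#' Noise-free voxel signal:
#' \deqn{S(\theta,b) = \sum_i w_i S_0 (1-f) e^{-b \theta' Q_i \theta}
#'       + S_0 f e^{-b D_{iso}}}
#' with \eqn{D_{iso} = 3 \times 10^{-3}} mm^2/s. Rician noise draws two
#' Gaussian channels of standard deviation \eqn{\sigma = S_0 / SNR} and takes
#' the magnitude.
#'
#' @param tensors list of \code{list(tensor = 3x3 or 6-vector, fraction)};
#'   fractions must sum to 1
#' @param f free-water fraction in [0, 1]
#' @param s0 non-weighted signal
#' @param gtab a \linkS4class{GradientTable}
#' @param snr signal-to-noise ratio at b=0 (\code{Inf} for noise-free)
#' @param seed integer seed used when \code{snr} is finite
#' @param dIso isotropic diffusivity (mm^2/s)
#' @return numeric vector of per-volume signals
#' @export
simulateMixtureSignal <- function(tensors, f, s0, gtab, snr = Inf, seed = 1L,
                                  dIso = D_ISO_DEFAULT) {
  stopifnot(f >= 0, f <= 1)
  fr <- vapply(tensors, function(t) t$fraction, numeric(1))
  stopifnot(abs(sum(fr) - 1) < 1e-8)
  b <- gtab@bvals
  X <- tensorDesign(gtab@bvecs)      # n x 6
  tissue <- 0
  for (tt in tensors) {
    q <- if (is.matrix(tt$tensor)) tensorMatToVec(tt$tensor) else tt$tensor
    if (min(eigen(tensorVecToMat(q), symmetric = TRUE, only.values = TRUE)$values) < 0)
      stop("tensor is not positive semi-definite")
    tissue <- tissue + tt$fraction * exp(-b * drop(X %*% q))
  }
  s <- s0 * (1 - f) * tissue + s0 * f * exp(-b * dIso)
  if (is.finite(snr)) {
    sigma <- s0 / snr
    s <- withSeed(seed, sqrt((s + rnorm(length(s), 0, sigma))^2 +
                             rnorm(length(s), 0, sigma)^2))
  }
  s
}

#' Phantom specification
#'
#' Bundles are cylinders around straight centerlines (voxel-grid mm
#' coordinates); lesion ROIs are boxes with an elevated free-water fraction;
#' the ventricle region is pure free water. Geometry uses 1-based voxel
#' coordinates scaled by \code{voxelSize}.
#'
#' @param gridShape 3D voxel counts
#' @param voxelSize isotropic voxel size in mm (default 1.8)
#' @param bundles list of \code{list(start, end, radius, evals)} with
#'   \code{start}/\code{end} in voxel units, \code{radius} in mm and
#'   \code{evals} tensor eigenvalues in mm^2/s
#' @param fwBackground baseline free-water fraction inside white matter
#' @param lesions list of \code{list(min, max, f)} voxel-coordinate boxes
#' @param ventricle optional \code{list(min, max)} voxel box of pure free water
#' @param snr Rician SNR at b=0 (default 30); \code{Inf} for noise-free
#' @param s0 non-weighted signal level
#' @param seed integer seed
#' @return a \code{PhantomSpec} list
#' @export
phantomSpec <- function(gridShape = c(14, 12, 7), voxelSize = 1.8,
                        bundles = list(defaultBundle(gridShape)),
                        fwBackground = 0.05, lesions = list(),
                        ventricle = NULL, snr = 30, s0 = 100, seed = 1L) {
  for (le in lesions) stopifnot(le$f >= 0, le$f <= 1)
  stopifnot(fwBackground >= 0, fwBackground <= 1, snr > 0)
  structure(list(gridShape = as.integer(gridShape), voxelSize = voxelSize,
                 bundles = bundles, fwBackground = fwBackground,
                 lesions = lesions, ventricle = ventricle,
                 snr = snr, s0 = s0, seed = as.integer(seed)),
            class = "PhantomSpec")
}

#' Default straight bundle along x through the grid middle
#' @param gridShape 3D voxel counts
#' @param radius cylinder radius in mm
#' @param evals tensor eigenvalues in mm^2/s
#' @return bundle description list
#' @export
defaultBundle <- function(gridShape, radius = 2.4,
                          evals = c(1.7, 0.2, 0.2) * 1e-3) {
  mid <- (gridShape + 1) / 2
  list(start = c(1, mid[2], mid[3]), end = c(gridShape[1], mid[2], mid[3]),
       radius = radius, evals = evals)
}

## point-to-segment distance and tangent, all in mm
.segmentGeometry <- function(points, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- pmin(pmax((sweep(points, 2, a) %*% ab) / len2, 0), 1)
  proj <- outer(drop(t), ab) + matrix(a, nrow(points), 3, byrow = TRUE)
  list(dist = sqrt(rowSums((points - proj)^2)), tangent = ab / sqrt(len2))
}

#' Build a diffusion phantom and its ground truth
#'
#' Bundle voxels receive prolate tensors oriented along the centerline
#' tangent; crossing voxels carry an equal-fraction two-tensor mixture;
#' lesion voxels get an elevated free-water fraction; voxels outside any
#' bundle (and the ventricle box) are pure free water. Deterministic given
#' the spec's seed.
#'
#' @param spec a \code{\link{phantomSpec}}
#' @param gtab a \linkS4class{GradientTable}
#' @return list with \code{dwi} (a \linkS4class{DWIVolume}) and \code{truth}
#'   (f map, per-voxel orientations, bundle/WMH/ventricle/NAWM masks)
#' @export
buildPhantom <- function(spec, gtab) {
  d <- spec$gridShape
  nvox <- prod(d)
  coordVox <- arrayInd(seq_len(nvox), d)
  coordMm <- coordVox * spec$voxelSize
  affine <- diag(c(rep(spec$voxelSize, 3), 1))
  affine[1:3, 4] <- spec$voxelSize  # voxel (1,1,1) centre at voxelSize mm

  nb <- length(spec$bundles)
  member <- matrix(FALSE, nvox, nb)
  tangents <- vector("list", nb)
  for (k in seq_len(nb)) {
    bu <- spec$bundles[[k]]
    if (any(bu$start < 1) || any(bu$end > d) || any(bu$end < 1) || any(bu$start > d))
      stop("bundle centerline outside the grid")
    g <- .segmentGeometry(coordMm, bu$start * spec$voxelSize,
                          bu$end * spec$voxelSize)
    member[, k] <- g$dist <= bu$radius
    tangents[[k]] <- g$tangent
  }
  wm <- rowSums(member) > 0

  boxMask <- function(box) {
    m <- rep(TRUE, nvox)
    for (ax in 1:3)
      m <- m & coordVox[, ax] >= box$min[ax] & coordVox[, ax] <= box$max[ax]
    m
  }
  vent <- if (is.null(spec$ventricle)) rep(FALSE, nvox) else boxMask(spec$ventricle)
  wm <- wm & !vent

  fMap <- rep(1, nvox)               # background / ventricle: pure free water
  fMap[wm] <- spec$fwBackground
  wmh <- rep(FALSE, nvox)
  for (le in spec$lesions) {
    inLesion <- boxMask(le) & wm
    fMap[inLesion] <- le$f
    wmh <- wmh | inLesion
  }

  ## tissue attenuation per bundle (tensor constant within a bundle)
  b <- gtab@bvals
  X <- tensorDesign(gtab@bvecs)
  atten <- matrix(0, nb, length(b))
  for (k in seq_len(nb)) {
    bu <- spec$bundles[[k]]
    t1 <- tangents[[k]]
    # orthonormal frame around the tangent
    ref <- if (abs(t1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    t2 <- ref - sum(ref * t1) * t1; t2 <- t2 / sqrt(sum(t2^2))
    t3 <- c(t1[2] * t2[3] - t1[3] * t2[2], t1[3] * t2[1] - t1[1] * t2[3],
            t1[1] * t2[2] - t1[2] * t2[1])
    Q <- cbind(t1, t2, t3) %*% diag(bu$evals) %*% t(cbind(t1, t2, t3))
    atten[k, ] <- exp(-b * drop(X %*% tensorMatToVec(Q)))
  }
  attenWater <- exp(-b * D_ISO_DEFAULT)

  sig <- matrix(0, nvox, length(b))
  tissueMix <- matrix(0, nvox, length(b))
  inAny <- which(wm)
  if (length(inAny)) {
    w <- member[inAny, , drop = FALSE] * 1
    w <- w / rowSums(w)
    tissueMix[inAny, ] <- w %*% atten
  }
  sig <- spec$s0 * ((1 - fMap) * tissueMix +
                    outer(fMap, attenWater))
  if (is.finite(spec$snr)) {
    sigma <- spec$s0 / spec$snr
    sig <- withSeed(spec$seed,
      sqrt((sig + rnorm(length(sig), 0, sigma))^2 +
           matrix(rnorm(length(sig), 0, sigma), nvox)^2))
  }

  asVol <- function(v) array(v, d)
  orient <- array(NA_real_, c(d, 3))
  primary <- apply(member, 1, function(m) if (any(m)) which(m)[1] else NA_integer_)
  for (k in seq_len(nb)) {
    sel <- which(primary == k)
    for (ax in 1:3) orient[cbind(coordVox[sel, , drop = FALSE], ax)] <- tangents[[k]][ax]
  }

  dwi <- new("DWIVolume",
             signal = array(sig, c(d, length(b))), affine = affine,
             gtab = gtab, brainMask = asVol(rep(TRUE, nvox)),
             wmMask = asVol(wm))
  truth <- list(fMap = asVol(fMap), orientation = orient,
                bundleMembership = array(member, c(d, nb)),
                tangents = tangents,
                wmMask = asVol(wm), wmhMask = asVol(wmh),
                ventricleMask = asVol(vent), nawmMask = asVol(wm & !wmh),
                affine = affine, spec = spec)
  list(dwi = dwi, truth = truth)
}

#' Simulate a cohort of tract profiles with ordinal severity scores
#'
#' Each subject receives an ordinal score drawn from \code{scoreRange}; the
#' subject's profile is a smooth tract-shaped mean curve depressed in its
#' middle section proportionally to the score (scaled by \code{effectSize}
#' in units of the node noise SD) plus spatially correlated noise.
#' \code{effectSize = 0} gives a null cohort whose profiles are independent
#' of the score.
#'
#' @param nSubjects number of subjects (>= 10)
#' @param scoreRange integer vector of possible ordinal scores (default 2:6)
#' @param effectSize depression of the profile per score step, in node-noise
#'   SD units
#' @param seed integer seed
#' @param tracts character vector of tract names to simulate
#' @param metrics character vector of metric names
#' @param nNodes profile length (default 100)
#' @return list with \code{profiles} (long data.frame: subject, tract,
#'   metric, node, value) and \code{scores} (data.frame: subject, score)
#' @export
simulateCohort <- function(nSubjects, scoreRange = 2:6, effectSize = 1,
                           seed = 1L, tracts = "ATR_R", metrics = "dti_fa",
                           nNodes = 100L) {
  stopifnot(nSubjects >= 10)
  noiseSd <- 0.02
  node <- seq_len(nNodes)
  base <- 0.55 + 0.08 * sin(2 * pi * node / nNodes) -
    0.05 * cos(4 * pi * node / nNodes)
  bump <- exp(-((node - nNodes / 2)^2) / (2 * (nNodes / 8)^2))
  withSeed(seed, {
    scores <- sample(rep(scoreRange, length.out = nSubjects))
    rows <- vector("list", nSubjects * length(tracts) * length(metrics))
    i <- 0L
    for (s in seq_len(nSubjects)) {
      sev <- (scores[s] - min(scoreRange))
      for (tr in tracts) for (me in metrics) {
        ## smooth, long-range-correlated node noise (correlation length
        ## ~nNodes/8), as real tract profiles vary smoothly along the tract
        white <- rnorm(nNodes)
        kern <- exp(-((-30:30)^2) / (2 * (nNodes / 8)^2))
        eps <- as.numeric(stats::filter(c(rev(white[1:30]), white,
                                          rev(white[(nNodes - 29):nNodes])),
                                        kern / sum(kern), sides = 2))
        eps <- eps[31:(nNodes + 30)]
        eps <- eps / sd(eps) * noiseSd
        val <- base - effectSize * noiseSd * sev * bump + eps
        i <- i + 1L
        rows[[i]] <- data.frame(subject = sprintf("sub-%03d", s), tract = tr,
                                metric = me, node = node, value = val)
      }
    }
    list(profiles = do.call(rbind, rows),
         scores = data.frame(subject = sprintf("sub-%03d", seq_len(nSubjects)),
                             score = scores))
  })
}
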