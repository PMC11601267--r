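# Probabilistic streamline tractography on discretized fODFs.

#' Probabilistic tractography seeded in the white matter
#'
#' Seeds \code{seedsPerVoxel} jittered start points in every white-matter
#' voxel and propagates bidirectionally: at each step the next direction is
#' drawn from the voxel's non-negative fODF amplitudes restricted to a cone
#' of \code{maxAngleDeg} around the previous direction. A streamline
#' terminates when it leaves the volume, enters a voxel where
#' \code{stopMap < stopThreshold}, or no positive amplitude remains in the
#' cone. Deterministic given \code{seed}.
#'
#' @param sh an \linkS4class{SHField} (discretized internally) or a
#'   \linkS4class{DiscretizedODFField}
#' @param wmMask 3D logical seed mask
#' @param affine 4x4 voxel-to-world transform
#' @param seedsPerVoxel seeds per mask voxel (default 8)
#' @param stepMm step length in mm (default 0.9)
#' @param maxAngleDeg maximum turning angle per step (default 30)
#' @param stopMap 3D scalar stopping map (e.g. an FA map)
#' @param stopThreshold termination threshold on \code{stopMap} (default 0.2)
#' @param seed integer RNG seed
#' @param maxSteps per-direction step cap
#' @param minPoints minimum points for a streamline to be kept (default 3)
#' @param pmfThreshold amplitudes below this fraction of the voxel's maximum
#'   are never sampled (default 0.1)
#' @return list of n x 3 world-mm point matrices
#' @export
trackProbabilistic <- function(sh, wmMask, affine, seedsPerVoxel = 8L,
                               stepMm = 0.9, maxAngleDeg = 30, stopMap,
                               stopThreshold = 0.2, seed = 1L,
                               maxSteps = 200L, minPoints = 3L,
                               pmfThreshold = 0.1) {
  odf <- if (is(sh, "SHField")) discretizeFodf(sh) else sh
  if (!any(wmMask)) stop("empty white-matter seed mask")
  d3 <- dim(wmMask)
  V <- odf@vertices
  amp <- matrix(odf@amp, prod(d3), 362)
  amp[amp < 0] <- 0
  ## clip sub-threshold amplitudes so noise lobes are never sampled
  vmax <- apply(amp, 1, max)
  amp[amp < pmfThreshold * vmax] <- 0
  inFit <- array(FALSE, d3); inFit[odf@mask] <- TRUE

  cosMax <- cos(maxAngleDeg * pi / 180)
  inv <- solve(affine)
  toVoxel <- function(p) round(drop(inv %*% c(p, 1))[1:3] + 1)
  voxOk <- function(v) all(v >= 1) && all(v <= d3)
  linIdx <- function(v) v[1] + (v[2] - 1) * d3[1] + (v[3] - 1) * d3[1] * d3[2]

  seedVox <- which(wmMask)
  coord <- arrayInd(seedVox, d3)
  streamlines <- list()
  withSeed(seed, {
    for (sv in seq_along(seedVox)) {
      a0full <- amp[seedVox[sv], ]
      if (sum(a0full) <= 0) next
      for (rep in seq_len(seedsPerVoxel)) {
        jitter <- runif(3, -0.5, 0.5)
        pos0 <- drop(affine %*% c(coord[sv, ] - 1 + jitter, 1))[1:3]
        i0 <- sample.int(362, 1, prob = a0full)
        dir0 <- V[i0, ]
        halves <- lapply(c(1, -1), function(sgn) {
          pts <- matrix(NA_real_, maxSteps, 3)
          npt <- 0L
          pos <- pos0; dirc <- sgn * dir0
          for (st in seq_len(maxSteps)) {
            newPos <- pos + stepMm * dirc
            vox <- toVoxel(newPos)
            if (!voxOk(vox)) break
            li <- linIdx(vox)
            if (!inFit[li] || stopMap[li] < stopThreshold) break
            npt <- npt + 1L
            pts[npt, ] <- newPos
            pos <- newPos
            cosang <- drop(V %*% dirc)
            w <- amp[li, ] * (cosang >= cosMax)
            if (sum(w) <= 0) break
            dirc <- V[sample.int(362, 1, prob = w), ]
          }
          pts[seq_len(npt), , drop = FALSE]
        })
        slp <- rbind(halves[[2]][rev(seq_len(nrow(halves[[2]]))), , drop = FALSE],
                     matrix(pos0, 1, 3), halves[[1]])
        if (nrow(slp) >= minPoints)
          streamlines[[length(streamlines) + 1]] <- unname(slp)
      }
    }
  })
  streamlines
}
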