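# WMH segmentation/categorization and the split-half reliability statistics:
# fODF explained variance (and its percent increase), weighted Dice and
# ICC(2,1).

#' Threshold a WMH probability map
#'
#' Voxels with probability at or above \code{threshold} (inclusive; default
#' 0.5) become WMH.
#'
#' @param probMap 3D array with values in [0, 1]
#' @param threshold inclusion threshold
#' @return 3D logical mask
#' @export
segmentWmh <- function(probMap, threshold = 0.5) {
  if (min(probMap) < 0 || max(probMap) > 1)
    stop("probability map values must lie in [0, 1]")
  probMap >= threshold
}

#' Categorize WMH connected components as periventricular or deep
#'
#' Removes WMH voxels within \code{rimMm} of the ventricles (partial-volume
#' rim; the rim converts to voxels by ceiling against the voxel size), labels
#' the remaining WMH voxels into 26-connected components, and calls a
#' component periventricular iff it touches the rim-dilated ventricle
#' boundary, deep otherwise. NAWM is the white matter minus the WMH.
#'
#' @param wmh 3D logical WMH mask
#' @param ventricles 3D logical ventricle mask
#' @param wmMask 3D logical white-matter mask
#' @param rimMm rim width in mm (default 1)
#' @param voxelMm voxel size in mm (default 1.8)
#' @return a \linkS4class{WMHSegmentation}
#' @export
categorizeWmhRois <- function(wmh, ventricles, wmMask, rimMm = 1,
                              voxelMm = 1.8) {
  stopifnot(all(dim(wmh) == dim(ventricles)))
  rimVox <- max(1L, ceiling(rimMm / voxelMm))
  rimmed <- dilateMask26(ventricles, rimVox)          # ventricles + rim
  wmhClean <- wmh & !rimmed
  labels <- labelComponents26(wmhClean)
  k <- max(labels)
  touch <- dilateMask26(rimmed, 1L)                   # adjacency shell
  category <- character(k)
  for (i in seq_len(k))
    category[i] <- if (any(touch[labels == i])) "periventricular" else "deep"
  new("WMHSegmentation", wmh = wmhClean, labels = labels,
      category = category, nawm = wmMask & !wmhClean)
}

#' Per-voxel fODF split-half explained variance
#'
#' In each masked voxel, the squared Pearson correlation of the 362 paired
#' amplitudes of the two discretized fODF fields. Zero-variance voxels give
#' NaN.
#'
#' @param odfA,odfB \linkS4class{DiscretizedODFField}s on the same grid and
#'   sphere
#' @param mask 3D logical evaluation mask
#' @return 3D array of r-squared values (NaN where undefined)
#' @export
fodfReliabilityMap <- function(odfA, odfB, mask = NULL) {
  stopifnot(all(dim(odfA@amp) == dim(odfB@amp)))
  d3 <- dim(odfA@amp)[1:3]
  mask <- mask %||% (odfA@mask & odfB@mask)
  out <- array(NA_real_, d3)
  ma <- matrix(odfA@amp, prod(d3), 362)
  mb <- matrix(odfB@amp, prod(d3), 362)
  for (v in which(mask)) {
    if (sd(ma[v, ]) <= 0 || sd(mb[v, ]) <= 0) { out[v] <- NaN; next }
    out[v] <- cor(ma[v, ], mb[v, ])^2
  }
  out
}

#' Percent increase in reliability of the FWE condition over the original
#'
#' \code{(r2Fwe - r2Orig) / r2Orig * 100}. NaN when \code{r2Orig} is 0.
#'
#' @param r2Fwe,r2Orig explained-variance values
#' @return percent increase (vectorized)
#' @examples
#' percentIncrease(0.5, 0.4)  # 25
#' @export
percentIncrease <- function(r2Fwe, r2Orig) {
  ifelse(r2Orig == 0, NaN, (r2Fwe - r2Orig) / r2Orig * 100)
}

#' Weighted Dice coefficient of two density maps
#'
#' With visitation proportions \eqn{w_a, w_b},
#' \deqn{wDice = \frac{\sum_{v \in A \cap B} (w_a(v) + w_b(v))}
#'       {\sum_{v \in A} w_a(v) + \sum_{v \in B} w_b(v)}.}
#' Maps are normalized to visitation proportions if they are not already.
#'
#' @param tdmA,tdmB \linkS4class{TractDensityMap}s on the same grid
#' @return scalar in [0, 1]; NaN when both maps are empty
#' @export
weightedDice <- function(tdmA, tdmB) {
  a <- tdmA@counts; b <- tdmB@counts
  stopifnot(all(dim(a) == dim(b)))
  if (sum(a) == 0 && sum(b) == 0) return(NaN)
  if (!tdmA@normalized && sum(a) > 0) a <- a / sum(a)
  if (!tdmB@normalized && sum(b) > 0) b <- b / sum(b)
  inter <- a > 0 & b > 0
  (sum(a[inter]) + sum(b[inter])) / (sum(a) + sum(b))
}

#' ICC(2,1): two-way random effects, absolute agreement, single rater
#'
#' Standard mean-squares decomposition over an n x k ratings table (here
#' k = 2 split-halves; targets are e.g. the 100 nodes of a tract profile):
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + k (MS_C - MS_E)/n}.}
#'
#' @param ratings numeric matrix, targets x raters (no missing cells,
#'   >= 3 targets)
#' @return scalar ICC in [-1, 1]; NaN for zero total variance
#' @export
icc21 <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  stopifnot(n >= 3, k >= 2, !anyNA(ratings))
  grand <- mean(ratings)
  rowM <- rowMeans(ratings); colM <- colMeans(ratings)
  ssR <- k * sum((rowM - grand)^2)
  ssC <- n * sum((colM - grand)^2)
  ssT <- sum((ratings - grand)^2)
  ssE <- ssT - ssR - ssC
  msR <- ssR / (n - 1)
  msC <- ssC / (k - 1)
  msE <- ssE / ((n - 1) * (k - 1))
  den <- msR + (k - 1) * msE + k * (msC - msE) / n
  if (abs(den) < 1e-300) return(NaN)
  (msR - msE) / den
}
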