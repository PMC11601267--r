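# Gradient-table construction, shell detection and NIfTI / bvals / bvecs IO.

#' Construct a GradientTable
#'
#' Diffusion-weighted columns of \code{bvecs} are renormalized to unit length;
#' b=0 columns are zeroed. Shells are detected immediately (see
#' \code{\link{detectShells}}).
#'
#' @param bvals numeric vector of b-values (s/mm^2)
#' @param bvecs 3 x n matrix (or n x 3, auto-transposed) of directions
#' @param b0Threshold b-values at or below this count as b=0 (default 50)
#' @param tol shell clustering tolerance in s/mm^2 (default 100)
#' @return a \linkS4class{GradientTable}
#' @examples
#' gt <- gradientTable(c(0, 1000, 1000), cbind(0, c(1, 0, 0), c(0, 1, 0)))
#' shellIds(gt)
#' @export
gradientTable <- function(bvals, bvecs, b0Threshold = 50, tol = 100) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3 && ncol(bvecs) == 3) bvecs <- t(bvecs)
  stopifnot(nrow(bvecs) == 3, ncol(bvecs) == length(bvals))
  dw <- bvals > b0Threshold
  if (any(dw)) {
    nrm <- sqrt(colSums(bvecs[, dw, drop = FALSE]^2))
    if (any(nrm < 1e-12))
      stop("diffusion-weighted volume with zero direction vector")
    bvecs[, dw] <- sweep(bvecs[, dw, drop = FALSE], 2, nrm, `/`)
  }
  bvecs[, !dw] <- 0
  gt <- new("GradientTable", bvals = bvals, bvecs = bvecs,
            b0Threshold = b0Threshold,
            shellIds = integer(length(bvals)))
  detectShells(gt, tol = tol)
}

#' Assign shell labels by b-value clustering
#'
#' Volumes at or below the b=0 threshold form shell 0; remaining b-values are
#' single-linkage clustered with gap tolerance \code{tol} and labeled
#' 1..k by ascending nominal b-value. A cluster whose internal spread
#' exceeds \code{tol} means neighbouring shells overlap at this tolerance
#' and is an error.
#'
#' @param gtab a \linkS4class{GradientTable}
#' @param tol clustering tolerance in s/mm^2
#' @return the GradientTable with \code{shellIds} set
#' @export
detectShells <- function(gtab, tol = 100) {
  stopifnot(is(gtab, "GradientTable"), tol > 0, all(is.finite(gtab@bvals)))
  b <- gtab@bvals
  ids <- integer(length(b))
  dw <- which(b > gtab@b0Threshold)
  if (length(dw)) {
    ord <- dw[order(b[dw])]
    cluster <- cumsum(c(1, diff(b[ord]) > tol))
    for (k in unique(cluster)) {
      vals <- b[ord[cluster == k]]
      if (max(vals) - min(vals) > tol)
        stop(sprintf(
          "ambiguous shells: b-values %g..%g chain beyond tolerance %g",
          min(vals), max(vals), tol))
    }
    ids[ord] <- cluster
  }
  initialize(gtab, shellIds = as.integer(ids))
}

#' Nominal b-value of each detected shell
#' @param gtab a GradientTable
#' @return named numeric vector, names are shell ids
#' @export
shellTable <- function(gtab) {
  ids <- sort(unique(gtab@shellIds))
  setNames(vapply(ids, function(i) mean(gtab@bvals[gtab@shellIds == i]),
                  numeric(1)), ids)
}

## subset a GradientTable / DWIVolume by volume indices (original order kept)
subsetGtab <- function(gtab, idx) {
  idx <- sort(idx)
  new("GradientTable", bvals = gtab@bvals[idx],
      bvecs = gtab@bvecs[, idx, drop = FALSE],
      b0Threshold = gtab@b0Threshold, shellIds = gtab@shellIds[idx])
}

subsetVolumes <- function(dwi, idx) {
  idx <- sort(idx)
  new("DWIVolume", signal = dwi@signal[, , , idx, drop = FALSE],
      affine = dwi@affine, gtab = subsetGtab(dwi@gtab, idx),
      brainMask = dwi@brainMask, wmMask = dwi@wmMask)
}

## ---- file IO ---------------------------------------------------------------

#' Read FSL-style bvals/bvecs text files
#'
#' bvals is one whitespace-separated row; bvecs is three rows. Directions are
#' interpreted in the image coordinate frame (FSL dialect): when the affine's
#' rotation has positive determinant, the x component is flipped on load.
#'
#' @param bvalsPath,bvecsPath file paths
#' @param affine optional 4x4 voxel-to-world affine for the dialect flip
#' @param ... passed to \code{\link{gradientTable}}
#' @return a \linkS4class{GradientTable}
#' @export
readBvalsBvecs <- function(bvalsPath, bvecsPath, affine = NULL, ...) {
  bvals <- scan(bvalsPath, quiet = TRUE)
  bv <- as.matrix(read.table(bvecsPath))
  if (nrow(bv) != 3) bv <- t(bv)
  if (!is.null(affine) && det(affine[1:3, 1:3]) > 0) bv[1, ] <- -bv[1, ]
  gradientTable(bvals, bv, ...)
}

#' Write FSL-style bvals/bvecs text files
#' @param gtab a GradientTable
#' @param bvalsPath,bvecsPath output paths
#' @export
writeBvalsBvecs <- function(gtab, bvalsPath, bvecsPath) {
  writeLines(paste(format(gtab@bvals, trim = TRUE), collapse = " "), bvalsPath)
  writeLines(apply(gtab@bvecs, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvecsPath)
  invisible(NULL)
}

#' Read a 4D diffusion acquisition from NIfTI + bvals/bvecs
#' @param dwiPath 4D NIfTI path; \code{bvalsPath}, \code{bvecsPath} text files
#' @param brainMaskPath,wmMaskPath optional 3D NIfTI mask paths
#' @param ... passed to \code{\link{gradientTable}}
#' @return a \linkS4class{DWIVolume}
#' @export
readDwi <- function(dwiPath, bvalsPath, bvecsPath,
                    brainMaskPath = NULL, wmMaskPath = NULL, ...) {
  img <- RNifti::readNifti(dwiPath)
  affine <- structure(RNifti::xform(img), class = "matrix")
  affine <- matrix(as.numeric(affine), 4, 4)
  gtab <- readBvalsBvecs(bvalsPath, bvecsPath, affine = affine, ...)
  readMask <- function(p) {
    if (is.null(p)) return(NULL)
    array(as.array(RNifti::readNifti(p)) > 0.5, dim = dim(img)[1:3])
  }
  new("DWIVolume", signal = array(as.numeric(img), dim = dim(img)),
      affine = affine, gtab = gtab,
      brainMask = readMask(brainMaskPath), wmMask = readMask(wmMaskPath))
}

#' Write a DWIVolume as NIfTI + bvals/bvecs
#' @param dwi a DWIVolume
#' @param dwiPath output NIfTI path (.nii or .nii.gz)
#' @param bvalsPath,bvecsPath optional text output paths
#' @export
writeDwi <- function(dwi, dwiPath, bvalsPath = NULL, bvecsPath = NULL) {
  vox <- sqrt(colSums(dwi@affine[1:3, 1:3]^2))
  img <- RNifti::asNifti(dwi@signal, pixdim = vox)
  RNifti::writeNifti(img, dwiPath)
  if (!is.null(bvalsPath)) writeBvalsBvecs(dwi@gtab, bvalsPath, bvecsPath)
  invisible(dwiPath)
}

#' Write a 3D map as NIfTI
#' @param map 3D array; \code{affine} 4x4 transform; \code{path} output path
#' @export
writeMap <- function(map, affine, path) {
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::writeNifti(RNifti::asNifti(map * 1, pixdim = vox), path)
  invisible(path)
}
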