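# Central S4 data containers. Tensor fields use the 6-vector order
# (xx, yy, zz, xy, xz, yz); all diffusivities are in mm^2/s, b-values in
# s/mm^2 and spatial coordinates in world mm unless stated otherwise.

setClassUnion("arrayOrNULL", c("array", "NULL"))

#' GradientTable: per-volume diffusion weightings and directions
#'
#' Holds b-values (s/mm^2), unit gradient directions (3 x n, image frame,
#' FSL dialect), the b=0 threshold and integer shell labels (0 = b=0 shell).
#'
#' @slot bvals numeric vector of b-values
#' @slot bvecs 3 x n matrix of directions; columns for b <= b0Threshold may be zero
#' @slot b0Threshold scalar b-value below which a volume counts as b=0
#' @slot shellIds integer shell label per volume (0 for the b=0 shell)
#' @export
setClass("GradientTable",
  representation(bvals = "numeric", bvecs = "matrix",
                 b0Threshold = "numeric", shellIds = "integer"),
  validity = function(object) {
    n <- length(object@bvals)
    if (!all(is.finite(object@bvals))) return("bvals must be finite")
    if (ncol(object@bvecs) != n) return("bvals and bvecs lengths differ")
    if (nrow(object@bvecs) != 3) return("bvecs must be 3 x n")
    dw <- object@bvals > object@b0Threshold
    if (any(dw)) {
      nrm <- sqrt(colSums(object@bvecs[, dw, drop = FALSE]^2))
      if (any(abs(nrm - 1) > 1e-6))
        return("diffusion-weighted bvecs must have unit norm (1e-6)")
    }
    if (length(object@shellIds) != n) return("shellIds length mismatch")
    TRUE
  })

#' DWIVolume: a 4D diffusion acquisition on a voxel grid
#'
#' @slot signal 4D non-negative array (x, y, z, volume)
#' @slot affine 4 x 4 voxel-to-world (mm) transform
#' @slot gtab the \linkS4class{GradientTable}
#' @slot brainMask,wmMask optional 3D logical arrays on the same grid
#' @export
setClass("DWIVolume",
  representation(signal = "array", affine = "matrix", gtab = "GradientTable",
                 brainMask = "arrayOrNULL", wmMask = "arrayOrNULL"),
  validity = function(object) {
    d <- dim(object@signal)
    if (length(d) != 4) return("signal must be 4D")
    if (d[4] != length(object@gtab@bvals))
      return("4th signal dimension must equal gradient table length")
    if (!all(dim(object@affine) == c(4, 4))) return("affine must be 4 x 4")
    for (m in list(object@brainMask, object@wmMask))
      if (!is.null(m) && !all(dim(m) == d[1:3]))
        return("masks must share the 3D grid")
    TRUE
  })

#' SplitHalfPair: one acquisition split evenly per shell into two halves
#' @slot halfA,halfB the two \linkS4class{DWIVolume} halves
#' @slot indicesA,indicesB original volume indices carried by each half
#' @slot seed integer seed that produced the partition
#' @slot parentId identifier of the parent volume
#' @export
setClass("SplitHalfPair",
  representation(halfA = "DWIVolume", halfB = "DWIVolume",
                 indicesA = "integer", indicesB = "integer",
                 seed = "integer", parentId = "character"),
  validity = function(object) {
    if (length(intersect(object@indicesA, object@indicesB)) > 0)
      return("halves must be disjoint")
    TRUE
  })

#' FreeWaterFit: per-voxel bi-tensor free-water model parameters
#'
#' @slot s0 3D array of non-diffusion-weighted signal
#' @slot f 3D array of free-water fractions in [0, 1]
#' @slot q 4D array (x, y, z, 6) tissue tensor 6-vectors (mm^2/s)
#' @slot dIso fixed isotropic free-water diffusivity (mm^2/s)
#' @slot converged 3D logical; \code{nIter} 3D integer iteration counts
#' @slot mask 3D logical of fitted voxels
#' @export
setClass("FreeWaterFit",
  representation(s0 = "array", f = "array", q = "array", dIso = "numeric",
                 converged = "array", nIter = "array", mask = "array"),
  validity = function(object) {
    fin <- object@f[object@mask]
    if (length(fin) && (min(fin) < -1e-12 || max(fin) > 1 + 1e-12))
      return("f must lie in [0, 1] inside the mask")
    if (length(dim(object@q)) != 4 || dim(object@q)[4] != 6)
      return("q must be (x, y, z, 6)")
    TRUE
  })

#' DiffusionTensorFit: voxelwise single-tensor (DTI) fit
#' @slot s0 3D array; \code{d} 4D (x, y, z, 6) tensor field (mm^2/s);
#'   \code{mask} 3D logical
#' @export
setClass("DiffusionTensorFit",
  representation(s0 = "array", d = "array", mask = "array"))

#' KurtosisFit: voxelwise diffusional kurtosis (DKI) fit
#' @slot s0 3D array; \code{d} 4D (x, y, z, 6) diffusion tensor (mm^2/s);
#'   \code{w} 4D (x, y, z, 15) kurtosis tensor components (dimensionless);
#'   \code{mask} 3D logical
#' @export
setClass("KurtosisFit",
  representation(s0 = "array", d = "array", w = "array", mask = "array"))

#' ResponseFunction: prolate single-fiber response for deconvolution
#' @slot evals c(lambda_parallel, lambda_perpendicular) in mm^2/s
#' @slot s0 mean non-weighted signal of the response voxels
#' @export
setClass("ResponseFunction",
  representation(evals = "numeric", s0 = "numeric"),
  validity = function(object) {
    if (length(object@evals) != 2) return("evals must be length 2")
    if (any(object@evals <= 0)) return("eigenvalues must be positive")
    if (object@evals[1] < object@evals[2]) return("response must be prolate")
    TRUE
  })

#' SHField: per-voxel even-order real spherical-harmonic coefficients
#' @slot coef 4D array (x, y, z, ncoef); \code{lmax} even integer;
#'   \code{mask} 3D logical
#' @export
setClass("SHField",
  representation(coef = "array", lmax = "integer", mask = "array"),
  validity = function(object) {
    nc <- (object@lmax + 1) * (object@lmax + 2) / 2
    if (dim(object@coef)[4] != nc)
      return("coefficient count must be (lmax+1)(lmax+2)/2")
    TRUE
  })

#' DiscretizedODFField: fODF amplitudes on the frozen 362-vertex sphere
#' @slot amp 4D array (x, y, z, 362); \code{vertices} 362 x 3 unit vectors;
#'   \code{mask} 3D logical
#' @export
setClass("DiscretizedODFField",
  representation(amp = "array", vertices = "matrix", mask = "array"),
  validity = function(object) {
    if (nrow(object@vertices) != 362) return("sphere must have 362 vertices")
    if (dim(object@amp)[4] != 362) return("amplitude axis must be 362")
    TRUE
  })

#' TractDefinition: named tract with ordered inclusion and exclusion ROIs
#' @slot name,abbreviation tract vocabulary entries
#' @slot include ordered list of 3D logical ROI masks (>= 1)
#' @slot exclude list of 3D logical ROI masks
#' @export
setClass("TractDefinition",
  representation(name = "character", abbreviation = "character",
                 include = "list", exclude = "list"),
  validity = function(object) {
    if (length(object@include) < 1) return("at least one inclusion ROI required")
    TRUE
  })

#' Bundle: streamlines selected for one tract
#' @slot name tract name
#' @slot streamlines list of n x 3 world-mm point matrices
#' @slot removed number of streamlines dropped by cleaning
#' @slot threshold cleaning threshold used (SD units)
#' @export
setClass("Bundle",
  representation(name = "character", streamlines = "list",
                 removed = "integer", threshold = "numeric"))

#' TractDensityMap: per-voxel streamline visit counts
#' @slot counts 3D numeric array; \code{normalized} logical flag
#' @export
setClass("TractDensityMap",
  representation(counts = "array", normalized = "logical"))

#' TractProfile: a 100-node scalar profile along one tract
#' @slot tract,metric labels; \code{values} node means; \code{weights} summed
#'   node weights
#' @export
setClass("TractProfile",
  representation(tract = "character", metric = "character",
                 values = "numeric", weights = "numeric"),
  validity = function(object) {
    if (length(object@values) != length(object@weights))
      return("values and weights lengths differ")
    TRUE
  })

#' WMHSegmentation: labeled white-matter-hyperintensity ROIs
#' @slot wmh 3D logical WMH mask (rim voxels removed)
#' @slot labels 3D integer connected-component labels
#' @slot category per-component factor: "periventricular" or "deep"
#' @slot nawm 3D logical normal-appearing white matter mask
#' @export
setClass("WMHSegmentation",
  representation(wmh = "array", labels = "array", category = "character",
                 nawm = "array"))

#' ReliabilityReport: split-half reliability statistics for one study
#' @slot voxel data.frame of per-voxel/stratum fODF reliability rows
#' @slot dice data.frame of per-tract weighted Dice rows
#' @slot icc data.frame of per-tract/metric ICC rows
#' @slot summary data.frame of condition-difference summaries (with SEM)
#' @export
setClass("ReliabilityReport",
  representation(voxel = "data.frame", dice = "data.frame",
                 icc = "data.frame", summary = "data.frame"))

#' PredictionReport: cross-validated ordinal prediction results
#' @slot predictions data.frame (repeat, fold, subject, truth, predicted,
#'   one probability column per class)
#' @slot mae,r2 scalars; \code{roc} data.frame of per-cut ROC points;
#'   \code{auc} data.frame of per-cut AUCs
#' @export
setClass("PredictionReport",
  representation(predictions = "data.frame", mae = "numeric", r2 = "numeric",
                 roc = "data.frame", auc = "data.frame"))
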