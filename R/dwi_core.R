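# Acquisition-level operations: single-shell subsampling, split-half
# construction and the neighboring-DWI-correlation quality metric.

#' Subsample a multi-shell acquisition to a single shell
#'
#' Keeps all b=0 volumes plus the volumes of the shell whose nominal b-value
#' matches \code{keepB}, preserving the original volume ordering.
#'
#' @param dwi a \linkS4class{DWIVolume}
#' @param keepB nominal b-value of the shell to keep (s/mm^2)
#' @param tol matching tolerance against nominal shell b-values
#' @return a \linkS4class{DWIVolume}
#' @export
subsampleSingleShell <- function(dwi, keepB, tol = 100) {
  nominal <- shellTable(dwi@gtab)
  weighted <- nominal[names(nominal) != "0"]
  hit <- which(abs(weighted - keepB) <= tol)
  if (length(hit) != 1)
    stop(sprintf("no shell matches b = %g; available shells: %s",
                 keepB, paste(round(weighted), collapse = ", ")))
  keepId <- as.integer(names(weighted)[hit])
  idx <- which(dwi@gtab@shellIds %in% c(0L, keepId))
  subsetVolumes(dwi, idx)
}

#' Split an acquisition randomly and evenly at each b-value
#'
#' Per shell, volumes are randomly partitioned into two near-equal halves
#' (an odd shell gives its extra volume to half A). The partition is
#' deterministic for a given seed; each half keeps the original volume
#' ordering and carries a consistent gradient table.
#'
#' @param dwi a \linkS4class{DWIVolume}; every shell must have >= 2 volumes
#' @param seed integer seed
#' @param parentId identifier stored on the pair
#' @return a \linkS4class{SplitHalfPair}
#' @export
splitHalf <- function(dwi, seed, parentId = "dwi") {
  ids <- dwi@gtab@shellIds
  counts <- table(ids)
  if (any(counts < 2))
    stop("cannot split: shell(s) with a single volume: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  idxA <- integer(0)
  withSeed(seed, {
    for (s in sort(unique(ids))) {
      vols <- which(ids == s)
      perm <- sample(vols)
      idxA <- c(idxA, perm[seq_len(ceiling(length(vols) / 2))])
    }
  })
  idxA <- sort(idxA)
  idxB <- setdiff(seq_along(ids), idxA)
  new("SplitHalfPair",
      halfA = subsetVolumes(dwi, idxA), halfB = subsetVolumes(dwi, idxB),
      indicesA = as.integer(idxA), indicesB = as.integer(idxB),
      seed = as.integer(seed), parentId = parentId)
}

#' Neighboring DWI correlation (NDC) data-quality metric
#'
#' For every diffusion-weighted volume, finds its nearest q-space neighbour
#' by angular distance between gradient directions after antipodal folding
#' (ties broken by smallest b-value difference, then volume index; b=0
#' volumes are excluded), and averages the Pearson correlation of in-mask
#' signals over volumes.
#'
#' @param dwi a \linkS4class{DWIVolume} with a brain mask
#' @return scalar NDC in [-1, 1]
#' @export
neighboringDwiCorrelation <- function(dwi) {
  if (is.null(dwi@brainMask)) stop("NDC requires a brain mask")
  maskIdx <- which(dwi@brainMask)
  if (length(maskIdx) == 0) stop("empty brain mask")
  dw <- which(dwi@gtab@shellIds > 0)
  if (length(dw) < 2) stop("NDC requires >= 2 diffusion-weighted volumes")
  dirs <- t(dwi@gtab@bvecs[, dw, drop = FALSE])
  b <- dwi@gtab@bvals[dw]
  cosang <- abs(dirs %*% t(dirs))
  sig <- matrix(dwi@signal, prod(dim(dwi@signal)[1:3]),
                dim(dwi@signal)[4])[maskIdx, dw, drop = FALSE]
  cors <- vapply(seq_along(dw), function(i) {
    ang <- -cosang[i, ]          # most-parallel first
    ang[i] <- Inf
    ord <- order(ang, abs(b - b[i]), seq_along(dw))
    j <- ord[1]
    suppressWarnings(cor(sig[, i], sig[, j]))
  }, numeric(1))
  mean(cors, na.rm = TRUE)
}

#' Flag subjects whose NDC falls below the sample mean minus k SDs
#'
#' @param ndcValues per-subject NDC scalars (>= 2 subjects)
#' @param kSd exclusion threshold in sample standard deviations (default 2)
#' @return logical keep-flags, FALSE for excluded subjects
#' @examples
#' excludeByNdc(c(0.9, 0.9, 0.9, 0.3))
#' @export
excludeByNdc <- function(ndcValues, kSd = 2) {
  stopifnot(length(ndcValues) >= 2, kSd > 0)
  ndcValues >= mean(ndcValues) - kSd * sd(ndcValues)
}
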