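# Bundle selection, cleaning, resampling, density maps and tract profiles.

#' The 28-tract controlled vocabulary
#' @return data.frame with columns \code{abbreviation} and \code{name}
#' @export
tractTable <- function() {
  read.table(system.file("extdata", "tracts.tsv", package = "fwetract"),
             sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

## ordered voxel indices visited by a streamline (supersampled to half-voxel)
.streamlineVoxels <- function(s, affine, d3) {
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  s <- .superSample(s, min(vox) / 2)
  cc <- round(worldToVoxel(s, affine))
  ok <- cc[, 1] >= 1 & cc[, 2] >= 1 & cc[, 3] >= 1 &
        cc[, 1] <= d3[1] & cc[, 2] <= d3[2] & cc[, 3] <= d3[3]
  cc <- cc[ok, , drop = FALSE]
  if (!nrow(cc)) return(integer(0))
  li <- voxelLinearIndex(cc, d3)
  li[c(TRUE, diff(li) != 0)]
}

.superSample <- function(s, maxSpacing) {
  if (nrow(s) < 2) return(s)
  seg <- sqrt(rowSums(diff(s)^2))
  if (all(seg <= maxSpacing)) return(s)
  out <- list(s[1, , drop = FALSE])
  for (i in seq_along(seg)) {
    k <- ceiling(seg[i] / maxSpacing)
    t <- seq_len(k) / k
    out[[length(out) + 1]] <-
      (1 - t) %o% s[i, ] + t %o% s[i + 1, ]
  }
  do.call(rbind, out)
}

#' Select streamlines for a tract by inclusion/exclusion ROI logic
#'
#' A streamline is kept iff it intersects every inclusion ROI in order along
#' its arc (streamlines are orientation-normalized: a streamline traversing
#' the ROIs in reverse order is flipped) and intersects no exclusion ROI.
#'
#' @param streamlines list of n x 3 world-mm matrices
#' @param tract a \linkS4class{TractDefinition}
#' @param affine 4x4 voxel-to-world transform of the ROI grid
#' @return a \linkS4class{Bundle}
#' @export
selectBundle <- function(streamlines, tract, affine) {
  d3 <- dim(tract@include[[1]])
  incIdx <- lapply(tract@include, which)
  excIdx <- if (length(tract@exclude)) unique(unlist(lapply(tract@exclude, which)))
            else integer(0)
  kept <- list()
  for (s in streamlines) {
    li <- .streamlineVoxels(s, affine, d3)
    if (length(excIdx) && any(li %in% excIdx)) next
    pos <- vapply(incIdx, function(r) {
      hit <- which(li %in% r)
      if (length(hit)) median(hit) else NA_real_
    }, numeric(1))
    if (anyNA(pos)) next
    if (is.unsorted(pos, strictly = FALSE)) {
      if (is.unsorted(rev(pos), strictly = FALSE)) next  # out of order both ways
      s <- s[rev(seq_len(nrow(s))), , drop = FALSE]
    }
    kept[[length(kept) + 1]] <- s
  }
  new("Bundle", name = tract@name, streamlines = kept,
      removed = 0L, threshold = NA_real_)
}

#' Resample a streamline to equidistant arc-length nodes
#' @param s n x 3 point matrix
#' @param nNodes target node count (>= 2); endpoints are preserved
#' @return nNodes x 3 matrix
#' @export
resampleStreamline <- function(s, nNodes = 100L) {
  stopifnot(nNodes >= 2)
  seg <- sqrt(rowSums(diff(s)^2))
  arc <- c(0, cumsum(seg))
  if (arc[length(arc)] <= 0) stop("zero-length streamline cannot be resampled")
  at <- seq(0, arc[length(arc)], length.out = nNodes)
  cbind(approx(arc, s[, 1], at, ties = "ordered")$y,
        approx(arc, s[, 2], at, ties = "ordered")$y,
        approx(arc, s[, 3], at, ties = "ordered")$y)
}

#' Remove streamlines deviating from the median bundle trajectory
#'
#' Resamples every streamline to \code{nNodes}, computes each streamline's
#' mean distance to the node-wise median trajectory, and iteratively removes
#' streamlines whose distance z-score exceeds \code{sdThreshold} (default 5)
#' until none is removed. The z-score uses the leave-one-out mean and SD of
#' the remaining streamlines' distances, so a single extreme outlier is
#' detectable in small bundles (an including z-score is bounded by
#' \code{(n-1)/sqrt(n)} and could never reach 5 below n = 27). A
#' zero-variance bundle removes nothing; a bundle that would shrink below 3
#' streamlines is returned as-is with a warning.
#'
#' @param bundle a \linkS4class{Bundle}
#' @param sdThreshold removal threshold in SD units
#' @param nNodes resampling resolution (default 100)
#' @return cleaned \linkS4class{Bundle} (streamlines resampled to nNodes)
#' @export
cleanBundle <- function(bundle, sdThreshold = 5, nNodes = 100L) {
  sls <- bundle@streamlines
  if (length(sls) < 3) {
    warning("bundle has fewer than 3 streamlines; returning unchanged")
    return(bundle)
  }
  rs <- lapply(sls, resampleStreamline, nNodes = nNodes)
  removed <- 0L
  repeat {
    arr <- simplify2array(rs)                         # nNodes x 3 x nstream
    med <- apply(arr, c(1, 2), median)
    dist <- vapply(seq_along(rs), function(i)
      mean(sqrt(rowSums((arr[, , i] - med)^2))), numeric(1))
    n <- length(dist)
    looMean <- (sum(dist) - dist) / (n - 1)
    looSd <- vapply(seq_len(n), function(i) sd(dist[-i]), numeric(1))
    z <- ifelse(looSd > 1e-12, (dist - looMean) / looSd, 0)
    drop <- which(z > sdThreshold)
    if (!length(drop)) break
    if (length(rs) - length(drop) < 3) {
      warning("cleaning would shrink bundle below 3 streamlines; stopping")
      break
    }
    rs <- rs[-drop]
    removed <- removed + length(drop)
  }
  new("Bundle", name = bundle@name, streamlines = rs,
      removed = removed, threshold = sdThreshold)
}

#' Streamline visitation density map
#'
#' Counts, per voxel, the number of streamlines that pass through it (each
#' streamline increments a voxel at most once). With \code{normalize = TRUE}
#' counts become visitation proportions summing to 1 over nonzero voxels.
#'
#' @param bundle a \linkS4class{Bundle}
#' @param d3 3D grid dimensions
#' @param affine 4x4 voxel-to-world transform
#' @param normalize return visitation proportions (default FALSE)
#' @return a \linkS4class{TractDensityMap}
#' @export
tractDensityMap <- function(bundle, d3, affine, normalize = FALSE) {
  counts <- array(0, d3)
  for (s in bundle@streamlines) {
    li <- unique(.streamlineVoxels(s, affine, d3))
    counts[li] <- counts[li] + 1
  }
  if (normalize && sum(counts) > 0) counts <- counts / sum(counts)
  new("TractDensityMap", counts = counts, normalized = normalize)
}

#' Tract profile of a scalar map along a bundle
#'
#' Each streamline is resampled to \code{nNodes} and orientation-normalized
#' against the bundle's first streamline. The node-k value is the weighted
#' mean over streamlines of the scalar sampled at each streamline's node-k
#' point, with weight 1/(d + 0.1 mm) where d is the point's distance from
#' the node-k median position.
#'
#' @param bundle a \linkS4class{Bundle}
#' @param scalarMap 3D array on the tracking grid
#' @param affine 4x4 voxel-to-world transform
#' @param nNodes profile length (default 100)
#' @param tract,metric labels stored on the profile
#' @return a \linkS4class{TractProfile}
#' @export
computeTractProfile <- function(bundle, scalarMap, affine, nNodes = 100L,
                                tract = bundle@name, metric = "scalar") {
  if (!length(bundle@streamlines)) {
    warning("empty bundle; returning all-NaN profile")
    return(new("TractProfile", tract = tract, metric = metric,
               values = rep(NaN, nNodes), weights = rep(0, nNodes)))
  }
  d3 <- dim(scalarMap)
  rs <- lapply(bundle@streamlines, function(s)
    if (nrow(s) == nNodes) s else resampleStreamline(s, nNodes = nNodes))
  ref <- rs[[1]]
  n <- nNodes
  for (i in seq_along(rs)[-1]) {
    fwd <- sum((rs[[i]][1, ] - ref[1, ])^2) + sum((rs[[i]][n, ] - ref[n, ])^2)
    rev_ <- sum((rs[[i]][1, ] - ref[n, ])^2) + sum((rs[[i]][n, ] - ref[1, ])^2)
    if (rev_ < fwd) rs[[i]] <- rs[[i]][n:1, , drop = FALSE]
  }
  arr <- simplify2array(rs)                            # n x 3 x nstream
  med <- apply(arr, c(1, 2), median)
  values <- numeric(n); wsum <- numeric(n)
  for (k in seq_len(n)) {
    pts <- t(arr[k, , ])                               # nstream x 3
    cc <- round(worldToVoxel(pts, affine))
    ok <- cc[, 1] >= 1 & cc[, 2] >= 1 & cc[, 3] >= 1 &
          cc[, 1] <= d3[1] & cc[, 2] <= d3[2] & cc[, 3] <= d3[3]
    if (!any(ok)) { values[k] <- NaN; next }
    vals <- scalarMap[voxelLinearIndex(cc[ok, , drop = FALSE], d3)]
    dmm <- sqrt(rowSums(sweep(pts[ok, , drop = FALSE], 2, med[k, ])^2))
    w <- 1 / (dmm + 0.1)
    values[k] <- sum(w * vals) / sum(w)
    wsum[k] <- sum(w)
  }
  new("TractProfile", tract = tract, metric = metric,
      values = values, weights = wsum)
}

## ---- streamline file IO (MRtrix .tck) --------------------------------------

#' Write streamlines to an MRtrix .tck file
#' @param streamlines list of n x 3 world-mm matrices
#' @param path output path
#' @export
writeTck <- function(streamlines, path) {
  hdr <- c("mrtrix tracks", "datatype: Float32LE",
           sprintf("count: %d", length(streamlines)))
  offset <- sum(nchar(hdr)) + length(hdr) + nchar("file: . ") + 16 + nchar("END") + 1
  hdr <- c(hdr, sprintf("file: . %d", offset))
  txt <- paste0(paste(c(hdr, "END"), collapse = "\n"), "\n")
  # recompute offset with the actual header text (fixed-width file field)
  off <- nchar(txt)
  hdr[length(hdr)] <- sprintf("file: . %d", off)
  txt2 <- paste0(paste(c(hdr, "END"), collapse = "\n"), "\n")
  while (nchar(txt2) != off) {
    off <- nchar(txt2)
    hdr[length(hdr)] <- sprintf("file: . %d", off)
    txt2 <- paste0(paste(c(hdr, "END"), collapse = "\n"), "\n")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(txt2, con, eos = NULL)
  for (s in streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

#' Read streamlines from an MRtrix .tck file
#' @param path .tck path
#' @return list of n x 3 matrices
#' @export
readTck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character(0)
  repeat {
    ch <- character(0)
    repeat {
      b <- readBin(con, "raw", 1)
      if (rawToChar(b) == "\n") break
      ch <- c(ch, rawToChar(b))
    }
    line <- paste(ch, collapse = "")
    if (line == "END") break
    lines <- c(lines, line)
  }
  off <- as.integer(sub("file: \\. ", "", grep("^file:", lines, value = TRUE)))
  seek(con, off)
  vals <- readBin(con, "numeric", n = 3e7, size = 4, endian = "little")
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  breaks <- which(apply(m, 1, function(r) any(is.nan(r) | is.infinite(r))))
  out <- list(); start <- 1
  for (b in breaks) {
    if (b > start) out[[length(out) + 1]] <- m[start:(b - 1), , drop = FALSE]
    start <- b + 1
  }
  out
}
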