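# Internal helpers: seeded RNG, 3D morphology, tensor bookkeeping.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded package internals do
#' not perturb user-level reproducibility.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of \code{expr}
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- tensor bookkeeping ----------------------------------------------------
## 6-vector order: xx, yy, zz, xy, xz, yz

tensorVecToMat <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}

tensorMatToVec <- function(m) {
  c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
}

## design rows for the quadratic form g' D g on tensor 6-vectors
tensorDesign <- function(bvecs) {
  g <- t(bvecs)  # n x 3
  cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
        2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
}

## eigen-clamp a tensor 6-vector to [lo, hi]
clampTensorVec <- function(v, lo, hi) {
  e <- eigen(tensorVecToMat(v), symmetric = TRUE)
  vals <- pmin(pmax(e$values, lo), hi)
  tensorMatToVec(e$vectors %*% diag(vals) %*% t(e$vectors))
}

## ---- 3D mask morphology ----------------------------------------------------

.offsets26 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
})

## shift a 3D logical array by (dx,dy,dz), padding with FALSE
shiftMask <- function(mask, dx, dy, dz) {
  d <- dim(mask)
  out <- array(FALSE, d)
  xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
  ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
  zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[xs, ys, zs] <- mask[xs - dx, ys - dy, zs - dz]
  out
}

#' Dilate a 3D binary mask with the 26-neighbourhood
#' @param mask 3D logical array
#' @param iter number of dilation passes
#' @return 3D logical array
#' @keywords internal
dilateMask26 <- function(mask, iter = 1L) {
  m <- mask
  for (i in seq_len(iter)) {
    out <- m
    for (k in seq_len(nrow(.offsets26)))
      out <- out | shiftMask(m, .offsets26[k, 1], .offsets26[k, 2], .offsets26[k, 3])
    m <- out
  }
  m
}

#' Label 26-connected components of a 3D binary mask
#' @param mask 3D logical array
#' @return integer array, 0 outside the mask, component ids 1..k inside
#' @keywords internal
labelComponents26 <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, d)
  idx <- which(mask)
  if (length(idx) == 0L) return(labels)
  coord <- arrayInd(idx, d)
  inmask <- array(FALSE, d); inmask[idx] <- TRUE
  nextLab <- 0L
  for (i in idx) {
    if (labels[i] != 0L) next
    nextLab <- nextLab + 1L
    queue <- i
    labels[i] <- nextLab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cc <- arrayInd(cur, d)
      for (k in seq_len(nrow(.offsets26))) {
        x <- cc[1] + .offsets26[k, 1]; y <- cc[2] + .offsets26[k, 2]; z <- cc[3] + .offsets26[k, 3]
        if (x < 1 || y < 1 || z < 1 || x > d[1] || y > d[2] || z > d[3]) next
        j <- x + (y - 1L) * d[1] + (z - 1L) * d[1] * d[2]
        if (inmask[j] && labels[j] == 0L) {
          labels[j] <- nextLab
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

## linear voxel index from 1-based voxel coordinates (matrix n x 3)
voxelLinearIndex <- function(coord, dim3) {
  coord[, 1] + (coord[, 2] - 1L) * dim3[1] + (coord[, 3] - 1L) * dim3[1] * dim3[2]
}

## world mm -> 1-based voxel coordinate (nearest voxel centre), given affine
worldToVoxel <- function(points, affine) {
  inv <- solve(affine)
  p <- cbind(points, 1) %*% t(inv)
  p[, 1:3, drop = FALSE] + 1  # 0-based ijk -> 1-based
}

voxelToWorld <- function(coord, affine) {
  p <- cbind(coord - 1, 1) %*% t(affine)
  p[, 1:3, drop = FALSE]
}
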