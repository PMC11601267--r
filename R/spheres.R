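# Direction sets, the frozen 362-vertex sphere and the real symmetric
# spherical-harmonic basis used for fODF work.

#' Approximately uniform unit directions by electrostatic repulsion
#'
#' Minimizes the Coulomb energy of \code{n} points and their antipodes on the
#' unit sphere by projected gradient descent with a decaying step. The result
#' is deterministic for a given \code{(n, seed)} and cached per session.
#'
#' @param n number of directions
#' @param seed integer seed for the initial configuration
#' @param iter descent iterations
#' @return n x 3 matrix of unit row vectors
#' @export
repulsionDirections <- function(n, seed = 42L, iter = 300L) {
  stopifnot(n >= 1)
  key <- sprintf("dirs_%d_%d_%d", n, seed, iter)
  cache <- get("cache", envir = .fwetract_env)
  if (!is.null(cache[[key]])) return(cache[[key]])
  x <- withSeed(seed, {
    x0 <- matrix(rnorm(3 * n), n, 3)
    x0 / sqrt(rowSums(x0^2))
  })
  if (n > 1) {
    for (it in seq_len(iter)) {
      step <- 0.1 * 0.99^it
      G <- x %*% t(x)
      r1 <- sqrt(pmax(2 - 2 * G, 1e-18))   # |xi - xj|
      r2 <- sqrt(pmax(2 + 2 * G, 1e-18))   # |xi + xj|
      A <- 1 / r1^3 + 1 / r2^3
      B <- 1 / r1^3 - 1 / r2^3
      diag(A) <- 0; diag(B) <- 0
      force <- x * rowSums(A) - B %*% x
      # tangential projection, normalized step
      force <- force - x * rowSums(force * x)
      nf <- sqrt(rowSums(force^2))
      x <- x + force * (step / pmax(max(nf), 1e-12))
      x <- x / sqrt(rowSums(x^2))
    }
  }
  cache[[key]] <- x
  x
}

#' Minimum pairwise angle of a direction set (antipodally folded)
#' @param dirs n x 3 unit row vectors
#' @return smallest pairwise angle in degrees
#' @export
minPairwiseAngle <- function(dirs) {
  g <- abs(dirs %*% t(dirs))
  diag(g) <- 0
  acos(pmin(max(g), 1)) * 180 / pi
}

#' The frozen 362-vertex antipodally symmetric sphere
#'
#' fODFs are discretized on this fixed vertex set so that split-half
#' correlations are comparable across runs and machines. The set is an
#' electrostatic-repulsion configuration of 181 directions plus antipodes,
#' shipped with the package.
#'
#' @return 362 x 3 matrix of unit row vectors
#' @export
unitSphere362 <- function() {
  cache <- get("cache", envir = .fwetract_env)
  if (!is.null(cache$sphere362)) return(cache$sphere362)
  path <- system.file("extdata", "sphere362.csv", package = "fwetract")
  v <- as.matrix(read.csv(path))
  dimnames(v) <- NULL
  stopifnot(nrow(v) == 362)
  cache$sphere362 <- v
  v
}

## number of even-order real SH coefficients up to lmax
nShCoef <- function(lmax) as.integer((lmax + 1) * (lmax + 2) / 2)

#' Real symmetric spherical-harmonic basis
#'
#' Even-order real SH evaluated at unit directions. Within each even degree l
#' the orders run m = -l..l with sin terms for m < 0, the zonal term at m = 0
#' and cos terms for m > 0; the basis is orthonormal on the sphere.
#'
#' @param lmax maximum (even) harmonic degree
#' @param dirs n x 3 matrix of unit row vectors
#' @return n x nShCoef(lmax) basis matrix
#' @export
sphericalHarmonicBasis <- function(lmax, dirs) {
  stopifnot(lmax %% 2 == 0)
  theta <- acos(pmin(pmax(dirs[, 3], -1), 1))
  phi <- atan2(dirs[, 2], dirs[, 1])
  n <- nrow(dirs)
  out <- matrix(0, n, nShCoef(lmax))
  col <- 0L
  for (l in seq(0, lmax, by = 2)) {
    P <- pracma::legendre(l, cos(theta))          # (l+1) x n, rows m = 0..l
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
    for (m in -l:l) {
      col <- col + 1L
      am <- abs(m)
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      plm <- P[am + 1, ]
      out[, col] <- if (m < 0) {
        sqrt(2) * nrm * plm * sin(am * phi)
      } else if (m == 0) {
        nrm * plm
      } else {
        sqrt(2) * nrm * plm * cos(am * phi)
      }
    }
  }
  out
}

## degree l of each SH column up to lmax
shDegrees <- function(lmax) {
  unlist(lapply(seq(0, lmax, by = 2), function(l) rep(l, 2 * l + 1)))
}
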