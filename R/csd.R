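# Constrained spherical deconvolution: single-fiber response estimation,
# multi-shell deconvolution with an iterative non-negativity constraint on
# the 362-vertex sphere, discretization, and peak extraction.

#' Estimate a single-fiber response function
#'
#' Fits DTI, selects voxels with FA at or above \code{faThreshold}
#' (default 0.7), and averages their axially symmetrized tensor eigenvalues
#' (lambda_parallel, mean of the two minor eigenvalues) and b=0 signal.
#'
#' @param dwi a \linkS4class{DWIVolume}
#' @param faThreshold FA selection threshold
#' @param mask 3D logical candidate mask
#' @return a \linkS4class{ResponseFunction}
#' @export
estimateResponse <- function(dwi, faThreshold = 0.7, mask = NULL) {
  fit <- fitDti(dwi, mask = mask)
  sc <- dtiScalars(fit)
  sel <- which(fit@mask & sc$fa >= faThreshold)
  if (!length(sel))
    stop(sprintf("no voxel reaches FA >= %g; lower the threshold", faThreshold))
  d <- dim(fit@s0)
  dm <- matrix(fit@d, prod(d), 6)
  ev <- t(vapply(sel, function(v)
    sort(pmax(eigen(tensorVecToMat(dm[v, ]), symmetric = TRUE,
                    only.values = TRUE)$values, 1e-6), decreasing = TRUE),
    numeric(3)))
  lam <- colMeans(ev)
  new("ResponseFunction", evals = c(lam[1], mean(lam[2:3])),
      s0 = mean(fit@s0[sel]))
}

## rotational harmonic coefficients r_l of the zonal response at one b-value:
## response signal S(t) = s0 exp(-b (lperp + (lpar - lperp) t^2)), t = cos(theta)
.responseZonalCoefs <- function(response, b, lmax, nQuad = 64L) {
  gl <- pracma::gaussLegendre(nQuad, -1, 1)
  t <- gl$x
  S <- response@s0 * exp(-b * (response@evals[2] +
                               (response@evals[1] - response@evals[2]) * t^2))
  vapply(seq(0, lmax, by = 2), function(l) {
    P <- pracma::legendre(l, t)
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
    nrm <- sqrt((2 * l + 1) / (4 * pi))
    2 * pi * sum(gl$w * S * nrm * P[1, ])
  }, numeric(1))
}

## largest even lmax whose coefficient count fits the direction count
maxSupportedLmax <- function(nDirs, cap = 8L) {
  l <- 0L
  while (l + 2 <= cap && nShCoef(l + 2L) <= nDirs) l <- l + 2L
  l
}

#' Constrained spherical deconvolution of multi- or single-shell data
#'
#' Deconvolves the diffusion-weighted signal (all nonzero shells stacked,
#' one rotational response per shell) by the single-fiber response into an
#' even-order SH fODF, with an iterative hard non-negativity constraint at
#' the frozen 362-vertex sphere: amplitudes below \code{tau} times the mean
#' initial l=0 amplitude are driven to zero. Converges when the active set
#' stabilizes, or after \code{maxIter} iterations.
#'
#' @param dwi a \linkS4class{DWIVolume}
#' @param response a \linkS4class{ResponseFunction}
#' @param lmax even SH order; \code{NULL} (default) picks the largest order
#'   (at most 8) supported by the direction count
#' @param mask 3D logical fit mask
#' @param tau constraint threshold, fraction of the mean l=0 amplitude
#' @param lambda constraint weight
#' @param maxIter constraint iteration cap (default 50)
#' @return an \linkS4class{SHField}
#' @export
fitCsd <- function(dwi, response, lmax = NULL, mask = NULL,
                   tau = 0.1, lambda = 1, maxIter = 50L) {
  gtab <- dwi@gtab
  dw <- which(gtab@shellIds > 0L)
  shells <- setdiff(unique(gtab@shellIds), 0L)
  perShellLmax <- vapply(shells, function(s)
    maxSupportedLmax(sum(gtab@shellIds[dw] == s)), integer(1))
  if (is.null(lmax)) lmax <- max(perShellLmax)
  if (lmax %% 2 != 0) stop("lmax must be even")
  if (lmax > max(perShellLmax))
    stop(sprintf("singular deconvolution: lmax %d needs %d coefficients but the largest shell supports only lmax %d",
                 lmax, nShCoef(lmax), max(perShellLmax)))
  nc <- nShCoef(lmax)
  d3 <- dim(dwi@signal)[1:3]
  mask <- mask %||% dwi@wmMask %||% dwi@brainMask %||% array(TRUE, d3)
  idx <- which(mask)
  sig <- matrix(dwi@signal, prod(d3), dim(dwi@signal)[4])[idx, dw, drop = FALSE]

  ## per-shell signal -> SH projection (exact for band-limited signals, so
  ## an isotropic per-shell mismatch cannot leak into higher degrees), then
  ## the deconvolution couples coefficients only within a degree
  degrees <- shDegrees(lmax)
  Fw <- NULL          # stacked rows: one per (shell, coefficient)
  proj <- list()      # per-shell projection matrices onto SH coefficients
  for (k in seq_along(shells)) {
    s <- shells[k]
    rows <- which(gtab@shellIds[dw] == s)
    lms <- min(lmax, perShellLmax[k])
    ncs <- nShCoef(lms)
    Y <- sphericalHarmonicBasis(lms, t(gtab@bvecs[, dw[rows], drop = FALSE]))
    P <- solve(crossprod(Y), t(Y))
    bShell <- mean(gtab@bvals[dw[rows]])
    rl <- .responseZonalCoefs(response, bShell, lmax)
    cl <- (sqrt(4 * pi / (2 * seq(0, lmax, by = 2) + 1)) * rl) / response@s0
    block <- matrix(0, ncs, nc)
    block[cbind(seq_len(ncs), seq_len(ncs))] <-
      cl[degrees[seq_len(ncs)] / 2 + 1]
    ## weight the block by the shell's direction count
    w <- sqrt(length(rows))
    Fw <- rbind(Fw, w * block)
    proj[[k]] <- list(rows = rows, P = w * P / response@s0, ncs = ncs)
  }
  B <- sphericalHarmonicBasis(lmax, unitSphere362())
  lambdaEff <- lambda * sqrt(mean(Fw[Fw != 0]^2))
  Finv <- solve(crossprod(Fw) + 1e-12 * diag(nc), t(Fw))

  nvox <- length(idx)
  coefs <- matrix(0, nvox, nc)
  for (v in seq_len(nvox)) {
    rhs0 <- unlist(lapply(proj, function(p)
      drop(p$P %*% sig[v, p$rows])))
    x <- drop(Finv %*% rhs0)
    thr <- tau * x[1] * B[1, 1]          # tau x mean l=0 amplitude
    neg <- rep(FALSE, 362)
    for (it in seq_len(maxIter)) {
      amp <- drop(B %*% x)
      negNew <- amp < thr
      if (identical(negNew, neg) && it > 1) break
      neg <- negNew
      if (!any(neg)) break
      M <- rbind(Fw, lambdaEff * B[neg, , drop = FALSE])
      rhs <- c(rhs0, numeric(sum(neg)))
      x <- tryCatch(qr.solve(M, rhs), error = function(e) x)
    }
    coefs[v, ] <- x
  }
  cm <- matrix(0, prod(d3), nc); cm[idx, ] <- coefs
  new("SHField", coef = array(cm, c(d3, nc)), lmax = as.integer(lmax),
      mask = array(as.logical(mask), d3))
}

#' Discretize an SH field on the frozen 362-vertex sphere
#' @param sh an \linkS4class{SHField}
#' @return a \linkS4class{DiscretizedODFField}
#' @export
discretizeFodf <- function(sh) {
  d3 <- dim(sh@coef)[1:3]
  V <- unitSphere362()
  B <- sphericalHarmonicBasis(sh@lmax, V)
  cm <- matrix(sh@coef, prod(d3), dim(sh@coef)[4])
  amp <- cm %*% t(B)
  new("DiscretizedODFField", amp = array(amp, c(d3, 362)),
      vertices = V, mask = sh@mask)
}

## cached vertex adjacency for local-maximum detection (neighbours within deg)
.sphereNeighbours <- function(V, deg = 16) {
  cache <- get("cache", envir = .fwetract_env)
  key <- sprintf("nbr_%g", deg)
  if (!is.null(cache[[key]])) return(cache[[key]])
  g <- V %*% t(V)
  adj <- lapply(seq_len(nrow(V)), function(i) {
    j <- which(g[i, ] >= cos(deg * pi / 180))
    setdiff(j, i)
  })
  cache[[key]] <- adj
  adj
}

#' Extract fODF peak directions
#'
#' Local maxima on the sphere vertex graph, kept if at or above
#' \code{relThreshold} times the voxel's maximum amplitude and suppressed
#' within \code{minSeparationDeg} of a stronger peak (antipodally folded);
#' at most 3 peaks per voxel. For a perfectly uniform fODF the lowest
#' vertex index wins.
#'
#' @param odf a \linkS4class{DiscretizedODFField}
#' @param minSeparationDeg peak separation (default 25)
#' @param relThreshold relative amplitude threshold (default 0.5)
#' @return list (one entry per masked voxel, named by linear voxel index) of
#'   k x 3 peak direction matrices
#' @export
extractPeaks <- function(odf, minSeparationDeg = 25, relThreshold = 0.5) {
  V <- odf@vertices
  adj <- .sphereNeighbours(V)
  d3 <- dim(odf@amp)[1:3]
  am <- matrix(odf@amp, prod(d3), 362)
  idx <- which(odf@mask)
  out <- vector("list", length(idx))
  names(out) <- idx
  cosSep <- cos(minSeparationDeg * pi / 180)
  for (k in seq_along(idx)) {
    a <- am[idx[k], ]
    if (diff(range(a)) <= 1e-12 * max(abs(a), 1e-300)) {
      ## flat fODF: one arbitrary peak, lowest vertex index by convention
      out[[k]] <- V[1, , drop = FALSE]
      next
    }
    isMax <- vapply(seq_len(362), function(i) all(a[i] >= a[adj[[i]]]),
                    logical(1))
    cand <- which(isMax & a >= relThreshold * max(a) & a > 0)
    cand <- cand[order(-a[cand], cand)]
    kept <- integer(0)
    for (i in cand) {
      if (length(kept) >= 3) break
      if (all(abs(V[i, ] %*% t(V[kept, , drop = FALSE])) < cosSep) ||
          !length(kept))
        kept <- c(kept, i)
    }
    out[[k]] <- V[kept, , drop = FALSE]
  }
  out
}
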