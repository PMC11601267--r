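# The bi-tensor free-water model: signal prediction, multi-shell NLS fitting,
# single-shell spatially regularized fitting, and free-water elimination.
#
# Model per voxel:  S(theta, b) = S0 (1-f) exp(-b theta' Q theta)
#                                + S0 f exp(-b D_iso),
# with D_iso fixed at 3e-3 mm^2/s. The elimination step subtracts the second
# term:             S_fwe = S - S0 f exp(-b D_iso).

FW_EVAL_MIN <- 1e-5    # mm^2/s, post-fit tensor eigenvalue floor
FW_EVAL_MAX <- 2.5e-3  # mm^2/s, post-fit tensor eigenvalue cap

#' Predict the bi-tensor free-water signal
#'
#' Evaluates the mixture model exactly for every fitted voxel; at b = 0 the
#' prediction equals S0. Voxels outside the fit mask are NA.
#'
#' @param fit a \linkS4class{FreeWaterFit}
#' @param gtab a \linkS4class{GradientTable}
#' @return 4D array of predicted signals
#' @export
predictFwdtiSignal <- function(fit, gtab) {
  d <- dim(fit@s0)
  n <- length(gtab@bvals)
  out <- array(NA_real_, c(d, n))
  idx <- which(fit@mask)
  if (!length(idx)) return(out)
  b <- gtab@bvals
  X <- tensorDesign(gtab@bvecs)                       # n x 6
  qm <- matrix(fit@q, prod(d), 6)[idx, , drop = FALSE]
  expo <- exp(-(qm %*% t(X)) * rep(b, each = length(idx)))  # nvox x n
  attW <- exp(-b * fit@dIso)
  s0 <- fit@s0[idx]; f <- fit@f[idx]
  pred <- s0 * (1 - f) * expo + outer(s0 * f, attW)
  outm <- matrix(out, prod(d), n)
  outm[idx, ] <- pred
  array(outm, c(d, n))
}

## OLS log-linear tensor fit of corrected signals for many voxels at once.
## scorr: nvox x nw, returns list(coef = 7 x nvox, rss = per-voxel residual
## sum of squares in the *signal* domain vs scorr)
.tensorFitGivenF <- function(scorr, P, A, floorVal) {
  y <- t(log(pmax(scorr, floorVal)))       # nw x nvox
  coef <- P %*% y                          # 7 x nvox
  pred <- exp(A %*% coef)                  # nw x nvox
  rss <- colSums((t(scorr) - pred)^2)
  list(coef = coef, pred = pred, rss = rss)
}

#' Fit the free-water DTI model to multi-shell data
#'
#' Per-voxel non-linear least squares on the mixture model over
#' (S0, f, tensor). S0 is estimated from the b=0 volumes; f is profiled out
#' by a golden-section/Brent search with a closed-form log-linear tensor fit
#' at each candidate f (variable projection), then the joint parameters are
#' polished by damped Gauss-Newton. Tensor eigenvalues are clamped to
#' [1e-5, 2.5e-3] mm^2/s after the fit and f is constrained to [0, 1].
#'
#' @param dwi a \linkS4class{DWIVolume} with >= 2 nonzero shells and >= 1
#'   b=0 volume
#' @param mask 3D logical fit mask (default: white-matter mask, else brain
#'   mask, else everything)
#' @param refine run the Gauss-Newton polish (default TRUE)
#' @param maxIter polish iteration cap
#' @return a \linkS4class{FreeWaterFit}
#' @export
fitFwdtiMultishell <- function(dwi, mask = NULL, refine = TRUE, maxIter = 20L) {
  gtab <- dwi@gtab
  nShells <- length(setdiff(unique(gtab@shellIds), 0L))
  if (nShells < 2)
    stop("multi-shell fit requires >= 2 nonzero shells; use fitFwdtiSingleshell")
  if (!any(gtab@shellIds == 0L)) stop("at least one b=0 volume required")
  d <- dim(dwi@signal)[1:3]
  mask <- mask %||% dwi@wmMask %||% dwi@brainMask %||% array(TRUE, d)
  idx <- which(mask)
  sig <- matrix(dwi@signal, prod(d), dim(dwi@signal)[4])[idx, , drop = FALSE]

  isB0 <- gtab@shellIds == 0L
  w <- which(!isB0)
  b <- gtab@bvals[w]
  A <- cbind(1, -b * tensorDesign(gtab@bvecs[, w, drop = FALSE]))  # nw x 7
  P <- solve(crossprod(A), t(A))
  attW <- exp(-b * D_ISO_DEFAULT)

  s0 <- rowMeans(sig[, isB0, drop = FALSE])
  bad <- s0 <= 0 | apply(sig, 1, function(r) all(r == 0))

  nvox <- length(idx)
  fHat <- numeric(nvox); qHat <- matrix(0, nvox, 6)
  s0Hat <- s0; conv <- logical(nvox); nIt <- integer(nvox)
  floorVal <- pmax(1e-6 * s0, 1e-12)
  sw <- sig[, w, drop = FALSE]

  ## coarse f grid, vectorized across voxels
  fGrid <- seq(0, 0.95, by = 0.05)
  bestRss <- rep(Inf, nvox); bestF <- numeric(nvox)
  for (fv in fGrid) {
    scorr <- sw - outer(s0 * fv, attW)
    fit <- .tensorFitGivenF(scorr, P, A, floorVal)
    ## residual vs the *observed* signal: add back the water term
    rss <- colSums((t(sw) - fit$pred - outer(attW, s0 * fv))^2)
    better <- rss < bestRss
    bestRss[better] <- rss[better]; bestF[better] <- fv
  }

  ## per-voxel Brent refinement of f
  for (v in seq_len(nvox)) {
    if (bad[v]) next
    svec <- sw[v, ]; s0v <- s0[v]; fl <- floorVal[v]
    obj <- function(fv) {
      scorr <- svec - s0v * fv * attW
      coef <- P %*% log(pmax(scorr, fl))
      sum((svec - exp(drop(A %*% coef)) - s0v * fv * attW)^2)
    }
    lo <- max(0, bestF[v] - 0.05); hi <- min(1, bestF[v] + 0.05)
    op <- optimize(obj, c(lo, hi), tol = 1e-7)
    fv <- op$minimum
    scorr <- svec - s0v * fv * attW
    coef <- drop(P %*% log(pmax(scorr, fl)))
    fHat[v] <- fv
    qHat[v, ] <- coef[2:7]
    s0Hat[v] <- s0v
    conv[v] <- TRUE
  }

  if (refine) {
    bAll <- gtab@bvals
    Xall <- tensorDesign(gtab@bvecs)
    attWall <- exp(-bAll * D_ISO_DEFAULT)
    for (v in seq_len(nvox)) {
      if (bad[v]) next
      res <- .gaussNewtonFw(sig[v, ], bAll, Xall, attWall,
                            c(log(s0Hat[v]), fHat[v], qHat[v, ]), maxIter)
      s0Hat[v] <- exp(res$p[1]); fHat[v] <- res$p[2]; qHat[v, ] <- res$p[3:8]
      conv[v] <- res$converged; nIt[v] <- res$iter
    }
  }

  ## clamp and assemble
  fHat <- pmin(pmax(fHat, 0), 1)
  for (v in seq_len(nvox))
    qHat[v, ] <- if (bad[v]) c(rep(0.7e-3, 3), 0, 0, 0) else
      clampTensorVec(qHat[v, ], FW_EVAL_MIN, FW_EVAL_MAX)

  .assembleFwFit(d, idx, s0Hat, fHat, qHat, conv & !bad, nIt, mask)
}

## damped Gauss-Newton on p = (log S0, f, q6) for the full mixture model
.gaussNewtonFw <- function(svec, b, X, attW, p, maxIter) {
  resid <- function(p) {
    T <- exp(-b * drop(X %*% p[3:8]))
    m <- exp(p[1]) * ((1 - p[2]) * T + p[2] * attW)
    list(r = svec - m, T = T, m = m)
  }
  cur <- resid(p); rss <- sum(cur$r^2)
  lambda <- 1e-3; converged <- FALSE; it <- 0L
  for (it in seq_len(maxIter)) {
    s0v <- exp(p[1])
    J <- cbind(cur$m,
               s0v * (attW - cur$T),
               -s0v * (1 - p[2]) * b * X * cur$T)
    g <- crossprod(J, cur$r)
    H <- crossprod(J)
    ok <- FALSE
    for (tries in 1:8) {
      step <- tryCatch(solve(H + lambda * diag(diag(H) + 1e-12), g),
                       error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      pNew <- p + drop(step)
      pNew[2] <- min(max(pNew[2], 1e-3), 1 - 1e-3)
      new <- resid(pNew)
      rssNew <- sum(new$r^2)
      if (rssNew <= rss) {
        if (rss - rssNew < 1e-12 * (rss + 1e-30)) converged <- TRUE
        p <- pNew; cur <- new; rss <- rssNew
        lambda <- max(lambda / 10, 1e-10); ok <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!ok || converged) { converged <- TRUE; break }
  }
  list(p = p, converged = converged, iter = it)
}

.assembleFwFit <- function(d, idx, s0Hat, fHat, qHat, conv, nIt, mask) {
  mk3 <- function(vals, fill = 0) { a <- array(fill, d); a[idx] <- vals; a }
  qArr <- array(0, c(d, 6))
  qm <- matrix(qArr, prod(d), 6); qm[idx, ] <- qHat
  new("FreeWaterFit", s0 = mk3(s0Hat), f = mk3(fHat),
      q = array(qm, c(d, 6)), dIso = D_ISO_DEFAULT,
      converged = mk3(conv, FALSE), nIter = mk3(nIt, 0L),
      mask = array(as.logical(mask), d))
}

#' Fit the free-water DTI model to single-shell data
#'
#' Single-shell fitting is ill-posed voxelwise, so the fit couples neighbours:
#' iterative gradient descent on the data-fidelity term plus a spatial
#' smoothness penalty on the tensor field. The free-water fraction is
#' initialized per voxel from the observed b=0-normalized shell attenuation
#' interpolated between a typical-tissue bound and the pure-water bound, and
#' is kept within the per-voxel interval implied by tissue diffusivities in
#' [0.1, 2.5]e-3 mm^2/s.
#'
#' @param dwi a \linkS4class{DWIVolume} with exactly one nonzero shell
#' @param mask 3D logical fit mask
#' @param regWeight spatial-smoothness weight (dimensionless; default 1)
#' @param nIter descent iterations (default 100)
#' @param step descent step (default 1e-3, on unit-scaled parameters)
#' @param fixF optional 3D array: hold f fixed at these values
#' @param mdTypical typical tissue mean diffusivity used for the f
#'   initialization (mm^2/s)
#' @return a \linkS4class{FreeWaterFit}
#' @export
fitFwdtiSingleshell <- function(dwi, mask = NULL, regWeight = 1, nIter = 100L,
                                step = 1e-3, fixF = NULL,
                                mdTypical = 0.6e-3) {
  gtab <- dwi@gtab
  shells <- setdiff(unique(gtab@shellIds), 0L)
  if (length(shells) != 1)
    stop("single-shell fit requires exactly one nonzero shell; use fitFwdtiMultishell")
  if (!any(gtab@shellIds == 0L)) stop("at least one b=0 volume required")
  d <- dim(dwi@signal)[1:3]
  mask <- mask %||% dwi@wmMask %||% dwi@brainMask %||% array(TRUE, d)
  idx <- which(mask)
  nvox <- length(idx)
  sig <- matrix(dwi@signal, prod(d), dim(dwi@signal)[4])[idx, , drop = FALSE]

  isB0 <- gtab@shellIds == 0L
  w <- which(!isB0)
  b <- mean(gtab@bvals[w])
  X <- tensorDesign(gtab@bvecs[, w, drop = FALSE])    # nw x 6
  nw <- length(w)
  s0 <- pmax(rowMeans(sig[, isB0, drop = FALSE]), 1e-12)
  sw <- sig[, w, drop = FALSE]

  ## per-voxel f bounds and initialization from attenuation interpolation
  aMean <- rowMeans(sw) / s0
  aw <- exp(-b * D_ISO_DEFAULT)
  atMin <- exp(-b * FW_EVAL_MAX)        # strongest tissue decay
  atMax <- exp(-b * 1e-4)               # weakest tissue decay
  fFromAt <- function(at) pmin(pmax((at - aMean) / (at - aw), 0), 1 - 1e-3)
  fMin <- fFromAt(atMin); fMax <- fFromAt(atMax)
  swap <- fMin > fMax
  tmp <- fMin[swap]; fMin[swap] <- fMax[swap]; fMax[swap] <- tmp
  f <- pmin(pmax(fFromAt(exp(-b * mdTypical)), fMin), fMax)
  fixed <- !is.null(fixF)
  if (fixed) { f <- fixF[idx]; fMin <- f; fMax <- f }

  ## tensor init: log-linear fit of the f-corrected signal with known S0(1-f)
  ## (no intercept: at a single b the intercept is collinear with the trace)
  A <- -gtab@bvals[w] * X
  P <- solve(crossprod(A), t(A))
  scorr <- sw - outer(s0 * f, rep(aw, nw))
  y <- log(pmax(scorr, pmax(1e-6 * s0, 1e-12))) -
       log(pmax(s0 * (1 - f), 1e-12))
  qs <- t(P %*% t(y)) / 1e-3                           # nvox x 6, unit scale

  ## neighbour structure (6-neighbourhood forward differences inside mask)
  lin <- array(0L, d); lin[idx] <- seq_len(nvox)
  coord <- arrayInd(idx, d)
  nb <- list()
  for (off in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    cc <- sweep(coord, 2, off, `+`)
    ok <- cc[, 1] <= d[1] & cc[, 2] <= d[2] & cc[, 3] <= d[3]
    j <- integer(nvox)
    j[ok] <- lin[cc[ok, , drop = FALSE]]
    keep <- ok & j > 0
    nb[[length(nb) + 1]] <- cbind(which(keep), j[keep])
  }
  edges <- do.call(rbind, nb)

  attWvec <- rep(aw, nw)
  scale2 <- 1 / s0^2
  for (it in seq_len(nIter)) {
    Tmat <- exp(-(qs * 1e-3) %*% t(b * X))             # nvox x nw
    m <- s0 * (1 - f) * Tmat + outer(s0 * f, attWvec)
    r <- m - sw                                        # nvox x nw
    ## data gradients
    gF <- rowSums(r * (aw - Tmat)) * 2 * scale2 * s0
    common <- r * Tmat * (s0 * (1 - f)) * (-b * 1e-3) * 2 * scale2
    gQ <- common %*% X                                  # nvox x 6
    ## smoothness gradient on qs
    if (regWeight > 0 && nrow(edges)) {
      diff <- qs[edges[, 1], , drop = FALSE] - qs[edges[, 2], , drop = FALSE]
      gR <- matrix(0, nvox, 6)
      for (k in 1:6) {
        a1 <- rowsum(2 * regWeight * diff[, k], edges[, 1], reorder = FALSE)
        gR[as.integer(rownames(a1)), k] <- gR[as.integer(rownames(a1)), k] + a1
        a2 <- rowsum(-2 * regWeight * diff[, k], edges[, 2], reorder = FALSE)
        gR[as.integer(rownames(a2)), k] <- gR[as.integer(rownames(a2)), k] + a2
      }
      gQ <- gQ + gR
    }
    qs <- qs - step * gQ
    if (!fixed) f <- pmin(pmax(f - step * gF, fMin), fMax)
  }

  q <- qs * 1e-3
  for (v in seq_len(nvox))
    q[v, ] <- clampTensorVec(q[v, ], FW_EVAL_MIN, FW_EVAL_MAX)
  .assembleFwFit(d, idx, s0, pmin(pmax(f, 0), 1), q,
                 rep(TRUE, nvox), rep(as.integer(nIter), nvox), mask)
}

#' Eliminate the free-water signal component
#'
#' Subtracts the isotropic compartment per voxel and volume:
#' \code{S_fwe = S - S0 f exp(-b D_iso)}; negative results are clamped to 0.
#' b=0 volumes become \code{S0 (1 - f)} up to noise. Voxels outside the fit
#' mask pass through unchanged.
#'
#' @param dwi a \linkS4class{DWIVolume}
#' @param fit a \linkS4class{FreeWaterFit} on the same grid
#' @return corrected \linkS4class{DWIVolume}
#' @export
eliminateFreeWater <- function(dwi, fit) {
  d <- dim(dwi@signal)
  if (!all(dim(fit@s0) == d[1:3]))
    stop("fit and volume grids differ")
  idx <- which(fit@mask)
  sig <- matrix(dwi@signal, prod(d[1:3]), d[4])
  attW <- exp(-dwi@gtab@bvals * fit@dIso)
  sig[idx, ] <- pmax(sig[idx, , drop = FALSE] -
                       outer(fit@s0[idx] * fit@f[idx], attW), 0)
  initialize(dwi, signal = array(sig, d))
}
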