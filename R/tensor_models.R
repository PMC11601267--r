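# Voxelwise DTI and DKI fitting and the scalar maps profiled along tracts
# (FA, MD, MK, WMTI-AWF). Log-signal weighted least squares throughout.

## fourth-order symmetric tensor design: 15 columns with multiplicities
.kt_idx <- rbind(
  c(1,1,1,1), c(2,2,2,2), c(3,3,3,3),
  c(1,1,1,2), c(1,1,1,3), c(1,2,2,2), c(2,2,2,3), c(1,3,3,3), c(2,3,3,3),
  c(1,1,2,2), c(1,1,3,3), c(2,2,3,3),
  c(1,1,2,3), c(1,2,2,3), c(1,2,3,3))
.kt_mult <- c(1, 1, 1, 4, 4, 4, 4, 4, 4, 6, 6, 6, 12, 12, 12)

kurtosisDesign <- function(bvecs) {
  g <- t(bvecs)  # n x 3
  out <- matrix(0, nrow(g), 15)
  for (k in 1:15) {
    ii <- .kt_idx[k, ]
    out[, k] <- .kt_mult[k] * g[, ii[1]] * g[, ii[2]] * g[, ii[3]] * g[, ii[4]]
  }
  out
}

.checkDirections <- function(gtab, minDirs) {
  dw <- gtab@shellIds > 0
  if (!any(gtab@shellIds == 0L)) stop("at least one b=0 volume required")
  dirs <- unique(round(t(gtab@bvecs[, dw, drop = FALSE]), 6))
  if (nrow(dirs) < minDirs)
    stop(sprintf("need >= %d unique diffusion directions, got %d",
                 minDirs, nrow(dirs)))
}

## generic per-voxel WLS of log-signal on a design matrix
.wlsLogFit <- function(sig, A, s0ref) {
  nvox <- nrow(sig)
  coefs <- matrix(0, nvox, ncol(A))
  for (v in seq_len(nvox)) {
    y <- log(pmax(sig[v, ], 1e-6 * max(s0ref[v], 1e-12)))
    w <- pmax(sig[v, ], 0)^2
    Aw <- A * sqrt(w)
    coefs[v, ] <- tryCatch(qr.solve(Aw, y * sqrt(w)),
                           error = function(e) rep(NA_real_, ncol(A)))
  }
  coefs
}

#' Fit the diffusion tensor (DTI) model
#'
#' Weighted least squares on log-signals (weights = squared signal);
#' non-positive signals are floored at 1e-6 of the voxel's b=0 level before
#' the log.
#'
#' @param dwi a \linkS4class{DWIVolume} with >= 6 unique directions and a b=0
#' @param mask 3D logical fit mask
#' @return a \linkS4class{DiffusionTensorFit}
#' @export
fitDti <- function(dwi, mask = NULL) {
  .checkDirections(dwi@gtab, 6)
  d <- dim(dwi@signal)[1:3]
  mask <- mask %||% dwi@wmMask %||% dwi@brainMask %||% array(TRUE, d)
  idx <- which(mask)
  sig <- matrix(dwi@signal, prod(d), dim(dwi@signal)[4])[idx, , drop = FALSE]
  b <- dwi@gtab@bvals
  A <- cbind(1, -b * tensorDesign(dwi@gtab@bvecs))
  s0ref <- rowMeans(sig[, dwi@gtab@shellIds == 0L, drop = FALSE])
  coefs <- .wlsLogFit(sig, A, s0ref)
  s0 <- array(0, d); s0[idx] <- exp(coefs[, 1])
  dm <- matrix(0, prod(d), 6); dm[idx, ] <- coefs[, 2:7]
  new("DiffusionTensorFit", s0 = s0, d = array(dm, c(d, 6)),
      mask = array(as.logical(mask), d))
}

## eigenvalue-based FA; eigenvalues clamped >= 0 first
.faFromEvals <- function(ev) {
  ev <- pmax(ev, 0)
  md <- mean(ev)
  num <- sum((ev - md)^2)
  den <- sum(ev^2)
  if (den <= 0) return(0)
  min(sqrt(1.5 * num / den), 1)
}

#' DTI scalar maps: fractional anisotropy and mean diffusivity
#' @param fit a \linkS4class{DiffusionTensorFit}
#' @return list with 3D arrays \code{fa} (in [0,1]) and \code{md} (mm^2/s)
#' @export
dtiScalars <- function(fit) {
  d <- dim(fit@s0)
  fa <- array(0, d); md <- array(0, d)
  idx <- which(fit@mask)
  dm <- matrix(fit@d, prod(d), 6)
  for (v in idx) {
    ev <- eigen(tensorVecToMat(dm[v, ]), symmetric = TRUE,
                only.values = TRUE)$values
    ev <- pmax(ev, 0)
    md[v] <- mean(ev)
    fa[v] <- .faFromEvals(ev)
  }
  list(fa = fa, md = md)
}

#' Fit the diffusional kurtosis (DKI) model
#'
#' Weighted least squares on the b and b^2 log-signal expansion for the
#' diffusion tensor and the 15 kurtosis-tensor components. Requires >= 2
#' nonzero shells and >= 21 unique measurements.
#'
#' @param dwi a \linkS4class{DWIVolume}
#' @param mask 3D logical fit mask
#' @return a \linkS4class{KurtosisFit}
#' @export
fitDki <- function(dwi, mask = NULL) {
  gtab <- dwi@gtab
  if (length(setdiff(unique(gtab@shellIds), 0L)) < 2)
    stop("DKI requires >= 2 nonzero shells")
  .checkDirections(gtab, 15)
  d <- dim(dwi@signal)[1:3]
  mask <- mask %||% dwi@wmMask %||% dwi@brainMask %||% array(TRUE, d)
  idx <- which(mask)
  sig <- matrix(dwi@signal, prod(d), dim(dwi@signal)[4])[idx, , drop = FALSE]
  b <- gtab@bvals
  A <- cbind(1, -b * tensorDesign(gtab@bvecs),
             (b^2 / 6) * kurtosisDesign(gtab@bvecs))
  s0ref <- rowMeans(sig[, gtab@shellIds == 0L, drop = FALSE])
  coefs <- .wlsLogFit(sig, A, s0ref)
  ## fitted kurtosis columns are V = MD^2 * W
  s0 <- array(0, d); s0[idx] <- exp(coefs[, 1])
  dm <- matrix(0, prod(d), 6); dm[idx, ] <- coefs[, 2:7]
  wm <- matrix(0, prod(d), 15)
  for (k in seq_along(idx)) {
    v <- idx[k]
    md <- mean(pmax(eigen(tensorVecToMat(coefs[k, 2:7]), symmetric = TRUE,
                          only.values = TRUE)$values, 0))
    wm[v, ] <- if (md > 0) coefs[k, 8:22] / md^2 else 0
  }
  new("KurtosisFit", s0 = s0, d = array(dm, c(d, 6)),
      w = array(wm, c(d, 15)), mask = array(as.logical(mask), d))
}

#' DKI scalar maps: FA, MD and mean kurtosis
#'
#' FA and MD come from the diffusion tensor as in \code{\link{dtiScalars}};
#' MK is the numerical mean of the apparent kurtosis over \code{nDirs}
#' repulsion directions, with apparent kurtosis clamped to [-3/7, 10].
#'
#' @param fit a \linkS4class{KurtosisFit}
#' @param nDirs quadrature direction count (default 180)
#' @return list with 3D arrays \code{fa}, \code{md}, \code{mk}
#' @export
dkiScalars <- function(fit, nDirs = 180L) {
  d <- dim(fit@s0)
  dirs <- repulsionDirections(nDirs)
  X2 <- tensorDesign(t(dirs))
  X4 <- kurtosisDesign(t(dirs))
  fa <- array(0, d); md <- array(0, d); mk <- array(0, d)
  idx <- which(fit@mask)
  dm <- matrix(fit@d, prod(d), 6)[idx, , drop = FALSE]
  wm <- matrix(fit@w, prod(d), 15)[idx, , drop = FALSE]
  for (k in seq_along(idx)) {
    ev <- pmax(eigen(tensorVecToMat(dm[k, ]), symmetric = TRUE,
                     only.values = TRUE)$values, 0)
    md[idx[k]] <- mean(ev)
    fa[idx[k]] <- .faFromEvals(ev)
  }
  ## apparent kurtosis, vectorized over voxels:
  ## K(n) = MD^2 sum(n^4 W) / D(n)^2, clamped to [-3/7, 10]
  dn <- pmax(dm %*% t(X2), 1e-12)          # nvox x ndirs
  kap <- (md[idx]^2) * (wm %*% t(X4)) / dn^2
  kap <- pmin(pmax(kap, -3 / 7), 10)
  mk[idx] <- rowMeans(kap)
  list(fa = fa, md = md, mk = mk)
}

#' WMTI axonal water fraction map
#'
#' AWF = K_max / (K_max + 3), with K_max the maximum apparent kurtosis over a
#' repulsion direction set; clamped to [0, 1]. Assumes well-aligned white
#' matter voxels (caller's responsibility). The estimator follows the
#' standard white-matter tract integrity construction.
#'
#' @param fit a \linkS4class{KurtosisFit}
#' @param nDirs direction count for the maximum search (default 180)
#' @return 3D AWF array
#' @export
wmtiAwf <- function(fit, nDirs = 180L) {
  d <- dim(fit@s0)
  dirs <- repulsionDirections(nDirs)
  X2 <- tensorDesign(t(dirs))
  X4 <- kurtosisDesign(t(dirs))
  awf <- array(0, d)
  idx <- which(fit@mask)
  dm <- matrix(fit@d, prod(d), 6)[idx, , drop = FALSE]
  wm <- matrix(fit@w, prod(d), 15)[idx, , drop = FALSE]
  md <- vapply(seq_along(idx), function(k)
    mean(pmax(eigen(tensorVecToMat(dm[k, ]), symmetric = TRUE,
                    only.values = TRUE)$values, 0)), numeric(1))
  dn <- pmax(dm %*% t(X2), 1e-12)
  kap <- pmin(pmax((md^2) * (wm %*% t(X4)) / dn^2, -3 / 7), 10)
  kmax <- pmax(apply(kap, 1, max), 0)
  awf[idx] <- pmin(kmax / (kmax + 3), 1)
  awf
}
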