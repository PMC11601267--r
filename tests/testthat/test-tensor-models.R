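# DTI / DKI fitting and the scalar maps (FA, MD, MK, WMTI-AWF).

test_that("DTI recovers a noise-free tensor and its scalar maps", {
  gt <- fullGtab()
  dwi <- voxelDwi(matrix(mixSignal(0, gt), 1), gt)
  fit <- fitDti(dwi)
  expect_lt(max(abs(fit@d[1, 1, 1, ] - tensorMatToVec(wmTensor()))), 1e-6)
  sc <- dtiScalars(fit)
  expect_equal(sc$md[1], 0.7e-3, tolerance = 1e-9)
  # independent closed-form FA oracle for (1.7, 0.2, 0.2)e-3
  ev <- c(1.7, 0.2, 0.2) * 1e-3
  faOracle <- sqrt(1.5 * sum((ev - mean(ev))^2) / sum(ev^2))
  expect_equal(sc$fa[1], faOracle, tolerance = 1e-6)
  expect_equal(round(faOracle, 3), 0.870)

  # isotropic signal: FA = 0
  iso <- voxelDwi(matrix(100 * exp(-bvals(gt) * 0.7e-3), 1), gt)
  expect_equal(dtiScalars(fitDti(iso))$fa[1], 0, tolerance = 1e-9)

  # log-linear model: invariant to global scaling
  fit10 <- fitDti(voxelDwi(matrix(mixSignal(0, gt) * 10, 1), gt))
  expect_equal(fit10@d[1, 1, 1, ], fit@d[1, 1, 1, ], tolerance = 1e-12)

  # too few directions
  gt6 <- gradientTable(c(0, rep(1000, 4)),
                       cbind(0, t(repulsionDirections(4))))
  expect_error(fitDti(voxelDwi(matrix(1, 1, 5), gt6)), "unique")
})

test_that("DKI reduces to DTI for Gaussian signals and detects non-Gaussianity", {
  gt <- fullGtab()
  gauss <- voxelDwi(matrix(mixSignal(0, gt), 1), gt)
  kfit <- fitDki(gauss)
  dfit <- fitDti(gauss)
  expect_lt(max(abs(kfit@d[1, 1, 1, ] - dfit@d[1, 1, 1, ])), 1e-6)
  expect_lt(abs(dkiScalars(kfit)$mk[1]), 0.02)

  # 50/50 mixture of two distinct tensors: MK > 0, direction of the
  # analytic two-Gaussian kurtosis oracle K(n) = 3 Var(D_i(n)) / Dbar(n)^2
  qA <- wmTensor(); qB <- diag(c(0.2, 1.7, 0.2) * 1e-3)
  s2 <- simulateMixtureSignal(list(list(tensor = qA, fraction = 0.5),
                                   list(tensor = qB, fraction = 0.5)),
                              f = 0, s0 = 100, gtab = gt)
  k2 <- fitDki(voxelDwi(matrix(s2, 1), gt))
  mk2 <- dkiScalars(k2)$mk[1]
  expect_gt(mk2, 0)
  dirs <- repulsionDirections(180)
  X2 <- tensorDesign(t(dirs))
  da <- drop(X2 %*% tensorMatToVec(qA)); db <- drop(X2 %*% tensorMatToVec(qB))
  kOracle <- mean(3 * (0.5 * (da - (da + db) / 2)^2 +
                       0.5 * (db - (da + db) / 2)^2) / ((da + db) / 2)^2)
  # the b^2-truncated fit underestimates the small-b cumulant limit at
  # b_max = 2500; agreement is to leading order only
  expect_equal(mk2, kOracle, tolerance = 0.35)

  # adding free water raises MK versus f = 0
  sfw <- mixSignal(0.3, gt)
  mkfw <- dkiScalars(fitDki(voxelDwi(matrix(sfw, 1), gt)))$mk[1]
  expect_gt(mkfw, mk2 * 0)   # positive
  expect_gt(mkfw, dkiScalars(fitDki(gauss))$mk[1])

  # single shell is rejected
  ssgt <- gradientTable(c(0, rep(1000, 30)),
                        cbind(0, t(repulsionDirections(30))))
  expect_error(fitDki(voxelDwi(matrix(1, 1, 31), ssgt)), "shells")
})

test_that("MK quadrature converges and respects exact limits", {
  d3 <- c(1, 1, 1)
  mkFit <- function(d6, w15)
    new("KurtosisFit", s0 = array(100, d3), d = array(d6, c(d3, 6)),
        w = array(w15, c(d3, 15)), mask = array(TRUE, d3))
  # W = 0 -> MK = 0 exactly
  f0 <- mkFit(tensorMatToVec(wmTensor()), rep(0, 15))
  expect_equal(dkiScalars(f0)$mk[1], 0)
  # isotropic D with isotropic W of apparent kurtosis k -> MK = k
  k <- 0.8
  d6 <- c(rep(1e-3, 3), 0, 0, 0)
  # isotropic kurtosis tensor: W1111 = W2222 = W3333 = k, W1122 etc = k/3
  w15 <- numeric(15); w15[1:3] <- k; w15[10:12] <- k / 3
  expect_equal(dkiScalars(mkFit(d6, w15))$mk[1], k, tolerance = 1e-9)
  # doubling the direction count barely moves MK for a smooth W
  gt <- fullGtab()
  s2 <- simulateMixtureSignal(list(list(tensor = wmTensor(), fraction = 0.5),
                                   list(tensor = diag(c(0.2, 1.7, 0.2) * 1e-3),
                                        fraction = 0.5)),
                              f = 0, s0 = 100, gtab = gt)
  kf <- fitDki(voxelDwi(matrix(s2, 1), gt))
  expect_lt(abs(dkiScalars(kf, nDirs = 360)$mk[1] -
                dkiScalars(kf, nDirs = 180)$mk[1]), 1e-3)
})

test_that("WMTI AWF follows its formula and approximates the intra-axonal fraction", {
  d3 <- c(1, 1, 1)
  mkFit <- function(d6, w15)
    new("KurtosisFit", s0 = array(100, d3), d = array(d6, c(d3, 6)),
        w = array(w15, c(d3, 15)), mask = array(TRUE, d3))
  # K_max = 0 -> AWF = 0
  expect_equal(wmtiAwf(mkFit(tensorMatToVec(wmTensor()), rep(0, 15)))[1], 0)
  # isotropic apparent kurtosis exactly 3 -> AWF = 0.5
  d6 <- c(rep(1e-3, 3), 0, 0, 0)
  w15 <- numeric(15); w15[1:3] <- 3; w15[10:12] <- 1
  expect_equal(wmtiAwf(mkFit(d6, w15))[1], 0.5, tolerance = 1e-9)
  # aligned two-compartment voxel: AWF near the constructed intra fraction
  gt <- fullGtab()
  fIntra <- 0.4
  s <- simulateMixtureSignal(
    list(list(tensor = diag(c(1.2, 0.001, 0.001) * 1e-3), fraction = fIntra),
         list(tensor = diag(c(1.2, 0.9, 0.9) * 1e-3), fraction = 1 - fIntra)),
    f = 0, s0 = 100, gtab = gt)
  awf <- wmtiAwf(fitDki(voxelDwi(matrix(s, 1), gt)))[1]
  expect_lt(abs(awf - fIntra), 0.1)
})

test_that("DTI on FWE-corrected noise-free mixtures matches the pure tissue", {
  gt <- fullGtab()
  dwi <- voxelDwi(matrix(mixSignal(0.4, gt), 1), gt)
  fit <- fitFwdtiMultishell(dwi)
  corr <- eliminateFreeWater(dwi, fit)
  faCorr <- dtiScalars(fitDti(corr))$fa[1]
  faPure <- dtiScalars(fitDti(voxelDwi(matrix(mixSignal(0, gt), 1), gt)))$fa[1]
  expect_lt(abs(faCorr - faPure), 1e-3)
})
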