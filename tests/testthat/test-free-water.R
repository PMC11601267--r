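# Bi-tensor free-water model: prediction, multi-/single-shell fitting and
# free-water elimination.

test_that("model prediction reproduces the generator and its limits", {
  gt <- fullGtab()
  d3 <- c(1, 1, 1)
  mkFit <- function(f, q = tensorMatToVec(wmTensor()), s0 = 100)
    new("FreeWaterFit", s0 = array(s0, d3), f = array(f, d3),
        q = array(q, c(d3, 6)), dIso = 3e-3,
        converged = array(TRUE, d3), nIter = array(1L, d3),
        mask = array(TRUE, d3))
  # f = 0: pure tensor decay; f = 1: direction-independent isotropic decay
  p0 <- predictFwdtiSignal(mkFit(0), gt)[1, 1, 1, ]
  expect_equal(p0, mixSignal(0, gt))
  p1 <- predictFwdtiSignal(mkFit(1), gt)[1, 1, 1, ]
  expect_equal(p1, 100 * exp(-bvals(gt) * 3e-3))
  # round-trip against the generator at a mixed f
  expect_equal(predictFwdtiSignal(mkFit(0.37), gt)[1, 1, 1, ],
               mixSignal(0.37, gt))
  # at b = 0 the prediction is S0
  expect_true(all(p0[shellIds(gt) == 0] == 100))
})

test_that("multi-shell NLS recovers truth parameters", {
  gt <- fullGtab()
  qTrue <- tensorMatToVec(wmTensor())
  # noise-free recovery over the f grid
  for (f in seq(0, 0.9, 0.1)) {
    fit <- fitFwdtiMultishell(voxelDwi(matrix(mixSignal(f, gt), 1), gt))
    expect_lt(abs(fit@f[1] - f), 1e-3)
    expect_lt(max(abs(fit@q[1, 1, 1, ] - qTrue)), 1e-5)
  }
  # f = 0 voxel: recovered f < 0.02 and Q matches a plain tensor fit within 1%
  dwi0 <- voxelDwi(matrix(mixSignal(0, gt), 1), gt)
  fit0 <- fitFwdtiMultishell(dwi0)
  expect_lt(fit0@f[1], 0.02)
  dref <- fitDti(dwi0)
  expect_lt(max(abs(fit0@q[1, 1, 1, ] - dref@d[1, 1, 1, ])) / 1.7e-3, 0.01)
  # Rician SNR 30, 100 voxels, truth f = 0.3
  sig <- t(vapply(1:100, function(i) mixSignal(0.3, gt, snr = 30, seed = i),
                  numeric(250)))
  fitn <- fitFwdtiMultishell(voxelDwi(sig, gt))
  expect_lt(mean(abs(fitn@f - 0.3)), 0.05)
})

test_that("multi-shell fit guards its preconditions and degenerate voxels", {
  gt <- fullGtab()
  ss <- gradientTable(c(0, rep(1000, 10)),
                      cbind(0, t(repulsionDirections(10))))
  expect_error(fitFwdtiMultishell(voxelDwi(matrix(1, 1, 11), ss)),
               "Singleshell")
  # all-zero voxel: flagged, f = 0, isotropic default tensor
  sig <- rbind(mixSignal(0.2, gt), 0)
  fit <- fitFwdtiMultishell(voxelDwi(sig, gt))
  expect_false(fit@converged[2, 1, 1])
  expect_equal(fit@f[2, 1, 1], 0)
  expect_equal(fit@q[2, 1, 1, ], c(rep(0.7e-3, 3), 0, 0, 0))
})

test_that("fitting is invariant to global signal scaling", {
  gt <- fullGtab()
  s <- matrix(mixSignal(0.35, gt), 1)
  f1 <- fitFwdtiMultishell(voxelDwi(s, gt))
  f2 <- fitFwdtiMultishell(voxelDwi(s * 13, gt))
  expect_equal(f2@s0[1] / f1@s0[1], 13, tolerance = 1e-6)
  expect_equal(f2@f[1], f1@f[1], tolerance = 1e-6)
  expect_equal(f2@q[1, 1, 1, ], f1@q[1, 1, 1, ], tolerance = 1e-6)
})

test_that("single-shell regularized fit recovers f and respects its oracle", {
  gt <- fullGtab()
  ph <- buildPhantom(phantomSpec(fwBackground = 0.3, snr = Inf), gt)
  ss <- subsampleSingleShell(ph$dwi, 1000)
  fit <- fitFwdtiSingleshell(ss, mask = ph$truth$wmMask)
  expect_lt(max(abs(fit@f[ph$truth$wmMask] - 0.3)), 0.05)

  # reg = 0 with f fixed at truth: tensor matches voxelwise least squares
  fitfix <- fitFwdtiSingleshell(ss, mask = ph$truth$wmMask, regWeight = 0,
                                fixF = ph$truth$fMap)
  v <- which(ph$truth$wmMask)[7]
  cc <- arrayInd(v, dim(ph$truth$wmMask))
  # oracle: voxelwise log-linear LS of the f-corrected single-shell signal
  w <- shellIds(gradients(ss)) > 0
  svec <- dwiSignal(ss)[cc[1], cc[2], cc[3], ]
  s0 <- mean(svec[!w])
  scorr <- svec[w] - s0 * 0.3 * exp(-1000 * 3e-3)
  A <- -1000 * tensorDesign(bvecs(ss)[, w])
  qOracle <- qr.solve(A, log(scorr / (s0 * 0.7)))
  expect_lt(max(abs(fitfix@q[cc[1], cc[2], cc[3], ] - qOracle)), 1e-5)

  # uniform pure water recovers f >= 0.9
  phw <- buildPhantom(phantomSpec(ventricle = list(min = c(1, 1, 1),
                                                   max = c(5, 5, 5)),
                                  snr = Inf), gt)
  ssw <- subsampleSingleShell(phw$dwi, 1000)
  fw <- fitFwdtiSingleshell(ssw, mask = phw$truth$ventricleMask)
  expect_gte(min(fw@f[phw$truth$ventricleMask]), 0.9)

  expect_error(fitFwdtiSingleshell(ph$dwi), "exactly one")
})

test_that("free-water elimination is the exact algebraic complement", {
  gt <- fullGtab()
  ph <- phantomLesionNF()
  # f = 0 everywhere: bit-exact identity
  d3 <- dim(ph$truth$wmMask)
  fit0 <- new("FreeWaterFit", s0 = array(100, d3), f = array(0, d3),
              q = array(0, c(d3, 6)), dIso = 3e-3,
              converged = array(TRUE, d3), nIter = array(0L, d3),
              mask = array(TRUE, d3))
  expect_identical(dwiSignal(eliminateFreeWater(ph$dwi, fit0)),
                   dwiSignal(ph$dwi))
  # truth fit turns noise-free mixtures into the pure-tissue signal
  fit <- fitFwdtiMultishell(ph$dwi, mask = ph$truth$wmMask)
  corr <- eliminateFreeWater(ph$dwi, fit)
  v <- which(ph$truth$wmhMask)[3]
  cc <- arrayInd(v, d3)
  pure <- mixSignal(0, gt, s0 = 100 * (1 - 0.6))
  expect_equal(corr@signal[cc[1], cc[2], cc[3], ], pure, tolerance = 1e-10)
  # b = 0 with f = 0.4, S0 = 100 -> 60
  gtb <- gradientTable(0, matrix(0, 3, 1))
  dwb <- voxelDwi(matrix(100, 1, 1), gtb)
  fb <- new("FreeWaterFit", s0 = array(100, c(1, 1, 1)),
            f = array(0.4, c(1, 1, 1)), q = array(0, c(1, 1, 1, 6)),
            dIso = 3e-3, converged = array(TRUE, c(1, 1, 1)),
            nIter = array(0L, c(1, 1, 1)), mask = array(TRUE, c(1, 1, 1)))
  expect_equal(dwiSignal(eliminateFreeWater(dwb, fb))[1, 1, 1, 1], 60)
  # grid mismatch errors
  expect_error(eliminateFreeWater(ph$dwi, fb), "grids differ")
})

test_that("eliminating free water then fitting a plain tensor recovers Q", {
  gt <- fullGtab()
  s <- matrix(mixSignal(0.5, gt), 1)
  dwi <- voxelDwi(s, gt)
  fit <- fitFwdtiMultishell(dwi)
  corr <- eliminateFreeWater(dwi, fit)
  dref <- fitDti(corr)
  expect_lt(max(abs(dref@d[1, 1, 1, ] - tensorMatToVec(wmTensor()))) / 1.7e-3,
            0.01)
})
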