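# Gradient tables, shells, split-half construction and the NDC QC metric.

test_that("shell detection recovers the reference acquisition and edge cases", {
  gt <- fullGtab()
  expect_equal(nVolumes(gt), 250)
  counts <- as.integer(table(shellIds(gt)))
  expect_equal(counts, c(26, 32, 64, 128))
  expect_equal(unname(round(shellTable(gt))), c(0, 500, 1000, 2500))

  # all b = 0: a single shell 0
  gt0 <- gradientTable(rep(0, 5), matrix(0, 3, 5))
  expect_true(all(shellIds(gt0) == 0L))

  # values within tolerance cluster to one shell
  gt2 <- gradientTable(c(0, 995, 1005), cbind(0, c(1, 0, 0), c(0, 1, 0)),
                       tol = 50)
  expect_equal(shellIds(gt2), c(0L, 1L, 1L))

  # a chain spreading beyond the tolerance is ambiguous
  expect_error(gradientTable(c(0, 1000, 1040, 1080, 1120),
                             rbind(1, 0, 0) [, c(1, 1, 1, 1, 1)], tol = 50),
               "ambiguous")
})

test_that("single-shell subsampling keeps b=0 plus the matched shell in order", {
  ph <- phantomNF()
  ss <- subsampleSingleShell(ph$dwi, 1000)
  expect_equal(as.integer(table(shellIds(gradients(ss)))), c(26, 64))

  # identity when only b=0 and the kept shell exist
  ss2 <- subsampleSingleShell(ss, 1000)
  expect_identical(dwiSignal(ss2), dwiSignal(ss))

  expect_error(subsampleSingleShell(ph$dwi, 700), "available shells")
})

test_that("split-half partitions evenly per shell and reconstructs the parent", {
  ph <- phantomNF()
  sp <- splitHalf(ph$dwi, seed = 7)
  for (half in list(sp@halfA, sp@halfB))
    expect_equal(as.integer(table(shellIds(gradients(half)))),
                 c(13, 16, 32, 64))
  # single-shell dataset: halves of 13 b=0 + 32 directions
  ss <- subsampleSingleShell(ph$dwi, 1000)
  sps <- splitHalf(ss, seed = 7)
  expect_equal(as.integer(table(shellIds(gradients(sps@halfA)))), c(13, 32))

  # union of indices = parent, intersection empty, reconstruction bit-exact
  expect_length(intersect(sp@indicesA, sp@indicesB), 0)
  expect_setequal(c(sp@indicesA, sp@indicesB), seq_len(250))
  rec <- array(NA_real_, dim(dwiSignal(ph$dwi)))
  rec[, , , sp@indicesA] <- dwiSignal(sp@halfA)
  rec[, , , sp@indicesB] <- dwiSignal(sp@halfB)
  expect_identical(rec, dwiSignal(ph$dwi))

  # different seeds: different partitions, identical per-shell counts
  sp2 <- splitHalf(ph$dwi, seed = 8)
  expect_false(identical(sp@indicesA, sp2@indicesA))
  expect_equal(table(shellIds(gradients(sp@halfA))),
               table(shellIds(gradients(sp2@halfA))))

  # an odd shell gives its extra volume to half A
  gt3 <- gradientTable(c(0, 0, rep(1000, 3)),
                       cbind(0, 0, diag(3)[, c(1, 2, 3)]))
  dwi3 <- voxelDwi(matrix(runif(5), 1), gt3)
  sp3 <- splitHalf(dwi3, seed = 1)
  expect_equal(sum(shellIds(gradients(sp3@halfA)) > 0), 2)
  expect_equal(sum(shellIds(gradients(sp3@halfB)) > 0), 1)

  # a shell with one volume cannot be split
  gt1 <- gradientTable(c(0, 0, 1000), cbind(0, 0, c(1, 0, 0)))
  expect_error(splitHalf(voxelDwi(matrix(1, 1, 3), gt1), seed = 1),
               "single volume")
})

test_that("NDC is 1 for duplicated volumes, ~0 for noise, high for smooth phantoms", {
  gt <- fullGtab()
  dup <- gradientTable(rep(bvals(gt), each = 2),
                       bvecs(gt)[, rep(seq_len(250), each = 2)])
  nvox <- 200
  base <- withSeed(3, matrix(rexp(nvox * 250, 1 / 50), nvox))
  sig <- base[, rep(seq_len(250), each = 2)]
  expect_equal(neighboringDwiCorrelation(voxelDwi(sig, dup)), 1)

  # independent noise volumes decorrelate
  gtn <- gradientTable(c(0, rep(1000, 16)),
                       cbind(0, t(repulsionDirections(16))))
  noise <- withSeed(4, matrix(rnorm(1e4 * 17), 1e4))
  ndc <- neighboringDwiCorrelation(voxelDwi(noise, gtn))
  expect_lt(abs(ndc), 0.05)

  # smooth orientation-diverse phantom at SNR 30
  g <- c(14, 14, 10)
  spec <- phantomSpec(gridShape = g, bundles = list(
    defaultBundle(g, radius = 3.5),
    list(start = c(7, 1, 3), end = c(7, 14, 3), radius = 3.5,
         evals = c(1.7, 0.2, 0.2) * 1e-3),
    list(start = c(4, 4, 1), end = c(4, 4, 10), radius = 3.5,
         evals = c(1.7, 0.2, 0.2) * 1e-3),
    list(start = c(2, 12, 1), end = c(12, 2, 10), radius = 3.5,
         evals = c(1.7, 0.2, 0.2) * 1e-3)),
    ventricle = list(min = c(11, 1, 8), max = c(14, 4, 10)),
    snr = 30, seed = 5)
  dwi <- buildPhantom(spec, fullGtab())$dwi
  expect_gt(neighboringDwiCorrelation(dwi), 0.9)

  # invariant to global positive scaling
  s2 <- dwi; s2@signal <- dwi@signal * 3.7
  expect_equal(neighboringDwiCorrelation(s2),
               neighboringDwiCorrelation(dwi), tolerance = 1e-12)

  expect_error(neighboringDwiCorrelation(
    initialize(dwi, brainMask = array(FALSE, dim(dwi@signal)[1:3]))),
    "empty")
})

test_that("NDC exclusion flags subjects 2 SDs below the sample mean", {
  # a single outlier in a tight cluster falls below mean - 2 sd
  vals <- c(0.91, 0.90, 0.89, 0.92, 0.90, 0.91, 0.90, 0.89, 0.91, 0.30)
  expect_equal(excludeByNdc(vals), c(rep(TRUE, 9), FALSE))
  expect_true(all(excludeByNdc(rep(0.8, 6))))   # sd = 0 keeps everyone
  # direct evaluation of the mean - k*sd rule on random data
  x <- withSeed(9, rnorm(50, 0.85, 0.05))
  expect_equal(excludeByNdc(x, kSd = 1.5), x >= mean(x) - 1.5 * sd(x))
})
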