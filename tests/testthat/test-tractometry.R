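# Bundle selection, cleaning, resampling, density maps and profiles.

## a straight streamline along x at (y, z), from x0 to x1 (mm)
straightLine <- function(x0, x1, y, z, n = 20)
  unname(cbind(seq(x0, x1, length.out = n), y, z))

test_that("the tract vocabulary has 28 entries", {
  tt <- tractTable()
  expect_equal(nrow(tt), 28)
  expect_true(all(c("ATR_R", "CST_L", "Occipital") %in% tt$abbreviation))
})

test_that("ROI logic keeps, orients and drops streamlines correctly", {
  d3 <- c(20, 9, 9)
  aff <- diag(c(1, 1, 1, 1))  # 1 mm grid for easy reasoning
  roi <- function(xs) { m <- array(FALSE, d3); m[xs, , ] <- TRUE; m }
  tract <- new("TractDefinition", name = "demo", abbreviation = "DM",
               include = list(roi(2:3), roi(17:18)), exclude = list(roi(20)))
  through <- straightLine(0.5, 18, 5, 5)
  reversed <- through[nrow(through):1, ]
  short <- straightLine(0.5, 9, 5, 5)
  excluded <- straightLine(0.5, 19.5, 5, 5)
  b <- selectBundle(list(through, reversed, short, excluded), tract, aff)
  expect_equal(nStreamlines(b), 2)
  # the reversed streamline was flipped to match ROI order
  expect_lt(b@streamlines[[2]][1, 1], b@streamlines[[2]][nrow(reversed), 1])
})

test_that("exclusion ROIs separate crossing-phantom bundles", {
  g <- c(13, 13, 7)
  spec <- phantomSpec(gridShape = g, bundles = list(
    defaultBundle(g),
    list(start = c(7, 1, 4), end = c(7, 13, 4), radius = 2.4,
         evals = c(1.7, 0.2, 0.2) * 1e-3)), snr = Inf)
  ph <- buildPhantom(spec, fullGtab())
  trA <- phantomTractDefinition(ph$truth, bundleIdx = 1)
  expect_equal(length(trA@exclude), 1)
  # streamline running along bundle B must be rejected from bundle A
  mid <- (g[2] + 1) / 2 * 1.8
  alongB <- straightLine(7 * 1.8, 7 * 1.8, 5, 4 * 1.8)[, c(2, 1, 3)]
  alongB <- cbind(7 * 1.8, seq(2, 22, length.out = 15), 4 * 1.8)
  alongA <- cbind(seq(2, 22, length.out = 15), mid, 4 * 1.8)
  b <- selectBundle(list(alongA, alongB), trA, ph$dwi@affine)
  expect_equal(nStreamlines(b), 1)
})

test_that("cleaning removes only far outliers and honors its guards", {
  coh <- lapply(1:20, function(i) straightLine(0, 20, 5 + i * 0.01, 5))
  outlier <- straightLine(0, 20, 45, 5)
  b <- new("Bundle", name = "t", streamlines = c(coh, list(outlier)),
           removed = 0L, threshold = NA_real_)
  cb <- cleanBundle(b)
  expect_equal(cb@removed, 1L)
  expect_equal(nStreamlines(cb), 20)
  # identical streamlines: zero variance, nothing removed
  same <- new("Bundle", name = "t",
              streamlines = lapply(1:5, function(i) straightLine(0, 20, 5, 5)),
              removed = 0L, threshold = NA_real_)
  expect_equal(cleanBundle(same)@removed, 0L)
  # infinite threshold is the identity
  expect_equal(cleanBundle(b, sdThreshold = Inf)@removed, 0L)
  # tiny bundles are returned unchanged with a warning
  expect_warning(cleanBundle(new("Bundle", name = "t",
                                 streamlines = coh[1:2], removed = 0L,
                                 threshold = NA_real_)), "fewer than 3")
})

test_that("resampling is arc-length uniform and endpoint preserving", {
  s <- resampleStreamline(rbind(c(0, 0, 0), c(0, 0, 9)), 100)
  expect_equal(diff(s[, 3]), rep(9 / 99, 99))
  ends <- resampleStreamline(rbind(c(0, 0, 0), c(1, 2, 3)), 2)
  expect_equal(ends, rbind(c(0, 0, 0), c(1, 2, 3)))
  # arc length preserved within 1% for a smooth helix
  t <- seq(0, 4 * pi, length.out = 400)
  helix <- cbind(cos(t), sin(t), t / 4)
  arcLen <- function(m) sum(sqrt(rowSums(diff(m)^2)))
  expect_lt(abs(arcLen(resampleStreamline(helix, 100)) - arcLen(helix)) /
            arcLen(helix), 0.01)
  expect_error(resampleStreamline(rbind(c(1, 1, 1), c(1, 1, 1)), 10),
               "zero-length")
})

test_that("density maps count each streamline once per voxel", {
  d3 <- c(10, 5, 5)
  aff <- diag(4)
  one <- straightLine(0, 9, 2, 2)
  b1 <- new("Bundle", name = "t", streamlines = list(one), removed = 0L,
            threshold = NA_real_)
  dm <- tractDensityMap(b1, d3, aff)
  expect_true(all(dm@counts[, 3, 3] == 1))
  expect_equal(sum(dm@counts), 10)
  # duplicating streamlines doubles counts, leaves the normalized map fixed
  b2 <- new("Bundle", name = "t", streamlines = list(one, one), removed = 0L,
            threshold = NA_real_)
  expect_equal(tractDensityMap(b2, d3, aff)@counts, 2 * dm@counts)
  expect_equal(tractDensityMap(b2, d3, aff, normalize = TRUE)@counts,
               tractDensityMap(b1, d3, aff, normalize = TRUE)@counts)
  expect_equal(sum(tractDensityMap(b1, d3, aff, normalize = TRUE)@counts), 1)
})

test_that("profiles weight streamline nodes by distance to the median", {
  d3 <- c(20, 9, 9); aff <- diag(4)
  sls <- lapply(1:5, function(i) straightLine(0, 19, 4 + i * 0.1, 4))
  b <- new("Bundle", name = "t", streamlines = sls, removed = 0L,
           threshold = NA_real_)
  # constant map -> constant profile
  pc <- computeTractProfile(b, array(3.3, d3), aff)
  expect_equal(profileValues(pc), rep(3.3, 100))
  # single streamline: the profile is the map sampled along it
  step <- array(0, d3); step[11:20, , ] <- 1
  b1 <- new("Bundle", name = "t", streamlines = sls[1], removed = 0L,
            threshold = NA_real_)
  p1 <- computeTractProfile(b1, step, aff)
  expectAt <- as.numeric(round(seq(0, 19, length.out = 100)) + 1 >= 11)
  expect_equal(profileValues(p1), expectAt)
  # a scalar step at the bundle midpoint lands within +-2 nodes of truth
  ps <- computeTractProfile(b, step, aff)
  jump <- which(diff(profileValues(ps)) > 0.5)
  expect_length(jump, 1)
  expect_lte(abs(jump - 50.5), 2)  # step edge at x = 9.5 of 19 mm ~ node 50.5
  # reversal invariance via orientation normalization
  slsRev <- sls; slsRev[[3]] <- slsRev[[3]][nrow(slsRev[[3]]):1, ]
  bR <- new("Bundle", name = "t", streamlines = slsRev, removed = 0L,
            threshold = NA_real_)
  expect_equal(profileValues(computeTractProfile(bR, step, aff)),
               profileValues(ps))
  # empty bundle: NaN profile with a warning
  expect_warning(pe <- computeTractProfile(
    new("Bundle", name = "t", streamlines = list(), removed = 0L,
        threshold = NA_real_), step, aff), "empty")
  expect_true(all(is.nan(profileValues(pe))))
})

test_that("tck files round-trip streamlines", {
  sls <- list(straightLine(0, 10, 1, 2), straightLine(3, 7, 2, 1, n = 5))
  path <- tempfile(fileext = ".tck")
  writeTck(sls, path)
  back <- readTck(path)
  expect_equal(length(back), 2)
  expect_equal(back[[1]], sls[[1]], tolerance = 1e-6)
  expect_equal(back[[2]], sls[[2]], tolerance = 1e-6)
})
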