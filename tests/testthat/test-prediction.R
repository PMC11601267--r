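# Feature assembly, cross-validated ordinal prediction, cumulative ROC and
# DeLong's test.

test_that("feature assembly is deterministic bookkeeping with guards", {
  coh <- simulateCohort(12, seed = 2)
  fm <- assembleFeatures(coh$profiles)
  expect_equal(nrow(fm$x), 12)
  expect_equal(ncol(fm$x), 100)        # 1 tract x 1 metric x 100 nodes
  # constant columns are dropped
  prof2 <- coh$profiles
  prof2$value[prof2$node == 1] <- 0.5
  expect_equal(ncol(assembleFeatures(prof2)$x), 99)
  # missing profiles are reported
  expect_error(assembleFeatures(coh$profiles[-(1:10), ]), "missing profiles")
})

test_that("separable cohorts are predicted accurately, deterministically", {
  # effect of 25 noise-SDs per score step: classes fully separated in
  # feature space (the premise is checked: 1-NN recovers them exactly)
  coh <- simulateCohort(40, effectSize = 25, seed = 31)
  fm <- assembleFeatures(coh$profiles)
  d <- as.matrix(dist(fm$x)); diag(d) <- Inf
  expect_equal(mean(coh$scores$score[apply(d, 1, which.min)] ==
                    coh$scores$score), 1)
  rep1 <- crossvalPredict(fm, coh$scores$score, nFolds = 5, nRepeats = 3,
                          seed = 4)
  acc <- mean(rep1@predictions$predicted == rep1@predictions$truth)
  expect_gt(acc, 0.9)
  expect_gt(min(rep1@auc$auc), 0.95)
  rep2 <- crossvalPredict(fm, coh$scores$score, nFolds = 5, nRepeats = 3,
                          seed = 4)
  expect_identical(rep1@predictions, rep2@predictions)
  # classes smaller than the fold count are refused
  expect_error(crossvalPredict(fm, coh$scores$score, nFolds = 11),
               "fewer members")
})

test_that("no information leaks from test folds into training", {
  # perturbing one test-fold subject's features must not change any other
  # subject's prediction in the same repeat/fold structure
  coh <- simulateCohort(20, effectSize = 3, seed = 9)
  fm <- assembleFeatures(coh$profiles)
  r1 <- crossvalPredict(fm, coh$scores$score, nFolds = 4, nRepeats = 1,
                        seed = 11)
  victim <- fm$subjects[1]
  fm2 <- fm
  fm2$x[1, ] <- fm2$x[1, ] + 100
  r2 <- crossvalPredict(fm2, coh$scores$score, nFolds = 4, nRepeats = 1,
                        seed = 11)
  sameFold <- r1@predictions$fold[r1@predictions$subject == victim]
  others <- r1@predictions$subject != victim &
            r1@predictions$fold == sameFold
  expect_equal(r1@predictions$predicted[others],
               r2@predictions$predicted[others])
})

test_that("MAE and variance explained follow their definitions", {
  perfect <- data.frame(truth = c(2, 3, 4, 5), predicted = c(2, 3, 4, 5))
  expect_equal(scorePredictions(perfect), list(mae = 0, r2 = 1))
  hand <- data.frame(truth = c(2, 4), predicted = c(3, 4))
  expect_equal(scorePredictions(hand)$mae, 0.5)
  constant <- data.frame(truth = c(2, 3, 4, 5), predicted = rep(3.5, 4))
  expect_lte(scorePredictions(constant)$r2, 0)
})

test_that("cumulative ROC dichotomizes stepwise and matches Mann-Whitney", {
  # perfectly separated scores: AUC 1 at every cut
  sc <- rep(2:6, each = 4)
  pr <- matrix(0, 20, 5, dimnames = list(NULL, 2:6))
  pr[cbind(seq_len(20), sc - 1)] <- 1
  r <- cumulativeRoc(sc, pr)
  expect_equal(nrow(r$auc), 4)
  expect_true(all(r$auc$auc == 1))
  # the cut labels step the low bin upward
  expect_equal(r$auc$cut[1], "<=2 vs >2")
  expect_equal(r$auc$cut[4], "<=5 vs >5")

  # AUC equals the Mann-Whitney U statistic identity
  lab <- withSeed(12, rbinom(200, 1, 0.4) == 1)
  dec <- withSeed(13, rnorm(200) + lab)
  auc <- fwetract:::.rocCurve(lab, dec)$auc
  u <- unname(wilcox.test(dec[lab], dec[!lab])$statistic)
  expect_equal(auc, u / (sum(lab) * sum(!lab)), tolerance = 1e-12)
  # independent labels and scores: AUC near 0.5 (3 SE at n = 200)
  dec0 <- withSeed(14, rnorm(200))
  auc0 <- fwetract:::.rocCurve(lab, dec0)$auc
  n1 <- sum(lab); n0 <- sum(!lab)
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(auc0 - 0.5), 3 * se)
  # AUC is invariant under strictly monotone transforms
  expect_equal(fwetract:::.rocCurve(lab, exp(dec))$auc, auc)
})

test_that("DeLong's test matches a bootstrap oracle and pROC", {
  withSeed(15, {
    lab <- rep(c(TRUE, FALSE), c(14, 16))
    s1 <- rnorm(30) + 1.2 * lab
    s2 <- 0.6 * s1 + rnorm(30, sd = 0.8)
  })
  dt <- delongTest(lab, s1, s2)
  # identical models: delta 0, p 1
  same <- delongTest(lab, s1, s1)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
  # internal consistency: AUC equals the threshold-sweep AUC
  expect_equal(dt$auc1, fwetract:::.rocCurve(lab, s1)$auc, tolerance = 1e-10)
  # bootstrap oracle for the p-value (resample subjects, normal approx)
  aucOf <- function(l, s) {
    r <- rank(s)
    (sum(r[l]) - sum(l) * (sum(l) + 1) / 2) / (sum(l) * sum(!l))
  }
  deltas <- withSeed(16, vapply(seq_len(1e5), function(i) {
    idx <- sample.int(30, replace = TRUE)
    if (length(unique(lab[idx])) < 2) return(NA_real_)
    aucOf(lab[idx], s1[idx]) - aucOf(lab[idx], s2[idx])
  }, numeric(1)))
  deltas <- deltas[!is.na(deltas)]
  pBoot <- 2 * pnorm(-abs(dt$delta) / sd(deltas))
  expect_lt(abs(dt$p - pBoot), 0.02)
  # independent cross-check against pROC's DeLong implementation
  pr <- suppressMessages(pROC::roc.test(
    pROC::roc(lab, s1, quiet = TRUE), pROC::roc(lab, s2, quiet = TRUE),
    method = "delong", paired = TRUE))
  expect_equal(dt$p, unname(pr$p.value), tolerance = 1e-8)
  expect_error(delongTest(rep(TRUE, 5), rnorm(5), rnorm(5)), "non-empty")
})
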