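# Cross-validated ordinal severity prediction from tract profiles:
# feature assembly, repeated stratified 5-fold ridge-penalized multinomial
# logistic regression, MAE / variance explained, cumulative ROC curves and
# DeLong's test for correlated AUCs.

#' Assemble a subjects-by-features matrix from long-format tract profiles
#'
#' Columns are ordered deterministically by (tract, metric, node). Every
#' subject must carry every tract x metric profile; globally constant
#' columns are dropped (zero-variance guard). Standardization and PCA happen
#' later, inside each training fold (see \code{\link{crossvalPredict}}).
#'
#' @param profiles data.frame with columns subject, tract, metric, node, value
#' @param metrics metrics to include (default: all present)
#' @return list of class \code{FeatureMatrix}: \code{x} (matrix),
#'   \code{subjects}, \code{columns} (metadata data.frame)
#' @export
assembleFeatures <- function(profiles, metrics = NULL) {
  metrics <- metrics %||% sort(unique(profiles$metric))
  profiles <- profiles[profiles$metric %in% metrics, ]
  subjects <- sort(unique(profiles$subject))
  combos <- unique(profiles[, c("tract", "metric")])
  combos <- combos[order(combos$tract, combos$metric), ]
  nodes <- sort(unique(profiles$node))
  key <- with(profiles, paste(subject, tract, metric, node, sep = "\r"))
  lookup <- setNames(profiles$value, key)
  cols <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i)
    data.frame(tract = combos$tract[i], metric = combos$metric[i],
               node = nodes)))
  x <- matrix(NA_real_, length(subjects), nrow(cols),
              dimnames = list(subjects, paste(cols$tract, cols$metric,
                                              cols$node, sep = ".")))
  for (s in seq_along(subjects)) {
    k <- paste(subjects[s], cols$tract, cols$metric, cols$node, sep = "\r")
    x[s, ] <- lookup[k]
  }
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)
    stop("missing profiles for e.g. subject ", subjects[bad[1, 1]],
         ", feature ", colnames(x)[bad[1, 2]])
  }
  keep <- apply(x, 2, function(col) sd(col) > 0)
  structure(list(x = x[, keep, drop = FALSE], subjects = subjects,
                 columns = cols[keep, , drop = FALSE]),
            class = "FeatureMatrix")
}

## stratified fold assignment, deterministic under the active RNG
.stratifiedFolds <- function(y, nFolds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    members <- sample(which(y == cl))
    fold[members] <- rep_len(seq_len(nFolds), length(members))
  }
  fold
}

#' Repeated stratified cross-validated ordinal prediction
#'
#' Multiclass L2-penalized (ridge) logistic regression with class weights
#' inversely proportional to class frequencies. Within every outer training
#' fold the features are z-score standardized, projected on principal
#' components retaining 95\% of the variance (both fit on the training fold
#' only and applied to the test fold) and the penalty strength is tuned by
#' an internal 3-fold cross-validation. The outer stratified
#' \code{nFolds}-fold split is repeated \code{nRepeats} times. Deterministic
#' given \code{seed}.
#'
#' @param features a \code{FeatureMatrix} from \code{\link{assembleFeatures}}
#' @param scores per-subject integer scores, aligned with
#'   \code{features$subjects}
#' @param nFolds outer folds (default 5)
#' @param nRepeats outer repetitions (default 20)
#' @param seed integer seed
#' @param pcaVar variance fraction retained by the projection (default 0.95)
#' @return a \linkS4class{PredictionReport}
#' @export
crossvalPredict <- function(features, scores, nFolds = 5L, nRepeats = 20L,
                            seed = 1L, pcaVar = 0.95) {
  x <- features$x
  y <- as.integer(scores)
  stopifnot(nrow(x) == length(y))
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need >= 2 distinct classes")
  counts <- table(y)
  if (any(counts < nFolds))
    stop("class(es) with fewer members than folds: ",
         paste(names(counts)[counts < nFolds], collapse = ", "),
         "; merge classes or reduce nFolds")
  wClass <- length(y) / (length(classes) * counts)   # inverse frequency

  preds <- list()
  withSeed(seed, {
    for (r in seq_len(nRepeats)) {
      fold <- .stratifiedFolds(y, nFolds)
      for (fo in seq_len(nFolds)) {
        tr <- which(fold != fo); te <- which(fold == fo)
        mu <- colMeans(x[tr, , drop = FALSE])
        sdv <- apply(x[tr, , drop = FALSE], 2, sd)
        use <- sdv > 0
        xt <- sweep(sweep(x[tr, use, drop = FALSE], 2, mu[use]), 2, sdv[use], `/`)
        xe <- sweep(sweep(x[te, use, drop = FALSE], 2, mu[use]), 2, sdv[use], `/`)
        pc <- prcomp(xt, center = FALSE, scale. = FALSE)
        cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
        nComp <- max(2L, min(which(cum >= pcaVar)))
        nComp <- min(nComp, ncol(pc$rotation))
        zt <- xt %*% pc$rotation[, seq_len(nComp), drop = FALSE]
        ze <- xe %*% pc$rotation[, seq_len(nComp), drop = FALSE]
        if (ncol(zt) < 2) { zt <- cbind(zt, 0); ze <- cbind(ze, 0) }
        wTr <- as.numeric(wClass[as.character(y[tr])])
        yTr <- factor(y[tr], levels = classes)
        ## ridge path: glmnet's default path stops far above the optimum for
        ## well-separated data, so span 8 decades below lambda_max explicitly
        ## glmnet warns about small per-class counts on every internal fold;
        ## expected at this scale, so muffled
        init <- suppressWarnings(
          glmnet::glmnet(zt, yTr, family = "multinomial", alpha = 0,
                         weights = wTr, nlambda = 3))
        lambdaSeq <- max(init$lambda) * 10^seq(0, -8, length.out = 60)
        nInner <- min(3L, min(table(y[tr])))
        if (nInner >= 3) {
          innerFold <- .stratifiedFolds(y[tr], nInner)
          cvfit <- suppressWarnings(
            glmnet::cv.glmnet(zt, yTr, family = "multinomial",
                              alpha = 0, foldid = innerFold,
                              weights = wTr, lambda = lambdaSeq,
                              type.measure = "deviance"))
          lam <- cvfit$lambda.min
        } else {
          ## too few per class to tune: middle of the regularization grid
          cvfit <- suppressWarnings(
            glmnet::glmnet(zt, yTr, family = "multinomial",
                           alpha = 0, weights = wTr,
                           lambda = lambdaSeq))
          lam <- median(cvfit$lambda)
        }
        pr <- drop(predict(cvfit, ze, s = lam, type = "response"))
        if (is.null(dim(pr))) pr <- matrix(pr, nrow = length(te))
        colnames(pr) <- paste0("p", classes)
        predClass <- classes[max.col(pr, ties.method = "first")]
        df <- data.frame(repeatId = r, fold = fo,
                         subject = features$subjects[te],
                         truth = y[te], predicted = predClass)
        preds[[length(preds) + 1]] <- cbind(df, as.data.frame(pr,
                                                check.names = FALSE))
      }
    }
  })
  predictions <- do.call(rbind, preds)
  sc <- .scoreTable(predictions, classes)
  ## pooled class probabilities per subject for the ROC analyses
  probCols <- paste0("p", classes)
  agg <- aggregate(predictions[probCols],
                   by = list(subject = predictions$subject), FUN = mean)
  truthBySubject <- predictions$truth[match(agg$subject, predictions$subject)]
  probs <- as.matrix(agg[probCols])
  colnames(probs) <- as.character(classes)
  roc <- cumulativeRoc(truthBySubject, probs)
  new("PredictionReport", predictions = predictions,
      mae = sc$mae, r2 = sc$r2, roc = roc$roc, auc = roc$auc)
}

.scoreTable <- function(predictions, classes) {
  mae <- mean(abs(predictions$predicted - predictions$truth))
  ssRes <- sum((predictions$truth - predictions$predicted)^2)
  ssTot <- sum((predictions$truth - mean(predictions$truth))^2)
  list(mae = mae, r2 = 1 - ssRes / ssTot)
}

#' MAE and variance explained of a prediction report
#'
#' MAE is the mean absolute ordinal distance between predicted and true
#' class; R^2 is computed on the predicted class values
#' (1 - SS_res / SS_tot).
#'
#' @param report a \linkS4class{PredictionReport}, or a data.frame with
#'   columns \code{truth} and \code{predicted}
#' @return list with \code{mae} and \code{r2}
#' @export
scorePredictions <- function(report) {
  tab <- if (is(report, "PredictionReport")) report@predictions else report
  .scoreTable(tab, sort(unique(tab$truth)))
}

## ROC by threshold sweep; trapezoid AUC (ties contribute half)
.rocCurve <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  P <- sum(labels); N <- length(labels) - P
  tp <- cumsum(lab); fp <- cumsum(!lab)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)   # last point of each tie block
  tpr <- c(0, tp[keep] / P); fpr <- c(0, fp[keep] / N)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Cumulative dichotomization ROC analysis of ordinal predictions
#'
#' For each cut c over the ordered classes, subjects are binarized into
#' low = \{score <= c\} versus high = \{score > c\} (the low bin absorbing
#' one more class at each step); the decision score is the summed predicted
#' probability of the high bin. Cuts leaving an empty side are skipped with
#' a warning.
#'
#' @param scores per-subject true ordinal scores
#' @param classProb subjects x classes probability matrix, columns named by
#'   class values
#' @return list with \code{roc} (data.frame: cut, fpr, tpr) and \code{auc}
#'   (data.frame: cut, auc, nLow, nHigh)
#' @export
cumulativeRoc <- function(scores, classProb) {
  classes <- sort(as.numeric(colnames(classProb)))
  rocRows <- list(); aucRows <- list()
  for (c0 in classes[-length(classes)]) {
    high <- scores > c0
    if (!any(high) || all(high)) {
      warning(sprintf("cut at %g leaves an empty side; skipped", c0))
      next
    }
    dec <- rowSums(classProb[, as.character(classes[classes > c0]),
                             drop = FALSE])
    rc <- .rocCurve(high, dec)
    cutLab <- sprintf("<=%g vs >%g", c0, c0)
    rocRows[[length(rocRows) + 1]] <-
      data.frame(cut = cutLab, fpr = rc$fpr, tpr = rc$tpr)
    aucRows[[length(aucRows) + 1]] <-
      data.frame(cut = cutLab, auc = rc$auc,
                 nLow = sum(!high), nHigh = sum(high))
  }
  list(roc = do.call(rbind, rocRows) %||% data.frame(),
       auc = do.call(rbind, aucRows) %||% data.frame())
}

.midrank <- function(x) rank(x, ties.method = "average")

#' DeLong's test for two correlated AUCs
#'
#' Compares the AUCs of two decision-score vectors computed on the same
#' subjects, using midrank-based placement values and the DeLong covariance
#' construction; returns the normal-approximation two-sided p-value.
#'
#' @param labels logical (or 0/1) outcome per subject
#' @param scores1,scores2 decision scores of the two models
#' @return list with \code{auc1}, \code{auc2}, \code{delta}, \code{variance},
#'   \code{z}, \code{p}
#' @export
delongTest <- function(labels, scores1, scores2) {
  labels <- as.logical(labels)
  m <- sum(labels); n <- sum(!labels)
  if (m == 0 || n == 0) stop("both outcome groups must be non-empty")
  placements <- function(sc) {
    x <- sc[labels]; y <- sc[!labels]
    rAll <- .midrank(c(x, y)); rX <- .midrank(x); rY <- .midrank(y)
    auc <- (sum(rAll[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
    v10 <- (rAll[seq_len(m)] - rX) / n
    v01 <- 1 - (rAll[m + seq_len(n)] - rY) / m
    list(auc = auc, v10 = v10, v01 = v01)
  }
  p1 <- placements(scores1); p2 <- placements(scores2)
  s10 <- cov(cbind(p1$v10, p2$v10))
  s01 <- cov(cbind(p1$v01, p2$v01))
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
        (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- p1$auc - p2$auc
  if (vd <= 0) {
    z <- if (abs(delta) < 1e-12) 0 else sign(delta) * Inf
  } else z <- delta / sqrt(vd)
  list(auc1 = p1$auc, auc2 = p2$auc, delta = delta, variance = vd,
       z = z, p = if (is.infinite(z)) 0 else 2 * pnorm(-abs(z)))
}
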