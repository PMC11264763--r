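#' One-vs-rest confusion counts
#'
#' @param yTrue,yPred equal-length label vectors over \code{codebook}
#' @param codebook ordered class names
#' @return integer matrix, one row per class, columns TP, FP, FN, TN
#' @export
confusionCounts <- function(yTrue, yPred, codebook) {
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  if (length(yTrue) != length(yPred)) stop("label vectors differ in length")
  bad <- setdiff(unique(c(yTrue, yPred)), codebook)
  if (length(bad)) stop("label(s) outside the codebook: ",
                        paste(bad, collapse = ", "))
  out <- t(vapply(codebook, function(cls) {
    tp <- sum(yTrue == cls & yPred == cls)
    fp <- sum(yTrue != cls & yPred == cls)
    fn <- sum(yTrue == cls & yPred != cls)
    tn <- sum(yTrue != cls & yPred != cls)
    c(TP = tp, FP = fp, FN = fn, TN = tn)
  }, integer(4)))
  rownames(out) <- codebook
  out
}

#' The five evaluation metrics from confusion counts
#'
#' Per class (one-vs-rest) and macro-averaged:
#' ACC = (TP+TN)/(TP+TN+FP+FN), TPR = TP/(TP+FN), PPV = TP/(TP+FP),
#' SPC = TN/(TN+FP), DSC = 2TP/(2TP+FP+FN).  A zero denominator defines
#' the metric as 0 (with a warning).
#'
#' @param counts matrix from \code{\link{confusionCounts}}
#' @return list: \code{perClass} (matrix classes x 5), \code{macro}
#'   (named vector of the 5 macro-averages)
#' @export
classMetrics <- function(counts) {
  safe <- function(num, den) {
    if (den == 0) { warning("zero denominator; metric defined as 0"); 0 }
    else num / den
  }
  per <- t(apply(counts, 1L, function(r) {
    tp <- unname(r["TP"]); fp <- unname(r["FP"])
    fn <- unname(r["FN"]); tn <- unname(r["TN"])
    c(ACC = safe(tp + tn, tp + tn + fp + fn),
      TPR = safe(tp, tp + fn),
      PPV = safe(tp, tp + fp),
      SPC = safe(tn, tn + fp),
      DSC = safe(2 * tp, 2 * tp + fp + fn))
  }))
  list(perClass = per, macro = colMeans(per))
}

## stratified, group-aware fold assignment: all rows of one group stay in
## one fold; groups are dealt to folds round-robin within each class
groupFolds <- function(labels, groups, k) {
  gl <- tapply(labels, groups, function(v) v[1])
  gnames <- names(gl)
  fold <- integer(length(gnames)); names(fold) <- gnames
  for (cls in unique(gl)) {
    g <- gnames[gl == cls]
    if (length(g) < 1) next
    g <- g[sample.int(length(g))]
    fold[g] <- rep_len(sample.int(k), length(g))
  }
  fold[as.character(groups)]
}

#' Grouped, stratified k-fold cross-validation of the grading pipeline
#'
#' Folds are stratified by label and grouped by parent-image id, so ROIs of
#' one parent never straddle a train/test boundary.  Inside every training
#' fold the full downstream pipeline is refit from scratch: min-max
#' scaling, NMF at rank \code{nmfK}, and the three-model voting ensemble;
#' the held-out fold is projected with the frozen scaler and basis.
#'
#' @param table a labeled \linkS4class{FeatureTable} (unscaled features)
#' @param k number of folds (default 10)
#' @param nmfK factorization rank (default 32)
#' @param seed RNG seed (controls fold assignment and all refits)
#' @param nmfIter NMF iteration budget per fold
#' @param svmArgs,flmArgs,treeArgs passed to the base trainers
#' @return list: \code{macro} (5 macro metrics of the pooled predictions),
#'   \code{perClass}, \code{perFold} (fold x metric matrix), \code{folds}
#'   (fold id per row), \code{predictions} (pooled data.frame incl. the
#'   three base votes), \code{auc} (one-vs-rest AUC per class),
#'   \code{accuracy} (plain pooled accuracy) and \code{baseAccuracy}
#'   (pooled accuracy of each base model alone)
#' @export
kfoldCv <- function(table, k = 10L, nmfK = 32L, seed = 0, nmfIter = 300L,
                    svmArgs = list(), flmArgs = list(), treeArgs = list()) {
  stopifnot(is(table, "FeatureTable"), length(table@labels) > 0)
  X <- table@values
  y <- table@labels
  groups <- if (length(table@parentId)) table@parentId
            else sprintf("row%d", seq_len(nrow(X)))
  if (k > min(table(tapply(y, groups, function(v) v[1]))))
    stop("k exceeds the group count of the smallest class")
  codebook <- unique(y)
  folds <- withSeed(seed, groupFolds(y, groups, k))
  pred <- character(nrow(X))
  baseVotes <- matrix(NA_character_, nrow(X), 3L,
                      dimnames = list(NULL, c("rbfSvm", "fastLargeMargin",
                                              "randomTree")))
  scores <- matrix(NA_real_, nrow(X), length(codebook),
                   dimnames = list(NULL, codebook))
  perFold <- matrix(NA_real_, k, 5L,
                    dimnames = list(NULL, c("ACC", "TPR", "PPV", "SPC", "DSC")))
  for (f in seq_len(k)) {
    tr <- folds != f
    sc <- fitMinMax(X[tr, , drop = FALSE])
    Xtr <- applyMinMax(X[tr, , drop = FALSE], sc)
    Xte <- applyMinMax(X[!tr, , drop = FALSE], sc)
    basis <- nmfFit(Xtr, k = nmfK, maxIter = nmfIter, seed = seed + f)
    Wtr <- basis@W
    Wte <- nmfTransform(basis, Xte)
    ens <- ensembleFit(Wtr, y[tr], seed = seed + 100L * f,
                       svmArgs = svmArgs, flmArgs = flmArgs,
                       treeArgs = treeArgs)
    pr <- ensemblePredict(ens, Wte)
    pred[!tr] <- pr$label
    baseVotes[!tr, ] <- as.matrix(pr[, colnames(baseVotes)])
    scores[!tr, ] <- as.matrix(pr[, paste0("score.", codebook)])
    perFold[f, ] <- classMetrics(confusionCounts(y[!tr], pr$label,
                                                 codebook))$macro
  }
  m <- classMetrics(confusionCounts(y, pred, codebook))
  auc <- vapply(codebook, function(cls)
    rocAuc(scores[, cls], y == cls), numeric(1))
  baseAccuracy <- colMeans(baseVotes == y)
  list(macro = m$macro, perClass = m$perClass, perFold = perFold,
       folds = folds, auc = auc, accuracy = mean(pred == y),
       baseAccuracy = baseAccuracy,
       predictions = data.frame(label = y, predicted = pred, fold = folds,
                                baseVotes, stringsAsFactors = FALSE))
}

#' Grouped, stratified holdout split
#'
#' Assigns whole groups to the test side, per class, until the requested
#' test fraction is reached as closely as group integrity allows.
#'
#' @param labels label per row
#' @param groups parent-image id per row (defaults to one group per row)
#' @param testFraction fraction of rows for testing (default 0.40)
#' @param seed RNG seed
#' @return list of integer row indices: \code{train}, \code{test}
#' @export
holdoutSplit <- function(labels, groups = NULL, testFraction = 0.40,
                         seed = 0) {
  labels <- as.character(labels)
  n <- length(labels)
  if (is.null(groups)) groups <- sprintf("row%d", seq_len(n))
  groups <- as.character(groups)
  gl <- tapply(labels, groups, function(v) v[1])
  withSeed(seed, {
    testGroups <- character()
    for (cls in unique(gl)) {
      g <- names(gl)[gl == cls]
      g <- g[sample.int(length(g))]
      sizes <- cumsum(vapply(g, function(gr) sum(groups == gr), integer(1)))
      want <- round(testFraction * sum(labels == cls))
      take <- which.min(abs(sizes - want))
      if (sizes[take] > 0 && want > 0) testGroups <- c(testGroups, g[seq_len(take)])
    }
    test <- which(groups %in% testGroups)
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' One-vs-rest AUC by the rank (Mann-Whitney) formula
#'
#' Trapezoidal area under the ROC curve with midrank handling of tied
#' scores: AUC = (R+ - n+(n+ + 1)/2) / (n+ n-) where R+ is the rank sum of
#' the positive scores.
#'
#' @param scores numeric scores, larger = more positive
#' @param positive logical (or 0/1) truth per score
#' @return AUC in [0, 1]
#' @export
rocAuc <- function(scores, positive) {
  positive <- as.logical(positive)
  nPos <- sum(positive); nNeg <- sum(!positive)
  if (nPos == 0 || nNeg == 0)
    stop("AUC undefined: need both positive and negative truths")
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}
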