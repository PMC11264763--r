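## stratified fold assignment for plain rows; returns integer fold id per row
stratifiedFolds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Train an RBF-kernel support vector machine with an inner grid search
#'
#' Soft-margin SVM with kernel \code{k(x, x') = exp(-gamma ||x - x'||^2)}
#' and one-vs-one multiclass handling.  The (C, gamma) point is chosen by
#' inner stratified cross-validation accuracy; ties prefer the smaller C,
#' then the smaller gamma.  Default grids: gamma in {1e-5, 1e-4, 1e-3} and
#' C in {0.1, 1, 10, 100, 1000, 10000}.
#'
#' @param X numeric matrix (rows x features)
#' @param y character/factor labels (>= 2 classes)
#' @param cGrid,gammaGrid hyper-parameter grids
#' @param cvFolds inner folds (default 3)
#' @param seed RNG seed for the inner fold assignment
#' @return a fitted model of class \code{rbfSvm} (list: \code{fit},
#'   \code{C}, \code{gamma}, \code{codebook})
#' @export
trainRbfSvm <- function(X, y, cGrid = c(0.1, 1, 10, 100, 1000, 10000),
                        gammaGrid = c(1e-5, 1e-4, 1e-3), cvFolds = 3L,
                        seed = 0) {
  y <- as.character(y)
  codebook <- unique(y)
  if (length(codebook) < 2L) stop("need at least two classes")
  grid <- expand.grid(C = cGrid, gamma = gammaGrid)
  withSeed(seed, {
    folds <- stratifiedFolds(y, cvFolds)
    acc <- vapply(seq_len(nrow(grid)), function(g) {
      ok <- 0L; n <- 0L
      for (f in seq_len(cvFolds)) {
        tr <- folds != f
        if (length(unique(y[tr])) < 2L) next
        fit <- e1071::svm(X[tr, , drop = FALSE], factor(y[tr], codebook),
                          kernel = "radial", cost = grid$C[g],
                          gamma = grid$gamma[g], scale = FALSE)
        pred <- as.character(predict(fit, X[!tr, , drop = FALSE]))
        ok <- ok + sum(pred == y[!tr]); n <- n + sum(!tr)
      }
      if (n) ok / n else 0
    }, numeric(1))
    best <- order(-acc, grid$C, grid$gamma)[1]
    fit <- e1071::svm(X, factor(y, codebook), kernel = "radial",
                      cost = grid$C[best], gamma = grid$gamma[best],
                      scale = FALSE)
    structure(list(fit = fit, C = grid$C[best], gamma = grid$gamma[best],
                   codebook = codebook, innerAccuracy = acc[best]),
              class = "rbfSvm")
  })
}

#' @export
predict.rbfSvm <- function(object, newdata, ...) {
  as.character(predict(object$fit, as.matrix(newdata)))
}

# per-class vote share of the one-vs-one SVM decision values, used as a
# continuous score for ROC analysis
svmClassScores <- function(model, newdata) {
  pr <- predict(model$fit, as.matrix(newdata), decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  cb <- model$codebook
  scores <- matrix(0, nrow(dv), length(cb), dimnames = list(NULL, cb))
  pairs <- strsplit(colnames(dv), "/", fixed = TRUE)
  for (p in seq_along(pairs)) {
    a <- pairs[[p]][1]; b <- pairs[[p]][2]
    scores[, a] <- scores[, a] + (dv[, p] > 0)
    scores[, b] <- scores[, b] + (dv[, p] <= 0)
  }
  scores / max(length(pairs), 1L)
}

# hinge-loss objective tau(w, b) = ||w||^2 / 2 + C sum max(0, 1 - y f(x))
flmObjective <- function(w, b, X, yy, C) {
  sum(w^2) / 2 + C * sum(pmax(0, 1 - yy * (X %*% w + b)))
}

# monotone batch solver for one binary large-margin problem: full-batch
# subgradient direction with a halving line search that only accepts
# objective decreases, so the per-epoch objective trace is non-increasing
flmSolveBinary <- function(X, yy, C, maxIter, tol) {
  p <- ncol(X)
  w <- numeric(p); b <- 0
  obj <- flmObjective(w, b, X, yy, C)
  trace <- obj
  step0 <- 1 / (C * nrow(X) + 1)
  for (it in seq_len(maxIter)) {
    viol <- as.vector(yy * (X %*% w + b)) < 1
    gw <- w - C * colSums(X[viol, , drop = FALSE] * yy[viol])
    gb <- -C * sum(yy[viol])
    step <- step0 * 64
    accepted <- FALSE
    for (h in 1:40) {
      w2 <- w - step * gw; b2 <- b - step * gb
      o2 <- flmObjective(w2, b2, X, yy, C)
      if (o2 < obj) { w <- w2; b <- b2; accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) break
    if ((obj - o2) / max(obj, 1e-12) < tol) { obj <- o2; trace <- c(trace, o2); break }
    obj <- o2
    trace <- c(trace, obj)
  }
  list(w = w, b = b, objective = obj, trace = trace)
}

#' Train the fast large-margin linear classifier
#'
#' Linear classifier minimizing the soft-margin objective
#' \code{||w||^2 / 2 + C sum delta_i} with hinge slack, by a monotone
#' batch solver with early stopping on relative objective change.
#' Multiclass is one-vs-rest; per-sample margins \code{y f(x)} are exposed
#' for diagnostics.
#'
#' @param X numeric matrix
#' @param y labels (>= 2 classes)
#' @param C soft-margin penalty (default 10)
#' @param maxIter maximum epochs per binary problem (default 300)
#' @param tol relative objective-change stopping threshold
#' @param seed unused (the solver is deterministic); kept for interface
#'   symmetry with the other base learners
#' @return model of class \code{fastLargeMargin}
#' @export
trainFastLargeMargin <- function(X, y, C = 10, maxIter = 300L, tol = 1e-8,
                                 seed = 0) {
  X <- as.matrix(X)
  y <- as.character(y)
  codebook <- unique(y)
  if (length(codebook) < 2L) stop("need at least two classes")
  fits <- lapply(codebook, function(cls) {
    yy <- ifelse(y == cls, 1, -1)
    flmSolveBinary(X, yy, C, maxIter, tol)
  })
  names(fits) <- codebook
  structure(list(fits = fits, codebook = codebook, C = C), class = "fastLargeMargin")
}

#' @export
predict.fastLargeMargin <- function(object, newdata, ...) {
  sc <- flmScores(object, newdata)
  object$codebook[max.col(sc, ties.method = "first")]
}

flmScores <- function(object, newdata) {
  X <- as.matrix(newdata)
  vapply(object$fits, function(f) as.vector(X %*% f$w + f$b),
         numeric(nrow(X)))
}

#' Margins of a fast large-margin model on a dataset
#'
#' Per-sample margin \code{rho = y f(x)} of the one-vs-rest problem for
#' each sample's true class.
#'
#' @param object a \code{fastLargeMargin} model
#' @param X data matrix
#' @param y true labels
#' @return numeric vector of margins
#' @export
flmMargins <- function(object, X, y) {
  sc <- flmScores(object, X)
  y <- as.character(y)
  vapply(seq_along(y), function(i) sc[i, y[i]], numeric(1))
}

shannonEntropy <- function(y) {
  p <- table(y) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# best threshold split of one feature by information gain
bestSplitOn <- function(x, y, parentE) {
  ux <- sort(unique(x))
  if (length(ux) < 2L) return(NULL)
  cuts <- (ux[-1] + ux[-length(ux)]) / 2
  if (length(cuts) > 32L)
    cuts <- stats::quantile(x, probs = seq(0.02, 0.98, length.out = 32L),
                            names = FALSE, type = 7)
  best <- NULL
  for (ct in unique(cuts)) {
    l <- x <= ct
    nl <- sum(l); nr <- length(x) - nl
    if (!nl || !nr) next
    ig <- parentE - (nl * shannonEntropy(y[l]) +
                     nr * shannonEntropy(y[!l])) / length(x)
    if (is.null(best) || ig > best$ig + 1e-12) best <- list(cut = ct, ig = ig)
  }
  best
}

growTree <- function(X, y, depth, maxDepth, mtry, minSplit, codebook) {
  counts <- table(factor(y, codebook))
  pred <- codebook[which.max(counts)]
  if (depth >= maxDepth || length(y) < minSplit ||
      length(unique(y)) == 1L)
    return(list(leaf = TRUE, pred = pred))
  parentE <- shannonEntropy(y)
  feats <- sample.int(ncol(X), min(mtry, ncol(X)))
  best <- NULL
  for (f in feats) {
    s <- bestSplitOn(X[, f], y, parentE)
    if (!is.null(s) && (is.null(best) || s$ig > best$ig + 1e-12))
      best <- c(s, feature = f)
  }
  if (is.null(best) || best$ig <= 1e-12)
    return(list(leaf = TRUE, pred = pred))
  l <- X[, best$feature] <= best$cut
  list(leaf = FALSE, feature = best$feature, cut = best$cut, ig = best$ig,
       left = growTree(X[l, , drop = FALSE], y[l], depth + 1L, maxDepth,
                       mtry, minSplit, codebook),
       right = growTree(X[!l, , drop = FALSE], y[!l], depth + 1L, maxDepth,
                        mtry, minSplit, codebook))
}

#' Train a random decision tree
#'
#' Single binary tree: at each node a random feature subset is drawn and
#' the split maximizing the information gain (parent entropy minus the
#' weighted mean child entropy, in bits) is taken; splits with no gain are
#' rejected and leaves predict the majority class.  Deterministic given
#' \code{seed}.  A single-class y yields a depth-0 tree predicting that
#' class.
#'
#' @param X numeric matrix
#' @param y labels
#' @param maxDepth maximum depth (default 12)
#' @param mtry features tried per node (default ceiling(p/2): a single
#'   randomized tree, unlike a forest member, has no averaging to absorb
#'   the variance of very small subsets)
#' @param minSplit minimum node size to attempt a split (default 2)
#' @param seed RNG seed
#' @return model of class \code{randomTree}
#' @export
trainRandomTree <- function(X, y, maxDepth = 12L, mtry = NULL, minSplit = 2L,
                            seed = 0) {
  X <- as.matrix(X)
  y <- as.character(y)
  codebook <- unique(y)
  if (is.null(mtry)) mtry <- max(1L, ceiling(ncol(X) / 2))
  root <- withSeed(seed,
    growTree(X, y, 0L, as.integer(maxDepth), as.integer(mtry),
             as.integer(minSplit), codebook))
  structure(list(root = root, codebook = codebook), class = "randomTree")
}

predictTreeRow <- function(node, x) {
  while (!node$leaf) node <- if (x[node$feature] <= node$cut) node$left else node$right
  node$pred
}

#' @export
predict.randomTree <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  vapply(seq_len(nrow(X)), function(i) predictTreeRow(object$root, X[i, ]),
         character(1))
}

#' Majority vote over an ordered triple of base-model labels
#'
#' Returns the modal label; a three-way tie falls back to the first base
#' model's vote (the RBF-SVM in the fixed ensemble order).
#'
#' @param votes character vector of 3 labels (or a matrix, rows = samples)
#' @return the winning label(s)
#' @export
majorityVote <- function(votes) {
  if (is.matrix(votes))
    return(apply(votes, 1L, majorityVote))
  counts <- table(votes)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) top else votes[1L]
}

#' Fit the hybrid voting ensemble
#'
#' Trains the RBF-SVM, the fast large-margin linear classifier and the
#' random decision tree on identical rows, in that fixed order; prediction
#' is the row-wise majority vote with ties resolved in favour of the
#' RBF-SVM.
#'
#' @param X numeric matrix (reduced features)
#' @param y labels
#' @param seed RNG seed (sub-seeds are derived per base model)
#' @param svmArgs,flmArgs,treeArgs extra arguments for the base trainers
#' @return a \linkS4class{TrainedEnsemble}
#' @export
ensembleFit <- function(X, y, seed = 0, svmArgs = list(), flmArgs = list(),
                        treeArgs = list()) {
  X <- as.matrix(X)
  y <- as.character(y)
  codebook <- unique(y)
  svm <- do.call(trainRbfSvm, c(list(X = X, y = y, seed = seed + 1L), svmArgs))
  flm <- do.call(trainFastLargeMargin,
                 c(list(X = X, y = y, seed = seed + 2L), flmArgs))
  tree <- do.call(trainRandomTree,
                  c(list(X = X, y = y, seed = seed + 3L), treeArgs))
  new("TrainedEnsemble",
      models = list(rbfSvm = svm, fastLargeMargin = flm, randomTree = tree),
      codebook = codebook,
      hyper = list(svm = list(C = svm$C, gamma = svm$gamma),
                   flm = list(C = flm$C), tree = list()))
}

#' Predict with the voting ensemble
#'
#' @param model a \linkS4class{TrainedEnsemble}
#' @param X numeric matrix
#' @return data.frame with the three base votes, the majority label and
#'   per-class scores (vote fractions averaged with the SVM's one-vs-one
#'   vote shares, for ROC analysis)
#' @export
ensemblePredict <- function(model, X) {
  stopifnot(is(model, "TrainedEnsemble"))
  X <- as.matrix(X)
  votes <- cbind(rbfSvm = predict(model@models$rbfSvm, X),
                 fastLargeMargin = predict(model@models$fastLargeMargin, X),
                 randomTree = predict(model@models$randomTree, X))
  final <- majorityVote(votes)
  cb <- model@codebook
  voteFrac <- vapply(cb, function(cl) rowMeans(votes == cl),
                     numeric(nrow(votes)))
  if (nrow(X) == 1L) voteFrac <- matrix(voteFrac, 1L,
                                        dimnames = list(NULL, cb))
  svmSc <- svmClassScores(model@models$rbfSvm, X)[, cb, drop = FALSE]
  scores <- (voteFrac + svmSc) / 2
  out <- data.frame(votes, label = final, stringsAsFactors = FALSE)
  colnames(scores) <- paste0("score.", cb)
  cbind(out, as.data.frame(voteFrac + 0)[, cb, drop = FALSE] |>
          stats::setNames(paste0("vote.", cb)), as.data.frame(scores))
}
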