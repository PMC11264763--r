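#' Fit min-max scaling statistics on a feature matrix
#'
#' @param X numeric matrix (rows = samples)
#' @return list with \code{min} and \code{max} per column
#' @export
fitMinMax <- function(X) {
  list(min = apply(X, 2L, min), max = apply(X, 2L, max))
}

#' Apply frozen min-max scaling statistics
#'
#' Columns are mapped to [0, 1] with the supplied (training-fold)
#' statistics; values outside the training range are clipped, and constant
#' training columns map to 0.
#'
#' @param X numeric matrix
#' @param stats output of \code{\link{fitMinMax}}
#' @return scaled matrix
#' @export
applyMinMax <- function(X, stats) {
  rng <- stats$max - stats$min
  rng[rng <= 0] <- 1
  Y <- sweep(sweep(X, 2L, stats$min), 2L, rng, "/")
  pmin(pmax(Y, 0), 1)
}

#' Fuse feature blocks into one non-negative table
#'
#' Column-binds the named blocks in the order given and min-max scales
#' every column to [0, 1].  Scaling statistics are fit on the fused matrix
#' unless frozen training statistics are supplied, and are returned so the
#' identical transform can be reapplied to held-out rows (non-negativity is
#' required downstream by the matrix factorization).
#'
#' @param blocks named list of numeric matrices with equal row counts, or
#'   of \linkS4class{FeatureTable}s
#' @param labels optional row labels for the fused table
#' @param parentId optional parent ids for the fused table
#' @param stats optional frozen scaling statistics
#' @return list: \code{table} (a \linkS4class{FeatureTable}, block-prefixed
#'   column names), \code{stats} (the scaling statistics used)
#' @export
fuseFeatures <- function(blocks, labels = character(), parentId = character(),
                         stats = NULL) {
  stopifnot(length(blocks) >= 1L, !is.null(names(blocks)))
  mats <- lapply(names(blocks), function(nm) {
    b <- blocks[[nm]]
    m <- if (is(b, "FeatureTable")) b@values else as.matrix(b)
    colnames(m) <- sprintf("%s.%s", nm, colnames(m))
    m
  })
  nr <- vapply(mats, nrow, integer(1))
  if (length(unique(nr)) != 1L)
    stop("row mismatch across blocks: ",
         paste(sprintf("%s=%d", names(blocks), nr), collapse = ", "))
  X <- do.call(cbind, mats)
  if (is.null(stats)) stats <- fitMinMax(X)
  list(table = FeatureTable(applyMinMax(X, stats), labels = labels,
                            parentId = parentId),
       stats = stats)
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimizes the Frobenius norm of X - W H over non-negative W, H with the
#' standard multiplicative update rules, starting from seeded uniform
#' random factors scaled by \code{sqrt(mean(X)/k)}.  The per-iteration
#' error trace is recorded and is non-increasing; iteration stops at
#' \code{maxIter} or when the relative error change falls below \code{tol}.
#'
#' @param X non-negative numeric matrix or \linkS4class{FeatureTable}
#'   (samples x features)
#' @param k factorization rank (default 32), \code{k < min(dim(X))}
#' @param maxIter maximum iterations (default 500)
#' @param tol relative error-change stopping threshold (default 1e-4)
#' @param seed RNG seed for the initialization
#' @return a \linkS4class{ReducedBasis}
#' @export
nmfFit <- function(X, k = 32L, maxIter = 500L, tol = 1e-4, seed = 0) {
  if (is(X, "FeatureTable")) X <- X@values
  X <- as.matrix(X)
  if (any(X < 0)) stop("X must be non-negative")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  n <- nrow(X); p <- ncol(X)
  eps <- 1e-12
  withSeed(seed, {
    sc <- sqrt(max(mean(X), eps) / k)
    W <- matrix(stats::runif(n * k), n, k) * sc
    H <- matrix(stats::runif(k * p), k, p) * sc
    err <- numeric(maxIter)
    prev <- Inf
    it <- 0L
    while (it < maxIter) {
      it <- it + 1L
      H <- H * (crossprod(W, X) / (crossprod(W, W) %*% H + eps))
      W <- W * (X %*% t(H) / (W %*% tcrossprod(H, H) + eps))
      err[it] <- sqrt(sum((X - W %*% H)^2))
      if (is.finite(prev) && prev > 0 &&
          abs(prev - err[it]) / prev < tol) break
      prev <- err[it]
    }
    new("ReducedBasis", W = W, H = H, k = k, fitError = err[it],
        errorTrace = err[seq_len(it)],
        featureNames = colnames(X) %||% character())
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Project new rows onto a fitted factorization
#'
#' Non-negative least-squares solve of min ||x - w H||_F over w >= 0 with H
#' frozen, by multiplicative updates on w.
#'
#' @param basis a \linkS4class{ReducedBasis}
#' @param xNew numeric matrix (rows x features), features matching the
#'   fitted table
#' @param maxIter,tol solver controls
#' @return non-negative matrix, rows x k
#' @export
nmfTransform <- function(basis, xNew, maxIter = 500L, tol = 1e-6) {
  stopifnot(is(basis, "ReducedBasis"))
  xNew <- as.matrix(xNew)
  if (ncol(xNew) != ncol(basis@H))
    stop("xNew width (", ncol(xNew), ") must match the basis (",
         ncol(basis@H), ")")
  if (any(xNew < 0)) stop("xNew must be non-negative")
  H <- basis@H
  eps <- 1e-12
  HHt <- tcrossprod(H, H)
  W <- matrix(mean(xNew) / max(basis@k, 1) + eps, nrow(xNew), basis@k)
  prev <- Inf
  for (it in seq_len(maxIter)) {
    W <- W * (xNew %*% t(H) / (W %*% HHt + eps))
    e <- sqrt(sum((xNew - W %*% H)^2))
    if (is.finite(prev) && prev > 0 && abs(prev - e) / prev < tol) break
    prev <- e
  }
  W
}

#' Sweep the factorization rank against downstream accuracy
#'
#' For each k in the grid, runs grouped, stratified k-fold cross-validation
#' of the full downstream pipeline (scaling, NMF at rank k, the voting
#' ensemble) and records the macro-averaged accuracy.
#'
#' @param table a labeled \linkS4class{FeatureTable}
#' @param kGrid ranks to evaluate (even values 2..100 by default)
#' @param cvFolds folds (default 5)
#' @param seed RNG seed
#' @param ... passed to \code{\link{kfoldCv}}
#' @return list: \code{table} (data.frame k, accuracy), \code{bestK}
#' @export
sweepK <- function(table, kGrid = seq(2L, 100L, by = 2L), cvFolds = 5L,
                   seed = 0, ...) {
  stopifnot(is(table, "FeatureTable"), length(table@labels) > 0)
  acc <- vapply(kGrid, function(k) {
    rep <- kfoldCv(table, k = cvFolds, nmfK = k, seed = seed, ...)
    rep$macro["ACC"]
  }, numeric(1))
  res <- data.frame(k = kGrid, accuracy = acc)
  list(table = res, bestK = kGrid[which.max(acc)])
}
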