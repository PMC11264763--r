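test_that("RBF-SVM separates simple clusters and honours the kernel contract", {
  set.seed(21)
  X <- matrix(c(rnorm(20, -3, 0.3), rnorm(20, 3, 0.3)), ncol = 1)
  y <- rep(c("lo", "hi"), each = 20)
  fit <- trainRbfSvm(X, y, cGrid = c(1, 100), gammaGrid = c(0.01, 1),
                     cvFolds = 2L, seed = 1)
  expect_identical(predict(fit, X), y)

  # kernel at zero distance is exp(0) = 1: a point is its own neighbor
  expect_equal(exp(-fit$gamma * sum((X[1, ] - X[1, ])^2)), 1)

  # kernel matrix is symmetric PSD on a random sample
  set.seed(22)
  Z <- matrix(rnorm(30), 10, 3)
  K <- exp(-0.5 * as.matrix(stats::dist(Z))^2)
  expect_equal(K, t(K))
  expect_true(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) >
                -1e-8)
  expect_error(trainRbfSvm(X, rep("one", 40)), "two classes")
})

test_that("the XOR layout is solved like a reference RBF machine", {
  X <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c("a", "a", "b", "b")
  fit <- e1071::svm(X, factor(y), kernel = "radial", gamma = 1, cost = 1000,
                    scale = FALSE)
  expect_identical(as.character(predict(fit, X)), y)
  ours <- trainRbfSvm(rbind(X, X, X), rep(y, 3), cGrid = 1000, gammaGrid = 1,
                      cvFolds = 2L, seed = 2)
  expect_identical(predict(ours, X), y)
})

test_that("fast large margin attains positive margins and a monotone objective", {
  set.seed(23)
  X <- rbind(matrix(rnorm(40, -2, 0.4), ncol = 2),
             matrix(rnorm(40, 2, 0.4), ncol = 2))
  y <- rep(c("neg", "pos"), each = 20)
  fit <- trainFastLargeMargin(X, y, C = 10)
  expect_true(all(flmMargins(fit, X, y) > 0))       # separable: rho > 0
  for (f in fit$fits)
    expect_true(all(diff(f$trace) <= 0))            # objective non-increasing

  # analytic two-point problem: w -> 1, b -> 0 at large C
  X2 <- matrix(c(-1, 1), 2, 1)
  fit2 <- trainFastLargeMargin(X2, c("n", "p"), C = 1000, maxIter = 5000L,
                               tol = 1e-12)
  f <- fit2$fits[["p"]]
  expect_equal(unname(f$w), 1, tolerance = 0.05)
  expect_equal(f$b, 0, tolerance = 0.05)
})

test_that("random tree splits maximize information gain deterministically", {
  # perfect split: IG = 1 bit on a balanced two-class node
  X <- matrix(c(1, 2, 3, 4, 11, 12, 13, 14), ncol = 1)
  y <- rep(c("a", "b"), each = 4)
  fit <- trainRandomTree(X, y, seed = 1)
  expect_false(fit$root$leaf)
  expect_equal(fit$root$ig, 1)
  expect_identical(predict(fit, X), y)

  # pure node never splits
  pure <- trainRandomTree(X, rep("a", 8), seed = 1)
  expect_true(pure$root$leaf)
  expect_identical(predict(pure, X), rep("a", 8))

  # uninformative feature (children mirror the parent): no split accepted
  Xu <- matrix(rep(c(0, 1), 6), ncol = 1)
  yu <- rep(c("a", "b"), each = 6)
  fitu <- trainRandomTree(Xu, yu, seed = 2)
  expect_true(fitu$root$leaf)

  set.seed(24)
  Xr <- matrix(rnorm(200), 50, 4); yr <- sample(c("a", "b"), 50, TRUE)
  t1 <- trainRandomTree(Xr, yr, seed = 5)
  t2 <- trainRandomTree(Xr, yr, seed = 5)
  expect_identical(predict(t1, Xr), predict(t2, Xr))
})

test_that("majority vote equals the exhaustive mode-with-tie-break oracle", {
  expect_identical(majorityVote(c("A", "A", "B")), "A")
  expect_identical(majorityVote(c("A", "B", "C")), "A")   # tie -> first model
  labs <- c("a", "b", "c")
  triples <- expand.grid(m1 = labs, m2 = labs, m3 = labs,
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(triples))) {
    v <- unlist(triples[i, ])
    expect_identical(unname(majorityVote(v)), unname(oracleMajority(v)))
  }
  # matrix form is row-wise
  m <- rbind(c("a", "a", "b"), c("c", "b", "b"))
  expect_identical(majorityVote(m), c("a", "b"))
})

test_that("the ensemble trains three models and votes deterministically", {
  set.seed(25)
  X <- rbind(matrix(rnorm(60, 0, 0.5), ncol = 2),
             matrix(rnorm(60, 3, 0.5), ncol = 2),
             cbind(rnorm(30, 0, 0.5), rnorm(30, 3, 0.5)))
  y <- rep(c("u", "v", "w"), each = 30)
  ens <- ensembleFit(X, y, seed = 7, svmArgs = list(cGrid = c(1, 100),
                                                    gammaGrid = c(0.1, 1)))
  expect_s4_class(ens, "TrainedEnsemble")
  pr <- ensemblePredict(ens, X)
  expect_true(mean(pr$label == y) > 0.95)
  # vote fractions are a distribution over the codebook
  vf <- as.matrix(pr[, paste0("vote.", ens@codebook)])
  expect_equal(unname(rowSums(vf)), rep(1, nrow(X)))
  # unanimous rows carry full vote fraction
  unan <- pr$rbfSvm == pr$fastLargeMargin & pr$rbfSvm == pr$randomTree
  expect_true(all(apply(vf[unan, ], 1, max) == 1))

  ens2 <- ensembleFit(X, y, seed = 7, svmArgs = list(cGrid = c(1, 100),
                                                     gammaGrid = c(0.1, 1)))
  expect_identical(ensemblePredict(ens2, X), pr)

  # when at least two models agree on every row, the ensemble is at least
  # as accurate as the weakest base model
  base <- vapply(c("rbfSvm", "fastLargeMargin", "randomTree"),
                 function(m) mean(pr[[m]] == y), numeric(1))
  agree2 <- apply(pr[, 1:3], 1, function(v) max(table(v)) >= 2)
  if (all(agree2)) expect_gte(mean(pr$label == y), min(base))
})
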