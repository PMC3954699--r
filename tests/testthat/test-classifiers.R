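mkTrain <- function(X, y) SiteTrainingSet(X, y)

test_that("fitBins places equal-width edges and handles degenerate features", {
  # uniform grid on [0,10]: edges at 2,4,6,8
  X <- matrix(seq(0, 10, length.out = 101), nrow = 1,
              dimnames = list("f1", NULL))
  edges <- fitBins(X)
  expect_equal(drop(edges), c(2, 4, 6, 8), tolerance = 1e-12)

  # constant feature: everything lands in one bin
  Xc <- matrix(3, nrow = 1, ncol = 10, dimnames = list("c", NULL))
  ec <- fitBins(Xc)
  bins <- 1L + rowSums(outer(c(3, 3, 3), drop(ec), ">="))
  expect_true(length(unique(bins)) == 1L)

  # out-of-range values clamp into the edge bins
  e <- fitBins(X)
  expect_equal(1L + sum(-5 >= drop(e)), 1L)
  expect_equal(1L + sum(50 >= drop(e)), 5L)
})

test_that("nbFit separates a 1-feature toy and respects the prior", {
  X <- matrix(c(runif(100, 0, 1), runif(100, 9, 10)), nrow = 1,
              dimnames = list("f1", NULL))
  y <- rep(c("positive", "negative"), each = 100)
  m <- nbFit(mkTrain(X, y), priorPositive = 0.5)
  p0 <- predictProba(m, 0.5)
  expect_gte(p0[["positive"]], 0.99)
  p4 <- predictProba(m, 9.5)
  expect_lte(p4[["positive"]], 0.01)

  # identical class distributions: posterior equals the prior exactly
  Xs <- matrix(rep(c(1, 2, 3, 4), 2), nrow = 1, dimnames = list("f1", NULL))
  ys <- rep(c("positive", "negative"), each = 4)
  msym <- nbFit(mkTrain(Xs, ys), priorPositive = 0.5)
  expect_equal(predictProba(msym, 2.5)[["positive"]], 0.5, tolerance = 1e-12)
  m3 <- nbFit(mkTrain(Xs, ys), priorPositive = 0.3)
  expect_equal(predictProba(m3, 2.5)[["positive"]], 0.3, tolerance = 1e-12)

  # raising P strictly increases p_positive for a fixed example
  priors <- c(0.05, 0.2, 0.5, 0.8, 0.95)
  ps <- vapply(priors, function(P)
    predictProba(nbFit(mkTrain(X, y), P), 5)[["positive"]], numeric(1))
  expect_true(all(diff(ps) > 0))

  expect_error(nbFit(mkTrain(X, rep("positive", 200)), 0.5), "both classes")
})

test_that("nb posterior equals the brute-force Bayes oracle", {
  set.seed(41)
  for (trial in 1:20) {
    nf <- sample(1:3, 1)
    n <- sample(c(10, 30), 1)
    X <- matrix(sample(0:4, nf * n, replace = TRUE) + rnorm(nf * n, 0, .01),
                nrow = nf, dimnames = list(paste0("f", 1:nf), NULL))
    y <- sample(c("positive", "negative"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    P <- runif(1, 0.1, 0.9)
    m <- nbFit(mkTrain(X, y), priorPositive = P)
    xNew <- X[, sample(n, 1)]
    got <- predictProba(m, xNew)[["positive"]]
    want <- nbOracle(X, y, xNew, P)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("the log-space posterior survives 480 small likelihoods", {
  # every observed per-feature likelihood ~ 1e-3 in BOTH classes: the
  # direct product underflows double precision (1e-1440 in numerator and
  # denominator) yet the posterior must come back as exactly the prior
  nf <- 480L
  edges <- matrix(rep(c(1, 2, 3, 4), nf), nrow = nf, byrow = TRUE)
  ll <- matrix(log(c(1e-3, rep((1 - 1e-3) / 4, 4))), nrow = nf,
               ncol = 5, byrow = TRUE)
  m <- new("NBModel", edges = edges, logLikPos = ll, logLikNeg = ll,
           priorPositive = 0.3, featureNames = paste0("f", 1:nf))
  p <- predictProba(m, rep(0.5, nf))  # all features in bin 1
  expect_equal(p[["positive"]], 0.3, tolerance = 1e-12)
  # sanity: the naive product path would be 0/0
  expect_identical((1e-3)^480, 0)
})

test_that("nb decision flips as the prior crosses the tie point", {
  X <- matrix(c(0, 0, 1, 10, 10, 9), nrow = 1, dimnames = list("f", NULL))
  y <- c(rep("positive", 3), rep("negative", 3))
  xq <- 5  # middle bin, sparse for both classes
  pLow <- predictProba(nbFit(mkTrain(X, y), 0.05), xq)[["positive"]]
  pHigh <- predictProba(nbFit(mkTrain(X, y), 0.95), xq)[["positive"]]
  expect_lt(pLow, 0.5)
  expect_gt(pHigh, 0.5)
})

test_that("svmFit learns separable data with calibrated probabilities", {
  set.seed(42)
  ts <- makeGaussianSites(60, 60, dim = 2, dPrime = 8, seed = 5)
  m <- svmFit(ts, cost = 1, seed = 1)
  X <- t(featureMatrix(ts))
  pred <- predictProba(m, X)[, "positive"] >= 0.5
  expect_equal(mean(pred == (exampleLabels(ts) == "positive")), 1)

  # probabilities are monotone in the decision value
  dec <- svmDecision(m, X)
  p <- predictProba(m, X)[, "positive"]
  expect_true(all(diff(p[order(dec)]) >= 0))

  # far on the positive side -> confident probability
  far <- matrix(4 / sqrt(2), nrow = 1, ncol = 2)
  expect_gt(predictProba(m, far)[, "positive"], 0.9)

  expect_error(svmFit(ts, cost = -1), "positive")
})

test_that("svm probabilities match the solver's own prediction path", {
  ts <- makeGaussianSites(40, 80, dim = 6, dPrime = 4, seed = 9)
  X <- t(featureMatrix(ts))
  y <- factor(exampleLabels(ts), levels = c("negative", "positive"))
  ctr <- colMeans(X); scl <- apply(X, 2, sd)
  Xs <- scale(X, ctr, scl)
  set.seed(1)
  ref <- e1071::svm(Xs, y, kernel = "linear", cost = 2, scale = FALSE,
                    probability = TRUE)
  refP <- attr(predict(ref, Xs, probability = TRUE),
               "probabilities")[, "positive"]
  m <- svmFit(ts, cost = 2, seed = 1)
  got <- predictProba(m, X)[, "positive"]
  expect_equal(unname(got), unname(refP), tolerance = 1e-9)
})

test_that("label-flip symmetry holds within calibration tolerance", {
  ts <- makeGaussianSites(50, 50, dim = 4, dPrime = 5, seed = 13)
  flipped <- SiteTrainingSet(
    featureMatrix(ts),
    ifelse(exampleLabels(ts) == "positive", "negative", "positive"))
  m1 <- svmFit(ts, cost = 1, seed = 3)
  m2 <- svmFit(flipped, cost = 1, seed = 3)
  X <- t(featureMatrix(ts))
  p1 <- predictProba(m1, X)[, "positive"]
  p2 <- predictProba(m2, X)[, "negative"]
  expect_equal(unname(p1), unname(p2), tolerance = 0.05)
})

test_that("training-order permutation does not change either classifier", {
  ts <- makeGaussianSites(30, 60, dim = 5, dPrime = 4, seed = 17)
  perm <- sample(90)
  tsPerm <- SiteTrainingSet(featureMatrix(ts)[, perm],
                            exampleLabels(ts)[perm])
  X <- t(featureMatrix(ts))
  pNB1 <- predictProba(nbFit(ts, 0.3), X)[, "positive"]
  pNB2 <- predictProba(nbFit(tsPerm, 0.3), X)[, "positive"]
  expect_equal(pNB1, pNB2, tolerance = 1e-12)
  mS1 <- svmFit(ts, 1, seed = 2); mS2 <- svmFit(tsPerm, 1, seed = 2)
  # the margin solution is order-invariant up to the solver's convergence
  # tolerance; the calibration's internal CV partitions depend on data
  # order, so probabilities agree approximately
  expect_equal(svmDecision(mS1, X), svmDecision(mS2, X), tolerance = 1e-2)
  pS1 <- predictProba(mS1, X)[, "positive"]
  pS2 <- predictProba(mS2, X)[, "positive"]
  expect_equal(pS1, pS2, tolerance = 0.02)
})

test_that("hinge violations shrink as C grows on a fixed overlapping toy", {
  ts <- makeGaussianSites(40, 40, dim = 2, dPrime = 1.5, seed = 23)
  X <- t(featureMatrix(ts))
  yNum <- ifelse(exampleLabels(ts) == "positive", 1, -1)
  viol <- vapply(c(0.01, 1, 100), function(C) {
    m <- svmFit(ts, cost = C, seed = 1)
    dec <- svmDecision(m, X)
    sum(pmax(0, 1 - yNum * dec))   # total hinge loss at unit margin
  }, numeric(1))
  expect_true(all(diff(viol) <= 1e-8))
})
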