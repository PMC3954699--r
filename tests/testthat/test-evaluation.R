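test_that("stratified folds partition each class within one example", {
  y <- rep(c("positive", "negative"), c(10, 10))
  f <- stratifiedFolds(y, F = 5, seed = 1)
  expect_equal(sort(unique(f)), 1:5)
  tab <- table(f, y)
  expect_true(all(tab == 2L))  # exact divisibility: 2 + 2 per fold

  # heavy imbalance: pigeonhole on the +/-1 rule
  y2 <- rep(c("positive", "negative"), c(7, 5000))
  f2 <- stratifiedFolds(y2, F = 5, seed = 3)
  tab2 <- table(f2, y2)
  expect_true(all(tab2[, "positive"] %in% c(1L, 2L)))
  expect_true(all(tab2[, "negative"] == 1000L))

  # determinism and seed sensitivity
  expect_identical(f2, stratifiedFolds(y2, F = 5, seed = 3))
  expect_false(identical(f2, stratifiedFolds(y2, F = 5, seed = 4)))

  expect_error(stratifiedFolds(rep(c("positive", "negative"), c(3, 100)),
                               F = 5), "at least F")
})

test_that("cross-validation predicts each example exactly once, out of fold", {
  ts <- makeGaussianSites(20, 40, dim = 4, dPrime = 6, seed = 7)
  pred <- crossValidate(ts, "nb", param = 0.5, F = 5, seed = 2)
  expect_equal(sort(pred$example), 1:60)        # bijection with examples
  expect_false(anyNA(pred$pPositive))
  # fold column matches the assignment that trained without that example
  f <- stratifiedFolds(exampleLabels(ts), F = 5, seed = 2)
  expect_equal(pred$fold, f)

  # fully separable data: recall 1 at the achievable 99%-precision point
  op <- selectThreshold(pred, target = 0.99)
  expect_equal(op$recall, 1)
})

test_that("pr curve matches the brute-force confusion oracle", {
  set.seed(51)
  for (trial in 1:25) {
    n <- sample(20:60, 1)
    pred <- data.frame(
      label = sample(c("positive", "negative"), n, replace = TRUE,
                     prob = c(.4, .6)),
      pPositive = round(runif(n), 2))   # force score ties
    if (length(unique(pred$label)) < 2) next
    curve <- prCurve(pred)
    # one point per distinct probability plus the all-negative point
    expect_equal(nrow(curve), length(unique(pred$pPositive)) + 1L)
    for (i in seq_len(nrow(curve))) {
      want <- confusionOracle(pred$label, pred$pPositive,
                              curve$threshold[i])
      expect_equal(unlist(curve[i, c("tp", "fp", "fn", "tn")]),
                   want[c("tp", "fp", "fn", "tn")],
                   ignore_attr = TRUE)
    }
    # totals and monotonicity
    expect_true(all(curve$tp + curve$fn == sum(pred$label == "positive")))
    expect_true(all(curve$fp + curve$tn == sum(pred$label == "negative")))
    expect_true(all(diff(curve$recall[order(curve$threshold)]) <= 0 |
                    is.na(diff(curve$recall))))
  }
})

test_that("perfect separation yields a precision-1, recall-1 point", {
  pred <- makeScoredSet(data.frame(count = c(10, 10),
                                   label = c("positive", "negative"),
                                   score = c(0.9, 0.1)))
  curve <- prCurve(pred)
  expect_true(any(curve$precision == 1 & curve$recall == 1, na.rm = TRUE))
})

test_that("threshold selection picks the closest achievable precision", {
  # achievable precisions include exactly 0.99 -> that point wins
  pred <- makeScoredSet(data.frame(
    count = c(99, 1, 900), label = c("positive", "negative", "negative"),
    score = c(0.98, 0.98, 0.1)))
  op <- selectThreshold(pred, target = 0.99)
  expect_equal(op$precision, 0.99)
  expect_equal(op$tp, 99); expect_equal(op$fp, 1)

  # nearest achievable precisions {0.98, 1.00} vs target 0.99:
  # equidistant tie broken toward precision >= target
  pred2 <- makeScoredSet(data.frame(
    count = c(49, 49, 2, 100),
    label = c("positive", "positive", "negative", "negative"),
    score = c(0.9, 0.8, 0.8, 0.1)))
  curve2 <- prCurve(pred2)
  expect_true(all(c(1, 0.98) %in% round(curve2$precision, 10)))
  op2 <- selectThreshold(pred2, target = 0.99)
  expect_equal(op2$precision, 1)

  # returned point is at least as close as every curve point (exhaustive)
  set.seed(52)
  for (trial in 1:20) {
    n <- sample(30:80, 1)
    pr <- data.frame(label = sample(c("positive", "negative"), n, TRUE),
                     pPositive = round(runif(n), 2))
    if (length(unique(pr$label)) < 2) next
    opX <- selectThreshold(pr, target = 0.99)
    curveX <- prCurve(pr)
    dBest <- abs(opX$precision - 0.99)
    dAll <- abs(curveX$precision - 0.99)
    expect_true(all(dBest <= dAll[!is.na(dAll)] + 1e-12))
  }
})

test_that("grid search maximizes recall at the target precision", {
  ts <- makeGaussianSites(25, 100, dim = 6, dPrime = 5, seed = 19)
  gs <- gridSearch(ts, "nb", grid = c(0.2, 0.5), targetPrecision = 0.99,
                   seed = 4)
  expect_true(gs$param %in% c(0.2, 0.5))
  expect_equal(nrow(gs$summary), 2L)
  # single-value grid returns that value
  gs1 <- gridSearch(ts, "nb", grid = 0.4, seed = 4)
  expect_equal(gs1$param, 0.4)
  expect_error(gridSearch(ts, "nb", grid = numeric(0)), "empty")

  # an underfit cost loses to a workable cost: two parallel stripes
  # (y = x +/- 1) are separable by y - x, but at C = 1e-5 the fit
  # degenerates toward the class-mean direction, which misranks badly
  set.seed(20)
  n <- 40
  x <- runif(2 * n, -10, 10)
  yy <- x + rep(c(1, -1), each = n) + rnorm(2 * n, 0, 0.05)
  ts2 <- SiteTrainingSet(rbind(f1 = x, f2 = yy),
                         rep(c("positive", "negative"), each = n))
  gs2 <- gridSearch(ts2, "svm", grid = c(1e-5, 1), seed = 5)
  expect_equal(gs2$param, 1)
})

test_that("grid-search ties break toward the smaller parameter", {
  # fully separable for both priors -> equal recall 1; smaller wins
  ts <- makeGaussianSites(20, 40, dim = 3, dPrime = 10, seed = 21)
  gs <- gridSearch(ts, "nb", grid = c(0.3, 0.6), seed = 6)
  expect_equal(gs$param, 0.3)
})

test_that("the Wilson interval matches its closed form and shrinks with n", {
  z <- qnorm(0.975)
  wilson <- function(k, n) {
    ph <- k / n
    c((ph + z^2 / (2 * n) - z * sqrt(ph * (1 - ph) / n +
        z^2 / (4 * n^2))) / (1 + z^2 / n),
      (ph + z^2 / (2 * n) + z * sqrt(ph * (1 - ph) / n +
        z^2 / (4 * n^2))) / (1 + z^2 / n))
  }
  ci <- recallCI(50, 100)
  expect_equal(unname(ci), wilson(50, 100), tolerance = 1e-9)
  expect_equal(unname(recallCI(7, 19)), wilson(7, 19), tolerance = 1e-9)
  # k = n: upper bound is 1
  expect_equal(recallCI(20, 20)[["upper"]], 1)
  expect_gte(recallCI(0, 5)[["lower"]], 0)
  # same proportion, larger n -> narrower
  w1 <- diff(recallCI(5, 10)); w2 <- diff(recallCI(50, 100))
  expect_lt(w2, w1)
  # agreement with the base-R Wilson implementation (no continuity corr.)
  pt <- prop.test(37, 61, correct = FALSE)$conf.int
  expect_equal(unname(recallCI(37, 61)), as.numeric(pt), tolerance = 1e-9)
  expect_error(recallCI(3, 0), "n >= 1")
})

test_that("mapped confusion scores domain predictions against site truth", {
  mapping <- list(ASP_PROTEASE = c("PF00026", "PF00077"),
                  ZINC_PROTEASE = character())
  ex <- data.frame(label = c("positive", "positive", "negative",
                             "negative"))
  ex$domains <- list(c("PF00026"), c("PF99999"), character(),
                     c("PF00077", "PF12345"))
  out <- mappedConfusion(ex, mapping, "ASP_PROTEASE")
  # hand-computed: TP=1 (PF00026), FN=1, TN=1 (empty), FP=1 (PF00077)
  expect_equal(out$tp, 1L); expect_equal(out$fn, 1L)
  expect_equal(out$fp, 1L); expect_equal(out$tn, 1L)
  expect_equal(out$precision, 0.5)
  expect_equal(out$recall, 0.5)
  # unmapped site is unscorable
  expect_error(mappedConfusion(ex, mapping, "ZINC_PROTEASE"), "unscorable")
  expect_error(mappedConfusion(ex, mapping, "NOPE"), "unscorable")
})
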