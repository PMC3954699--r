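#' Fit the calibrated linear maximum-margin classifier
#'
#' Trains a soft-margin linear SVM (libsvm via \pkg{e1071}) on standardized
#' features with probability calibration (the Platt/Wu sigmoid extension as
#' implemented by the solver), then extracts the complete parameter set —
#' weight vector, offset, calibration coefficients and scaling statistics —
#' into a self-contained [SVMModel-class] whose predictions are pure linear
#' algebra.
#'
#' @param train a [SiteTrainingSet-class] containing both classes.
#' @param cost the cost parameter C (> 0); larger values fit the training
#'   data harder at the expense of generalization.
#' @param seed integer seed governing the calibration's internal
#'   cross-validation.
#' @return An [SVMModel-class].
#' @export
svmFit <- function(train, cost = 1, seed = 1L) {
  if (cost <= 0) stop("cost must be positive")
  y <- factor(train@labels, levels = c("negative", "positive"))
  if (nlevels(droplevels(y)) < 2L)
    stop("both classes must be present in the training set")
  X <- t(train@features)                      # examples x features
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1        # constant features pass through
  Xs <- scale(X, center = ctr, scale = scl)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old), add = TRUE)
  set.seed(seed)
  fit <- e1071::svm(Xs, y, kernel = "linear", cost = cost, scale = FALSE,
                    probability = TRUE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  firstLabel <- fit$levels[fit$labels[1]]
  new("SVMModel", w = unname(w), rho = fit$rho, probA = fit$probA,
      probB = fit$probB, positiveFirst = firstLabel == "positive",
      center = unname(ctr), scale = unname(scl), cost = cost,
      featureNames = rownames(train@features))
}

#' Decision values of the linear SVM
#'
#' `w . x_scaled - rho`, oriented toward the positive class.
#'
#' @param model an [SVMModel-class].
#' @param x numeric vector or examples-by-features matrix.
#' @return numeric vector of decision values.
#' @export
svmDecision <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(model@w))
    stop(sprintf("expected %d features, got %d", length(model@w), ncol(x)))
  Xs <- sweep(sweep(x, 2, model@center), 2, model@scale, "/")
  dec <- drop(Xs %*% model@w) - model@rho
  if (model@positiveFirst) dec else -dec
}

#' @describeIn predictProba calibrated sigmoid posterior from the linear
#'   SVM decision value.
#' @export
setMethod("predictProba", "SVMModel", function(model, x) {
  single <- is.null(dim(x))
  if (single) x <- matrix(x, nrow = 1L)
  dec <- svmDecision(model, x)
  decFirst <- if (model@positiveFirst) dec else -dec
  pFirst <- 1 / (1 + exp(model@probA * decFirst + model@probB))
  pPos <- if (model@positiveFirst) pFirst else 1 - pFirst
  out <- cbind(positive = pPos, negative = 1 - pPos)
  if (single) out[1, ] else out
})
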