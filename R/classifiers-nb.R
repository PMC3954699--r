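#' Fit per-feature histogram bins
#'
#' Equal-width bins spanning the pooled training range of each feature.
#' The returned inner edges map a value to bin `1 + sum(x >= edges)`, so
#' test values outside the training range clamp into the outer bins.
#' A constant feature gets a degenerate scheme whose middle bin catches the
#' constant, flanked by bins that stay empty in training.
#'
#' @param values numeric matrix, features x examples.
#' @param nBins number of bins (default 5).
#' @return numeric matrix features x (nBins - 1) of strictly increasing
#'   inner edges.
#' @export
fitBins <- function(values, nBins = 5L) {
  stopifnot(nBins >= 2L)
  nf <- nrow(values)
  edges <- matrix(NA_real_, nrow = nf, ncol = nBins - 1L,
                  dimnames = list(rownames(values), NULL))
  for (f in seq_len(nf)) {
    v <- values[f, ]
    v <- v[is.finite(v)]
    if (!length(v))
      stop("feature has no finite training values: ",
           rownames(values)[f] %||% f)
    lo <- min(v); hi <- max(v)
    if (hi > lo) {
      edges[f, ] <- lo + (hi - lo) * seq_len(nBins - 1L) / nBins
    } else {
      # constant feature: catch-all middle bin flanked by empty bins
      half <- floor((nBins - 1L) / 2L)
      eps <- max(abs(lo), 1) * 1e-6
      edges[f, ] <- lo + eps * (seq_len(nBins - 1L) - half - 0.5)
    }
  }
  edges
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# values (features x examples) -> integer bins (features x examples)
.binOf <- function(edges, values) {
  nb <- ncol(edges) + 1L
  out <- matrix(1L, nrow = nrow(values), ncol = ncol(values))
  for (k in seq_len(ncol(edges)))
    out <- out + (values >= edges[, k])
  out[out > nb] <- nb
  out
}

#' Fit the binned naive Bayes model
#'
#' Class-conditional per-feature bin probabilities with Laplace (+1)
#' smoothing; the positive-class prior is the supplied tunable parameter
#' `P`, not the empirical class rate.
#'
#' @param train a [SiteTrainingSet-class] containing both classes.
#' @param priorPositive the prior P, strictly in (0,1).
#' @param nBins number of histogram bins (default 5).
#' @return An [NBModel-class].
#' @export
nbFit <- function(train, priorPositive = 0.5, nBins = 5L) {
  stopifnot(priorPositive > 0, priorPositive < 1)
  y <- train@labels
  if (length(unique(y)) < 2L)
    stop("both classes must be present in the training set")
  X <- train@features
  edges <- fitBins(X, nBins)
  bins <- .binOf(edges, X)
  countBins <- function(cls) {
    B <- bins[, y == cls, drop = FALSE]
    cnt <- matrix(0, nrow = nrow(X), ncol = nBins)
    for (b in seq_len(nBins)) cnt[, b] <- rowSums(B == b)
    cnt
  }
  smooth <- function(cnt) log((cnt + 1) / (rowSums(cnt) + nBins))
  new("NBModel", edges = edges,
      logLikPos = smooth(countBins("positive")),
      logLikNeg = smooth(countBins("negative")),
      priorPositive = priorPositive,
      featureNames = rownames(X))
}

#' Naive Bayes posterior for feature vectors
#'
#' Combines the class-conditional bin likelihoods with the tunable prior by
#' Bayes' theorem, in log space:
#' `p_pos = P * prod(f(x|+)) / (P * prod(f(x|+)) + (1-P) * prod(f(x|-)))`.
#'
#' @param model an [NBModel-class].
#' @param x numeric vector of length `nrow(edges)`, or a matrix with one
#'   example per row.
#' @return named numeric `c(positive=, negative=)`, or a two-column matrix
#'   for matrix input.
#' @export
nbPosterior <- function(model, x) {
  single <- is.null(dim(x))
  if (single) x <- matrix(x, nrow = 1L)
  if (ncol(x) != nrow(model@edges))
    stop(sprintf("expected %d features, got %d", nrow(model@edges),
                 ncol(x)))
  bins <- .binOf(model@edges, t(x))          # features x examples
  idx <- cbind(rep(seq_len(nrow(bins)), ncol(bins)), as.vector(bins))
  llp <- colSums(matrix(model@logLikPos[idx], nrow = nrow(bins)))
  lln <- colSums(matrix(model@logLikNeg[idx], nrow = nrow(bins)))
  a <- log(model@priorPositive) + llp
  b <- log1p(-model@priorPositive) + lln
  pPos <- 1 / (1 + exp(b - a))
  out <- cbind(positive = pPos, negative = 1 - pPos)
  if (single) out[1, ] else out
}

#' @describeIn predictProba posterior from the binned naive Bayes model.
#' @export
setMethod("predictProba", "NBModel", function(model, x) nbPosterior(model, x))
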