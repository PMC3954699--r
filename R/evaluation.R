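#' Stratified fold assignment
#'
#' Random, seed-reproducible partition into `F` folds in which the per-fold
#' counts of each class differ by at most one, preserving the class ratio —
#' essential at the ~1:100 imbalance these training sets have.
#'
#' @param labels character vector of example labels.
#' @param F number of folds (default 5).
#' @param seed integer seed.
#' @return integer vector of fold ids in `1:F`, one per example.
#' @export
stratifiedFolds <- function(labels, F = 5L, seed = 1L) {
  counts <- table(labels)
  if (any(counts < F))
    stop(sprintf("every class needs at least F = %d examples (have %s)",
                 F, paste(names(counts), counts, sep = "=",
                          collapse = ", ")))
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old), add = TRUE)
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in names(counts)) {
    idx <- sample(which(labels == cls))
    # deal round-robin, starting the deal at a random fold
    fold[idx] <- 1L + (sample.int(F, 1L) + seq_along(idx) - 1L) %% F
  }
  fold
}

#' Pooled cross-validation predictions (single continuous experiment)
#'
#' For each fold, a classifier is trained on the remaining folds with the
#' given top-level parameter and predicts the held-out fold; the held-out
#' posteriors from all folds are pooled and evaluated together as one
#' experiment (no per-fold recalibration).
#'
#' @param train a [SiteTrainingSet-class].
#' @param classifier "nb" or "svm".
#' @param param the top-level parameter: prior P for "nb", cost C for "svm".
#' @param F number of folds (default 5).
#' @param seed integer seed for the fold assignment (and, for the SVM, the
#'   per-fold calibration).
#' @return data.frame with one row per training example: `example` (column
#'   index into the set), `label`, `pPositive`, `fold`; the parameter value
#'   is attached as `attr(, "param")`.
#' @export
crossValidate <- function(train, classifier = c("nb", "svm"), param,
                          F = 5L, seed = 1L) {
  classifier <- match.arg(classifier)
  y <- train@labels
  fold <- stratifiedFolds(y, F = F, seed = seed)
  n <- length(y)
  pPos <- rep(NA_real_, n)
  for (i in seq_len(F)) {
    hold <- fold == i
    sub <- new("SiteTrainingSet",
               features = train@features[, !hold, drop = FALSE],
               labels = y[!hold],
               provenance = train@provenance[!hold, , drop = FALSE],
               catalogVersion = train@catalogVersion, seed = train@seed)
    model <- tryCatch(
      if (classifier == "nb") nbFit(sub, priorPositive = param)
      else svmFit(sub, cost = param, seed = seed + i),
      error = function(e)
        stop(sprintf("classifier failed on fold %d: %s", i,
                     conditionMessage(e))))
    pPos[hold] <- predictProba(model,
                               t(train@features[, hold, drop = FALSE]))[,
                               "positive"]
  }
  out <- data.frame(example = seq_len(n), label = y, pPositive = pPos,
                    fold = fold, stringsAsFactors = FALSE)
  attr(out, "param") <- param
  out
}

#' Precision-recall operating points of pooled predictions
#'
#' One operating point per distinct predicted probability (threshold = that
#' probability; an example is called positive when `pPositive >= threshold`)
#' plus the trivial all-negative point (threshold `Inf`, zero calls).
#'
#' @param pred data.frame with columns `label`, `pPositive` (as returned by
#'   [crossValidate] or [makeScoredSet]).
#' @return data.frame of operating points: threshold, precision (NA when no
#'   calls), recall, tp, fp, fn, tn.
#' @export
prCurve <- function(pred) {
  stopifnot(all(c("label", "pPositive") %in% names(pred)))
  y <- pred$label == "positive"
  if (!any(y) || all(y))
    stop("both labels must be present")
  p <- pred$pPositive
  ord <- order(p, decreasing = TRUE)
  ps <- p[ord]; ys <- y[ord]
  nPos <- sum(y); nNeg <- sum(!y)
  cumTP <- cumsum(ys); cumFP <- cumsum(!ys)
  last <- which(!duplicated(ps, fromLast = TRUE))  # last row of each score
  tp <- c(0L, cumTP[last]); fp <- c(0L, cumFP[last])
  data.frame(
    threshold = c(Inf, ps[last]),
    precision = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_),
    recall = tp / nPos,
    tp = tp, fp = fp, fn = nPos - tp, tn = nNeg - fp)
}

#' Select the operating point closest to a target precision
#'
#' Exact target precision is generally unattainable on a finite sample; the
#' closest achievable value is used.  Among the curve's points with at
#' least one positive call, the point minimizing |precision - target| is
#' returned; ties prefer precision >= target, then higher recall, then
#' higher threshold.
#'
#' @param pred pooled predictions (see [prCurve]) or an already-computed
#'   operating-point data.frame.
#' @param target target precision (default 0.99).
#' @return a single-row data.frame: threshold, precision, recall, tp, fp,
#'   fn, tn.
#' @export
selectThreshold <- function(pred, target = 0.99) {
  curve <- if (all(c("threshold", "tp") %in% names(pred))) pred
           else prCurve(pred)
  cand <- curve[!is.na(curve$precision), , drop = FALSE]
  if (!nrow(cand)) stop("no threshold yields a positive call")
  d <- abs(cand$precision - target)
  ord <- order(d, cand$precision < target, -cand$recall, -cand$threshold)
  out <- cand[ord[1], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default parameter grids
#'
#' The cost grid spans `2^-5, 2^-3, ..., 2^15`; the prior grid is
#' `{0.01, 0.05, 0.1, 0.2, ..., 0.9, 0.99}`.  Both are overridable at every
#' call site.
#'
#' @param classifier "nb" or "svm".
#' @return numeric vector of grid values.
#' @export
defaultGrid <- function(classifier = c("nb", "svm")) {
  classifier <- match.arg(classifier)
  if (classifier == "svm") 2^seq(-5L, 15L, by = 2L)
  else c(0.01, 0.05, seq(0.1, 0.9, by = 0.1), 0.99)
}

#' Grid search maximizing recall at a target precision
#'
#' For every candidate value of the top-level parameter, runs pooled
#' cross-validation, selects the threshold closest to the target precision
#' and records the recall there; returns the value with the highest such
#' recall (ties to the smaller value).  Misclassification counts at the
#' selected points are recorded for diagnostics.
#'
#' @param train a [SiteTrainingSet-class].
#' @param classifier "nb" or "svm".
#' @param grid numeric vector of candidate parameter values.
#' @param targetPrecision target precision (default 0.99).
#' @param F folds (default 5).
#' @param seed integer seed.
#' @return list with `param` (best value), `predictions` (its pooled
#'   predictions), `operatingPoint` (selected threshold row) and `summary`
#'   (per-grid-value recall/precision/misclassification table).
#' @export
gridSearch <- function(train, classifier = c("nb", "svm"),
                       grid = defaultGrid(classifier),
                       targetPrecision = 0.99, F = 5L, seed = 1L) {
  classifier <- match.arg(classifier)
  if (!length(grid)) stop("parameter grid is empty")
  grid <- sort(grid)
  best <- NULL
  rows <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    pred <- crossValidate(train, classifier, param = grid[k], F = F,
                          seed = seed)
    op <- selectThreshold(pred, target = targetPrecision)
    rows[[k]] <- data.frame(param = grid[k], threshold = op$threshold,
                            precision = op$precision, recall = op$recall,
                            misclassified = op$fp + op$fn)
    if (is.null(best) || op$recall > best$operatingPoint$recall) {
      best <- list(param = grid[k], predictions = pred,
                   operatingPoint = op)
    }
  }
  best$summary <- do.call(rbind, rows)
  best
}

#' Wilson score confidence interval for a proportion
#'
#' Used for the recall (and precision) intervals; well-behaved at
#' proportions near 0 and 1.
#'
#' @param k number of successes.
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return numeric `c(lower=, upper=)`, contained in `[0,1]`.
#' @export
recallCI <- function(k, n, level = 0.95) {
  stopifnot(n >= 1L, k >= 0L, k <= n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ph <- k / n
  denom <- 1 + z^2 / n
  mid <- (ph + z^2 / (2 * n)) / denom
  half <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, mid - half), upper = min(1, mid + half))
}

#' Score a sequence-level annotator against site-level truth
#'
#' Confusion-matrix logic for comparing domain predictions with site
#' labels through a site-to-domain mapping: a positive example is a true
#' positive when any predicted domain intersects the site's mapped set
#' (else a false negative); a negative example with a non-empty
#' intersection is a false positive (else a true negative).  Sites with no
#' mapping entry are unscorable.
#'
#' @param examples data.frame with a `label` column and a list-column
#'   `domains` of predicted domain identifiers per example.
#' @param mapping named list: site name -> character vector of acceptable
#'   domain identifiers.
#' @param site the site name to score.
#' @return single-row data.frame: precision (NA when no positive calls),
#'   recall, tp, fp, fn, tn.
#' @export
mappedConfusion <- function(examples, mapping, site) {
  if (!site %in% names(mapping) || !length(mapping[[site]]))
    stop(sprintf("site '%s' has no domain mapping; unscorable", site))
  ok <- mapping[[site]]
  hit <- vapply(examples$domains,
                function(d) length(intersect(d, ok)) > 0, logical(1))
  pos <- examples$label == "positive"
  tp <- sum(pos & hit); fn <- sum(pos & !hit)
  fp <- sum(!pos & hit); tn <- sum(!pos & !hit)
  data.frame(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
             recall = tp / (tp + fn), tp = tp, fp = fp, fn = fn, tn = tn)
}
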