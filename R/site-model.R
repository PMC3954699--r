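#' Train a thresholded site model
#'
#' Runs the full selection protocol: grid search over the classifier's
#' top-level parameter with stratified pooled cross-validation, threshold
#' selection at the closest-achievable target precision, then a final refit
#' on the complete training set with the winning parameter.  The achieved
#' (cross-validated) precision and recall are stored with the model.
#'
#' @param train a [SiteTrainingSet-class].
#' @param site site name recorded in the model.
#' @param classifier "nb" or "svm".
#' @param grid candidate parameter values (defaults to [defaultGrid]).
#' @param targetPrecision target precision (default 0.99).
#' @param F folds (default 5).
#' @param seed integer seed.
#' @param residueName,functionalAtom residue/atom type the model is
#'   centered on (recorded for scanning).
#' @return A [SiteModel-class].
#' @export
trainSiteModel <- function(train, site, classifier = c("nb", "svm"),
                           grid = defaultGrid(classifier),
                           targetPrecision = 0.99, F = 5L, seed = 1L,
                           residueName = NA_character_,
                           functionalAtom = NA_character_) {
  classifier <- match.arg(classifier)
  gs <- gridSearch(train, classifier, grid = grid,
                   targetPrecision = targetPrecision, F = F, seed = seed)
  op <- gs$operatingPoint
  clf <- if (classifier == "nb") nbFit(train, priorPositive = gs$param)
         else svmFit(train, cost = gs$param, seed = seed)
  # posteriors can saturate to 0/1 in floating point; keep the stored
  # threshold strictly inside (0,1) without changing any >= comparison
  thr <- min(max(op$threshold, 1e-12), 1 - 1e-12)
  model <- new("SiteModel", site = site, kind = classifier,
               classifier = clf, param = gs$param,
               threshold = thr, precision = op$precision,
               recall = op$recall, catalogVersion = train@catalogVersion,
               functionalAtom = functionalAtom, residueName = residueName,
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  attr(model, "gridSummary") <- gs$summary
  model
}

#' @describeIn predictProba dispatch through the model's classifier.
#' @export
setMethod("predictProba", "SiteModel",
          function(model, x) predictProba(model@classifier, x))

#' Scan a structure for predicted functional sites
#'
#' Every residue whose name equals the model's residue type and which
#' contains the functional atom is a candidate: the microenvironment is
#' computed at that atom and the model's posterior evaluated.  Residues
#' missing the atom are skipped with a message.  Hits are returned sorted
#' by descending probability (ties broken by chain/residue for stable
#' output).
#'
#' @param structure a [ProteinStructure-class] (secondary structure already
#'   assigned as desired).
#' @param model a [SiteModel-class].
#' @param pattern optional [SitePattern-class] supplying the residue/atom
#'   type when the model does not record them.
#' @param config a [ShellConfig-class].
#' @param catalog a [PropertyCatalog-class]; its version must match the
#'   model's.
#' @return data.frame of site hits: structureId, chain, resno, icode,
#'   residueName, atomName, pPositive, call.
#' @export
scanStructure <- function(structure, model, pattern = NULL,
                          config = ShellConfig(),
                          catalog = defaultPropertyCatalog()) {
  resName <- if (!is.na(model@residueName)) model@residueName
             else if (!is.null(pattern)) pattern@residueName
             else stop("model records no residue type and no pattern given")
  atName <- if (!is.na(model@functionalAtom)) model@functionalAtom
            else pattern@functionalAtom
  if (!identical(catalog@version, model@catalogVersion))
    stop(sprintf(
      "catalog version mismatch: model built with '%s', scanning with '%s'",
      model@catalogVersion, catalog@version))
  at <- structure@atoms
  resRows <- which(at$residueName == resName & !at$isHetero)
  resKey <- paste(at$chain, at$resno, at$icode, sep = "\r")
  empty <- data.frame(structureId = character(), chain = character(),
                      resno = integer(), icode = character(),
                      residueName = character(), atomName = character(),
                      pPositive = numeric(), call = logical(),
                      stringsAsFactors = FALSE)
  if (!length(resRows)) return(empty)
  centers <- NULL
  meta <- empty
  for (k in unique(resKey[resRows])) {
    rows <- which(resKey == k)
    hit <- rows[at$atomName[rows] == atName]
    if (!length(hit)) {
      message(sprintf("%s: residue %s%d%s lacks atom %s; skipped",
                      structure@id, at$chain[rows[1]], at$resno[rows[1]],
                      at$icode[rows[1]], atName))
      next
    }
    i <- hit[1]
    centers <- rbind(centers, c(at$x[i], at$y[i], at$z[i]))
    meta[nrow(meta) + 1L, ] <- list(structure@id, at$chain[i], at$resno[i],
                                    at$icode[i], at$residueName[i],
                                    at$atomName[i], NA_real_, NA)
  }
  if (is.null(centers)) return(empty)
  feats <- featurize(structure, centers, config = config, catalog = catalog)
  pr <- predictProba(model, feats)
  meta$pPositive <- pr[, "positive"]
  meta$call <- meta$pPositive >= model@threshold
  meta <- meta[order(-meta$pPositive, meta$chain, meta$resno, meta$icode), ,
               drop = FALSE]
  rownames(meta) <- NULL
  meta
}

#' Serialize a site model to JSON
#'
#' The envelope carries the metadata (site, kind, selected parameter,
#' threshold, achieved precision/recall, catalog version) and the complete
#' classifier parameters; numbers are written at full precision, so a
#' round-trip reproduces probabilities to machine accuracy.
#'
#' @param model a [SiteModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
saveSiteModel <- function(model, path) {
  clf <- model@classifier
  payload <- list(
    format = "SiteScan-model", formatVersion = 1L,
    site = model@site, kind = model@kind, param = model@param,
    threshold = model@threshold, precision = model@precision,
    recall = model@recall, catalogVersion = model@catalogVersion,
    residueName = model@residueName,
    functionalAtom = model@functionalAtom, created = model@created,
    classifier = if (model@kind == "nb") list(
      edges = clf@edges, logLikPos = clf@logLikPos,
      logLikNeg = clf@logLikNeg, priorPositive = clf@priorPositive,
      featureNames = clf@featureNames
    ) else list(
      w = clf@w, rho = clf@rho, probA = clf@probA, probB = clf@probB,
      positiveFirst = clf@positiveFirst, center = clf@center,
      scale = clf@scale, cost = clf@cost, featureNames = clf@featureNames
    ))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE, na = "null")
  invisible(path)
}

#' Deserialize a site model
#'
#' @param path path to a file written by [saveSiteModel].
#' @param catalog optional [PropertyCatalog-class]; when given, its version
#'   must match the stored model's.
#' @return A [SiteModel-class].
#' @export
loadSiteModel <- function(path, catalog = NULL) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "SiteScan-model"))
    stop("not a SiteScan model file: ", path)
  if (!is.null(catalog) && !identical(catalog@version, p$catalogVersion))
    stop(sprintf(
      "catalog version mismatch: model built with '%s', current '%s'",
      p$catalogVersion, catalog@version))
  c0 <- p$classifier
  clf <- if (p$kind == "nb") {
    nf <- length(c0$featureNames)
    new("NBModel",
        edges = matrix(unlist(c0$edges), nrow = nf,
                       dimnames = list(c0$featureNames, NULL)),
        logLikPos = matrix(unlist(c0$logLikPos), nrow = nf),
        logLikNeg = matrix(unlist(c0$logLikNeg), nrow = nf),
        priorPositive = c0$priorPositive, featureNames = c0$featureNames)
  } else {
    new("SVMModel", w = c0$w, rho = c0$rho, probA = c0$probA,
        probB = c0$probB, positiveFirst = c0$positiveFirst,
        center = c0$center, scale = c0$scale, cost = c0$cost,
        featureNames = c0$featureNames)
  }
  new("SiteModel", site = p$site, kind = p$kind, classifier = clf,
      param = p$param, threshold = p$threshold, precision = p$precision,
      recall = p$recall, catalogVersion = p$catalogVersion,
      residueName = p$residueName %||% NA_character_,
      functionalAtom = p$functionalAtom %||% NA_character_,
      created = p$created %||% "")
}
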