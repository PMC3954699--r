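#' Accessors for SiteScan classes
#'
#' Small extractor functions; user code should prefer these over direct
#' slot access.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("structureId", "ProteinStructure", function(x) x@id)

#' @rdname accessors
#' @export
setMethod("atomRecords", "ProteinStructure", function(x) x@atoms)

#' @rdname accessors
#' @export
setMethod("ssLabels", "ProteinStructure", function(x) x@ssLabels)

#' @rdname accessors
#' @export
setMethod("structureResolution", "ProteinStructure", function(x) x@resolution)

#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureVector", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("catalogVersion", "FeatureVector", function(x) x@catalogVersion)

#' @rdname accessors
#' @export
setMethod("catalogVersion", "PropertyCatalog", function(x) x@version)

#' @rdname accessors
#' @export
setMethod("catalogVersion", "SiteTrainingSet", function(x) x@catalogVersion)

#' @rdname accessors
#' @export
setMethod("catalogVersion", "SiteModel", function(x) x@catalogVersion)

#' @rdname accessors
#' @export
setMethod("catalogSize", "PropertyCatalog", function(x) nrow(x@properties))

#' @rdname accessors
#' @export
setMethod("featureMatrix", "SiteTrainingSet", function(x) x@features)

#' @rdname accessors
#' @export
setMethod("exampleLabels", "SiteTrainingSet", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("exampleProvenance", "SiteTrainingSet", function(x) x@provenance)

#' @rdname accessors
#' @export
setMethod("decisionThreshold", "SiteModel", function(x) x@threshold)

setMethod("show", "ProteinStructure", function(object) {
  cat(sprintf("ProteinStructure '%s': %d atoms (%d hetero), %d chains",
              object@id, nrow(object@atoms), sum(object@atoms$isHetero),
              length(unique(object@atoms$chain))),
      if (is.na(object@resolution)) ", resolution unknown"
      else sprintf(", %.2f A resolution", object@resolution), "\n", sep = "")
})

setMethod("show", "ShellConfig", function(object) {
  cat(sprintf("ShellConfig: %d shells x %.2f A (outer radius %.2f A)\n",
              object@nShells, object@thicknessA,
              object@nShells * object@thicknessA))
})

setMethod("show", "PropertyCatalog", function(object) {
  tab <- table(object@properties$group)
  cat(sprintf("PropertyCatalog '%s': %d properties\n", object@version,
              nrow(object@properties)))
  cat(paste(sprintf("  %s: %d", names(tab), as.integer(tab)),
            collapse = "\n"), "\n")
})

setMethod("show", "FeatureVector", function(object) {
  nz <- sum(object@values != 0)
  cat(sprintf(
    "FeatureVector (%d slots, %d non-zero) at (%.2f, %.2f, %.2f) [%s]\n",
    length(object@values), nz, object@center[1], object@center[2],
    object@center[3], object@sourceId))
})

setMethod("show", "ChainSequence", function(object) {
  s <- object@sequence
  cat(sprintf("ChainSequence %s (%d residues): %s\n", object@chainId,
              nchar(s),
              if (nchar(s) > 60) paste0(substr(s, 1, 57), "...") else s))
})

setMethod("show", "SitePattern", function(object) {
  cat(sprintf("SitePattern %s: %s\n  conserved position %d = %s, atom %s\n",
              object@name, object@pattern, object@conservedIndex,
              object@residueName, object@functionalAtom))
})

setMethod("show", "SiteTrainingSet", function(object) {
  cat(sprintf(
    "SiteTrainingSet: %d features x %d examples (%d positive, %d negative), catalog %s\n",
    nrow(object@features), ncol(object@features),
    sum(object@labels == "positive"), sum(object@labels == "negative"),
    object@catalogVersion))
})

setMethod("show", "NBModel", function(object) {
  cat(sprintf(
    "NBModel: %d features, %d bins, prior P(positive) = %.3g\n",
    nrow(object@edges), ncol(object@logLikPos), object@priorPositive))
})

setMethod("show", "SVMModel", function(object) {
  cat(sprintf("SVMModel: linear, %d features, cost C = %.3g\n",
              length(object@w), object@cost))
})

setMethod("show", "SiteModel", function(object) {
  cat(sprintf(
    "SiteModel %s [%s]: param %.3g, threshold %.4f, precision %.3f, recall %.3f\n  centered on %s %s, catalog %s\n",
    object@site, toupper(object@kind), object@param, object@threshold,
    object@precision, object@recall, object@residueName,
    object@functionalAtom, object@catalogVersion))
})
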