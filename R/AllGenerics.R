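#' @include AllClasses.R
NULL

#' Posterior class probabilities for a feature vector
#'
#' Dispatches on the classifier type. Both classifier classes return a
#' two-element named numeric `c(positive = p, negative = 1 - p)`.
#'
#' @param model A fitted [NBModel-class] or [SVMModel-class].
#' @param x A numeric vector (or matrix, one row per example) of feature
#'   values whose length (or column count) equals the model's feature count.
#' @return For a vector input, a named numeric of length 2 summing to 1;
#'   for a matrix input, a two-column matrix with columns
#'   `positive`, `negative`.
#' @export
setGeneric("predictProba", function(model, x) standardGeneric("predictProba"))

#' @rdname accessors
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))

#' @rdname accessors
#' @export
setGeneric("atomRecords", function(x) standardGeneric("atomRecords"))

#' @rdname accessors
#' @export
setGeneric("ssLabels", function(x) standardGeneric("ssLabels"))

#' @rdname accessors
#' @export
setGeneric("structureResolution", function(x) standardGeneric("structureResolution"))

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname accessors
#' @export
setGeneric("catalogVersion", function(x) standardGeneric("catalogVersion"))

#' @rdname accessors
#' @export
setGeneric("catalogSize", function(x) standardGeneric("catalogSize"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("exampleLabels", function(x) standardGeneric("exampleLabels"))

#' @rdname accessors
#' @export
setGeneric("exampleProvenance", function(x) standardGeneric("exampleProvenance"))

#' @rdname accessors
#' @export
setGeneric("decisionThreshold", function(x) standardGeneric("decisionThreshold"))
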