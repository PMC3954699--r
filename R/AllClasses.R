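#' Shell geometry of a microenvironment
#'
#' The descriptor accumulates properties in `nShells` concentric spherical
#' shells of constant thickness around a central point.  The defaults (six
#' shells of 1.25 Angstroms) give an outer radius of 7.5 Angstroms.  Shell
#' boundaries are half-open, `[k*t, (k+1)*t)`, so every distance below the
#' outer radius falls in exactly one shell.
#'
#' @slot nShells integer, number of shells (>= 1).
#' @slot thicknessA numeric, shell thickness in Angstroms (> 0).
#' @export
setClass("ShellConfig",
  representation(nShells = "integer", thicknessA = "numeric"),
  prototype(nShells = 6L, thicknessA = 1.25),
  validity = function(object) {
    msg <- NULL
    if (length(object@nShells) != 1L || is.na(object@nShells) ||
        object@nShells < 1L)
      msg <- c(msg, "nShells must be a single integer >= 1")
    if (length(object@thicknessA) != 1L || !is.finite(object@thicknessA) ||
        object@thicknessA <= 0)
      msg <- c(msg, "thicknessA must be a single positive number")
    if (is.null(msg)) TRUE else msg
  }
)

#' Constructor for ShellConfig
#' @param nShells number of shells.
#' @param thicknessA shell thickness in Angstroms.
#' @return A [ShellConfig-class] object.
#' @export
ShellConfig <- function(nShells = 6L, thicknessA = 1.25) {
  new("ShellConfig", nShells = as.integer(nShells),
      thicknessA = as.numeric(thicknessA))
}

#' Ordered catalog of per-shell physicochemical properties
#'
#' A versioned table defining, in fixed order, the properties accumulated in
#' every shell.  Each row has a `group` (AtomName, ChemicalGroup,
#' AtomProperties, ResidueName, ResidueProperties, SecondaryStructure), a
#' `name`, an accumulation `rule` (`indicator` rows count matching atoms,
#' `scalar` rows sum a per-atom value) and optional `params` (currently
#' `element=<E>` restricting a scalar to atoms of one element).
#'
#' @slot properties data.frame with columns group, name, rule, params.
#' @slot version character, catalog version tag recorded in every vector.
#' @export
setClass("PropertyCatalog",
  representation(properties = "data.frame", version = "character"),
  validity = function(object) {
    msg <- NULL
    need <- c("group", "name", "rule", "params")
    if (!all(need %in% names(object@properties)))
      msg <- c(msg, sprintf("properties must have columns %s",
                            paste(need, collapse = ", ")))
    else {
      full <- paste(object@properties$group, object@properties$name,
                    object@properties$params)
      if (anyDuplicated(full))
        msg <- c(msg, "property (group, name, params) entries must be unique")
      if (!all(object@properties$rule %in% c("indicator", "scalar")))
        msg <- c(msg, "rule must be 'indicator' or 'scalar'")
    }
    if (length(object@version) != 1L || !nzchar(object@version))
      msg <- c(msg, "version must be a non-empty string")
    if (is.null(msg)) TRUE else msg
  }
)

#' Parsed protein structure
#'
#' Atoms in file order with residue context, per-residue secondary-structure
#' labels, and the crystallographic resolution when the header reports one.
#'
#' @slot atoms data.frame, one row per atom: serial, atomName, element,
#'   residueName, chain, resno, icode, x, y, z, occupancy, bfactor, isHetero.
#' @slot ssLabels data.frame with columns chain, resno, icode, ss; one row
#'   per residue, `ss` one of 3Helix, 4Helix, 5Helix, Bridge, Strand, Turn,
#'   Bend, Coil, Het, Unknown.
#' @slot resolution numeric, Angstroms (NA when unknown).
#' @slot id character structure identifier.
#' @export
setClass("ProteinStructure",
  representation(atoms = "data.frame", ssLabels = "data.frame",
                 resolution = "numeric", id = "character"),
  validity = function(object) {
    msg <- NULL
    need <- c("serial", "atomName", "element", "residueName", "chain",
              "resno", "icode", "x", "y", "z", "occupancy", "bfactor",
              "isHetero")
    if (!all(need %in% names(object@atoms)))
      msg <- c(msg, sprintf("atoms must have columns %s",
                            paste(need, collapse = ", ")))
    else {
      if (nrow(object@atoms) &&
          !all(is.finite(object@atoms$x) & is.finite(object@atoms$y) &
               is.finite(object@atoms$z)))
        msg <- c(msg, "atom coordinates must be finite")
      if (nrow(object@atoms) && !all(nzchar(object@atoms$atomName)))
        msg <- c(msg, "atom names must be non-empty")
    }
    if (!all(c("chain", "resno", "icode", "ss") %in% names(object@ssLabels)))
      msg <- c(msg, "ssLabels must have columns chain, resno, icode, ss")
    else if (nrow(object@ssLabels) &&
             !all(object@ssLabels$ss %in% SS_CODES))
      msg <- c(msg, "ssLabels$ss contains codes outside the allowed set")
    if (is.null(msg)) TRUE else msg
  }
)

#' Secondary-structure vocabulary
#'
#' The ten per-residue secondary-structure codes used by the descriptor.
#' @export
SS_CODES <- c("3Helix", "4Helix", "5Helix", "Bridge", "Strand", "Turn",
              "Bend", "Coil", "Het", "Unknown")

#' One-letter sequence of a chain with its residue-number map
#'
#' @slot chainId character chain identifier.
#' @slot sequence one-letter amino-acid string; unknown residues are "X".
#' @slot residueKeys data.frame with columns resno, icode aligned 1:1 with
#'   the sequence characters.
#' @export
setClass("ChainSequence",
  representation(chainId = "character", sequence = "character",
                 residueKeys = "data.frame"),
  validity = function(object) {
    msg <- NULL
    if (length(object@sequence) != 1L)
      msg <- c(msg, "sequence must be a single string")
    else if (nchar(object@sequence) != nrow(object@residueKeys))
      msg <- c(msg, "sequence length must equal nrow(residueKeys)")
    if (!all(c("resno", "icode") %in% names(object@residueKeys)))
      msg <- c(msg, "residueKeys must have columns resno, icode")
    if (is.null(msg)) TRUE else msg
  }
)

#' A microenvironment descriptor
#'
#' Ordered accumulation of catalog properties per shell; names follow the
#' `shellK.group.name` scheme with shells numbered from 1 (innermost).
#'
#' @slot values named numeric of length nShells * catalog size.
#' @slot center numeric(3), the point the shells are drawn around.
#' @slot sourceId character provenance tag.
#' @slot catalogVersion character, version of the catalog used.
#' @export
setClass("FeatureVector",
  representation(values = "numeric", center = "numeric",
                 sourceId = "character", catalogVersion = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@center) != 3L || !all(is.finite(object@center)))
      msg <- c(msg, "center must be a finite 3-vector")
    if (is.null(names(object@values)))
      msg <- c(msg, "values must be named")
    if (is.null(msg)) TRUE else msg
  }
)

#' A sequence motif with a conserved functional position
#'
#' PROSITE-style pattern plus the 1-based index (within a matched span) of
#' the conserved residue and the side-chain atom at which microenvironments
#' are centered.
#'
#' @slot name character site name, e.g. "ASP_PROTEASE".
#' @slot pattern character, the PROSITE grammar string.
#' @slot elements list of parsed pattern elements (see [parsePrositePattern]).
#' @slot conservedIndex integer, 1-based position of the conserved residue
#'   within a matched span.
#' @slot residueName character 3-letter code of the conserved residue.
#' @slot functionalAtom character PDB atom name, e.g. "OD2".
#' @export
setClass("SitePattern",
  representation(name = "character", pattern = "character",
                 elements = "list", conservedIndex = "integer",
                 residueName = "character", functionalAtom = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@conservedIndex) != 1L || object@conservedIndex < 1L)
      msg <- c(msg, "conservedIndex must be a positive integer")
    minlen <- sum(vapply(object@elements, function(e) e$min, integer(1)))
    if (length(object@elements) && object@conservedIndex > minlen &&
        all(vapply(object@elements, function(e) e$min == e$max, logical(1))))
      msg <- c(msg, "conservedIndex exceeds the pattern length")
    if (is.null(msg)) TRUE else msg
  }
)

#' Labeled microenvironment training set
#'
#' A features-by-examples matrix with aligned labels and per-example
#' provenance, the unit of data consumed by the classifiers and the
#' cross-validation machinery.
#'
#' @slot features numeric matrix, rows = descriptor slots (named), columns =
#'   examples.
#' @slot labels character vector in {"positive","negative"}, one per column.
#' @slot provenance data.frame, one row per example: structureId, chain,
#'   resno, icode, atom.
#' @slot catalogVersion character catalog the features were computed with.
#' @slot seed integer seed recorded when sampling was involved (NA if none).
#' @export
setClass("SiteTrainingSet",
  representation(features = "matrix", labels = "character",
                 provenance = "data.frame", catalogVersion = "character",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    n <- ncol(object@features)
    if (length(object@labels) != n)
      msg <- c(msg, "one label per feature column required")
    if (!all(object@labels %in% c("positive", "negative")))
      msg <- c(msg, "labels must be 'positive' or 'negative'")
    if (nrow(object@provenance) != n)
      msg <- c(msg, "one provenance row per feature column required")
    if (is.null(rownames(object@features)))
      msg <- c(msg, "feature rows must be named")
    if (is.null(msg)) TRUE else msg
  }
)

#' Binned naive Bayes classifier
#'
#' Five-bin histograms per feature and class with Laplace smoothing and a
#' tunable positive-class prior; the posterior is computed in log space.
#'
#' @slot edges numeric matrix nFeatures x (nBins - 1) of strictly increasing
#'   inner bin edges; values map to bin `1 + sum(x >= edges)`, so values
#'   outside the training range clamp into the outer bins.
#' @slot logLikPos,logLikNeg numeric matrices nFeatures x nBins of smoothed
#'   log bin probabilities per class.
#' @slot priorPositive numeric in (0,1), the tunable prior P.
#' @slot featureNames character, names of expected feature slots.
#' @export
setClass("NBModel",
  representation(edges = "matrix", logLikPos = "matrix",
                 logLikNeg = "matrix", priorPositive = "numeric",
                 featureNames = "character"),
  validity = function(object) {
    msg <- NULL
    if (object@priorPositive <= 0 || object@priorPositive >= 1)
      msg <- c(msg, "priorPositive must lie strictly in (0,1)")
    if (nrow(object@logLikPos) != nrow(object@edges) ||
        nrow(object@logLikNeg) != nrow(object@edges))
      msg <- c(msg, "edges and log-likelihood matrices must agree in rows")
    if (max(abs(rowSums(exp(object@logLikPos)) - 1)) > 1e-6 ||
        max(abs(rowSums(exp(object@logLikNeg)) - 1)) > 1e-6)
      msg <- c(msg, "per-feature bin probabilities must sum to 1 per class")
    if (is.null(msg)) TRUE else msg
  }
)

#' Linear maximum-margin classifier with calibrated probabilities
#'
#' Soft-margin linear SVM fitted on standardized features; the stored
#' parameters (weight vector, offset, sigmoid calibration coefficients and
#' scaling statistics) fully determine prediction, so the model serializes
#' to plain JSON.
#'
#' @slot w numeric weight vector in the scaled feature space.
#' @slot rho numeric offset (decision value = w . x_scaled - rho).
#' @slot probA,probB numeric sigmoid calibration coefficients: the
#'   probability of the orientation class is 1/(1+exp(probA*dec + probB)).
#' @slot positiveFirst logical, TRUE when the decision value is oriented
#'   toward the positive class.
#' @slot center,scale numeric per-feature standardization statistics.
#' @slot cost numeric, the cost parameter C the model was fitted with.
#' @slot featureNames character, names of expected feature slots.
#' @export
setClass("SVMModel",
  representation(w = "numeric", rho = "numeric", probA = "numeric",
                 probB = "numeric", positiveFirst = "logical",
                 center = "numeric", scale = "numeric", cost = "numeric",
                 featureNames = "character"),
  validity = function(object) {
    msg <- NULL
    if (object@cost <= 0) msg <- c(msg, "cost must be positive")
    if (length(object@center) != length(object@w) ||
        length(object@scale) != length(object@w))
      msg <- c(msg, "center/scale must match the weight vector length")
    if (is.null(msg)) TRUE else msg
  }
)

#' A trained, thresholded site model ready for scanning
#'
#' @slot site character site name.
#' @slot kind character, "nb" or "svm".
#' @slot classifier the fitted [NBModel-class] or [SVMModel-class].
#' @slot param numeric, the selected top-level parameter (prior P or cost C).
#' @slot threshold numeric decision threshold on p_positive.
#' @slot precision,recall numeric, cross-validated performance at the
#'   threshold.
#' @slot catalogVersion character catalog version the model expects.
#' @slot functionalAtom,residueName character, the atom/residue the model
#'   is centered on.
#' @slot created character creation timestamp.
#' @export
setClass("SiteModel",
  representation(site = "character", kind = "character", classifier = "ANY",
                 param = "numeric", threshold = "numeric",
                 precision = "numeric", recall = "numeric",
                 catalogVersion = "character", functionalAtom = "character",
                 residueName = "character", created = "character"),
  validity = function(object) {
    msg <- NULL
    if (!object@kind %in% c("nb", "svm"))
      msg <- c(msg, "kind must be 'nb' or 'svm'")
    if (!is.na(object@threshold) &&
        (object@threshold <= 0 || object@threshold >= 1))
      msg <- c(msg, "threshold must lie strictly in (0,1)")
    if (is.null(msg)) TRUE else msg
  }
)
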