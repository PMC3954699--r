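#' Coordinate of the functional atom of a matched conserved residue
#'
#' @param structure a [ProteinStructure-class].
#' @param match one row of the data.frame returned by [matchSitePattern].
#' @param pattern the [SitePattern-class] the match came from.
#' @return numeric 3-vector, or `NULL` (with a message) when the conserved
#'   residue lacks the functional atom, e.g. a truncated side chain.
#' @export
extractPositive <- function(structure, match, pattern) {
  at <- structure@atoms
  hit <- at$chain == match$chain & at$resno == match$resno &
    at$icode == match$icode & at$atomName == pattern@functionalAtom
  if (!any(hit)) {
    message(sprintf(
      "%s: residue %s%d%s lacks atom %s; example skipped",
      structure@id, match$chain, match$resno, match$icode,
      pattern@functionalAtom))
    return(NULL)
  }
  i <- which(hit)[1]
  c(at$x[i], at$y[i], at$z[i])
}

#' Deduplicate structures by exact chain-sequence identity
#'
#' Groups entries whose extracted sequences are identical strings and keeps
#' one representative per group: the entry with the best (numerically
#' smallest) crystallographic resolution; entries with unknown resolution
#' lose to any numeric value; remaining ties go to the lexicographically
#' smallest structure id.
#'
#' @param entries data.frame with columns `id`, `sequence`, `resolution`
#'   (NA allowed).
#' @return the representative subset of `entries`, one row per distinct
#'   sequence, ordered by sequence.
#' @export
deduplicateStructures <- function(entries) {
  stopifnot(all(c("id", "sequence", "resolution") %in% names(entries)))
  keep <- integer(0)
  for (s in sort(unique(entries$sequence))) {
    idx <- which(entries$sequence == s)
    res <- entries$resolution[idx]
    key <- order(ifelse(is.na(res), Inf, res), entries$id[idx])
    keep <- c(keep, idx[key[1]])
  }
  out <- entries[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample negative-example atoms without replacement
#'
#' Draws exactly `n` distinct atoms uniformly at random from the eligible
#' pool — atoms whose residue name and atom name equal the requested ones.
#' The pool is expected to come from structures not associated with the
#' site being modeled; that exclusion is the caller's contract.
#'
#' @param pool data.frame with columns `structureId`, `residueName`,
#'   `atomName`, `chain`, `resno`, `icode`, `x`, `y`, `z`.
#' @param residueName,atomName the residue/atom type of the site's
#'   functional atom.
#' @param n number of atoms to draw (default 50000).
#' @param seed integer seed; the draw is reproducible for a fixed seed.
#' @param allowShort if TRUE, an eligible pool smaller than `n` returns the
#'   whole pool with a warning instead of an error.
#' @return the sampled subset of `pool`, `n` rows (or fewer under
#'   `allowShort`).
#' @export
sampleNegatives <- function(pool, residueName, atomName, n = 50000L,
                            seed = 1L, allowShort = FALSE) {
  stopifnot(n >= 1L)
  elig <- which(pool$residueName == residueName & pool$atomName == atomName)
  if (length(elig) < n) {
    if (!allowShort)
      stop(sprintf(
        "eligible pool (%d atoms of %s %s) is smaller than n = %d",
        length(elig), residueName, atomName, n))
    warning(sprintf("eligible pool has only %d atoms; returning all",
                    length(elig)))
    take <- elig
  } else {
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old), add = TRUE)
    set.seed(seed)
    take <- sample(elig, n, replace = FALSE)
  }
  out <- pool[take, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "seed") <- as.integer(seed)
  out
}

.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed.restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Build a labeled training set from positive and negative coordinates
#'
#' Featurizes every coordinate in its own structure and assembles the
#' labeled, provenance-tracked feature matrix the classifiers consume.
#'
#' @param positives,negatives data.frames with columns `structureId`,
#'   `chain`, `resno`, `icode`, `atom`, `x`, `y`, `z`.
#' @param structures named list of [ProteinStructure-class] objects keyed
#'   by structure id.
#' @param config a [ShellConfig-class].
#' @param catalog a [PropertyCatalog-class].
#' @param seed optional integer recorded in the set's provenance (e.g. the
#'   negative-sampling seed).
#' @return A [SiteTrainingSet-class].
#' @export
buildTrainingSet <- function(positives, negatives, structures,
                             config = ShellConfig(),
                             catalog = defaultPropertyCatalog(),
                             seed = NA_integer_) {
  stopifnot(nrow(positives) >= 1L, nrow(negatives) >= 1L)
  both <- rbind(cbind(positives, label = "positive"),
                cbind(negatives, label = "negative"))
  slots <- .shellSlotNames(config, catalog)
  feat <- matrix(NA_real_, nrow = length(slots), ncol = nrow(both),
                 dimnames = list(slots, NULL))
  for (id in unique(both$structureId)) {
    struct <- structures[[id]]
    if (is.null(struct)) stop("no structure supplied for id ", id)
    rows <- which(both$structureId == id)
    centers <- as.matrix(both[rows, c("x", "y", "z")])
    feat[, rows] <- t(featurize(struct, centers, config = config,
                                catalog = catalog))
  }
  new("SiteTrainingSet", features = feat,
      labels = as.character(both$label),
      provenance = data.frame(structureId = both$structureId,
                              chain = both$chain, resno = both$resno,
                              icode = both$icode, atom = both$atom,
                              stringsAsFactors = FALSE),
      catalogVersion = catalog@version, seed = as.integer(seed))
}

#' Assemble a training set directly from feature vectors
#'
#' Convenience constructor used by the synthetic-data generators and by
#' callers that already hold descriptor vectors.
#'
#' @param features numeric matrix, feature slots x examples, rownames set.
#' @param labels character vector in {"positive","negative"}.
#' @param provenance optional data.frame (one row per example).
#' @param catalogVersion catalog tag recorded with the set.
#' @param seed optional integer seed to record.
#' @return A [SiteTrainingSet-class].
#' @export
SiteTrainingSet <- function(features, labels, provenance = NULL,
                            catalogVersion = "unversioned",
                            seed = NA_integer_) {
  if (is.null(provenance))
    provenance <- data.frame(structureId = rep("synthetic", ncol(features)),
                             chain = "", resno = seq_len(ncol(features)),
                             icode = "", atom = "",
                             stringsAsFactors = FALSE)
  new("SiteTrainingSet", features = features, labels = labels,
      provenance = provenance, catalogVersion = catalogVersion,
      seed = as.integer(seed))
}
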