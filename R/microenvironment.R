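#' Shell index of a distance
#'
#' Maps a center-to-atom distance to its shell, with half-open boundaries
#' `[k*t, (k+1)*t)`.  Shells are numbered from 1 (innermost); distances at
#' or beyond the outer radius return `NA`.
#'
#' @param distance numeric vector of non-negative distances in Angstroms.
#' @param config a [ShellConfig-class].
#' @return integer vector of shell indices in `1:nShells`, or `NA` outside
#'   the outer radius.
#' @export
shellIndex <- function(distance, config = ShellConfig()) {
  if (any(distance < 0, na.rm = TRUE))
    stop("distances must be non-negative")
  idx <- floor(distance / config@thicknessA) + 1L
  idx[distance >= config@nShells * config@thicknessA] <- NA_integer_
  as.integer(idx)
}

.shellSlotNames <- function(config, catalog) {
  labs <- propertyLabels(catalog)
  unlist(lapply(seq_len(config@nShells),
                function(k) paste0("shell", k, ".", labs)),
         use.names = FALSE)
}

#' Compute microenvironment descriptors at one or more centers
#'
#' For every atom within the outer radius of a center, the atom's property
#' contributions (see [atomContributions]) are accumulated into the slots of
#' the shell its distance falls in; indicator properties count atoms, scalar
#' properties sum per-atom values.  Atoms at or beyond the outer radius do
#' not contribute; an atom sitting exactly at a center lands in shell 1.
#' No per-shell normalization is applied.
#'
#' @param structure a [ProteinStructure-class].
#' @param centers numeric 3-vector, or a matrix with one center per row.
#' @param config a [ShellConfig-class].
#' @param catalog a [PropertyCatalog-class].
#' @param sourceId provenance tag(s) for the resulting vector(s).
#' @param solvAcc optional per-atom solvent-accessibility values (defaults
#'   to 0; no geometric computation is attempted).
#' @return A [FeatureVector-class] for a single center; a numeric matrix
#'   (centers x slots) for a matrix of centers.
#' @export
featurize <- function(structure, centers, config = ShellConfig(),
                      catalog = defaultPropertyCatalog(),
                      sourceId = structure@id, solvAcc = NULL) {
  single <- is.null(dim(centers))
  if (single) {
    stopifnot(length(centers) == 3L, all(is.finite(centers)))
    centers <- matrix(centers, nrow = 1L)
  }
  stopifnot(ncol(centers) == 3L, all(is.finite(centers)))
  slots <- .shellSlotNames(config, catalog)
  out <- matrix(0, nrow = nrow(centers), ncol = length(slots),
                dimnames = list(rownames(centers), slots))
  at <- structure@atoms
  if (nrow(at)) {
    P <- .atomPropertyMatrix(structure, catalog, solvAcc = solvAcc)
    xyz <- cbind(at$x, at$y, at$z)
    for (i in seq_len(nrow(centers))) {
      d <- sqrt(colSums((t(xyz) - centers[i, ])^2))
      sh <- shellIndex(d, config)
      keep <- !is.na(sh)
      if (!any(keep)) next
      acc <- rowsum(P[keep, , drop = FALSE], group = sh[keep])
      ks <- as.integer(rownames(acc))
      for (r in seq_along(ks)) {
        off <- (ks[r] - 1L) * catalogSize(catalog)
        out[i, off + seq_len(catalogSize(catalog))] <- acc[r, ]
      }
    }
  }
  if (single) {
    new("FeatureVector", values = out[1, ], center = as.numeric(centers),
        sourceId = sourceId[1], catalogVersion = catalog@version)
  } else out
}
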