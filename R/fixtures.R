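#' Generate toy PDB text with prescribed geometry
#'
#' Builds well-formed ATOM/HETATM records from a spec that places each atom
#' at a given radius from the origin along a given unit direction, so
#' distance-dependent behavior (shell assignment, locality) can be tested
#' against known geometry.  Parsing the output reproduces every radius to
#' 1e-3 Angstroms (the PDB coordinate precision).
#'
#' @param atoms data.frame, one row per atom, with columns `atomName`,
#'   `residueName`, `chain`, `resno` and `radius`; optional `ux`, `uy`,
#'   `uz` (unit direction, default +x), `icode`, `het` (logical, HETATM),
#'   `occupancy`, `bfactor`, `element`.
#' @param ss optional data.frame of HELIX/SHEET-style spans with columns
#'   `kind` ("helix"/"sheet"), `chain`, `from`, `to` and for helices
#'   `class` (PDB helix class, default 1).
#' @param resolution optional resolution in Angstroms, written as a
#'   REMARK 2 record.
#' @return character vector of PDB lines.
#' @export
makeToyPDB <- function(atoms, ss = NULL, resolution = NULL) {
  if (is.null(atoms) || !nrow(atoms)) stop("empty atom spec")
  need <- c("atomName", "residueName", "chain", "resno", "radius")
  if (!all(need %in% names(atoms)))
    stop("atom spec needs columns ", paste(need, collapse = ", "))
  if (any(atoms$radius < 0)) stop("radii must be non-negative")
  if (any(!nzchar(atoms$atomName)) || any(!nzchar(atoms$residueName)))
    stop("atom and residue names must be non-empty")
  n <- nrow(atoms)
  ux <- atoms$ux %||% rep(1, n); uy <- atoms$uy %||% rep(0, n)
  uz <- atoms$uz %||% rep(0, n)
  nrm <- sqrt(ux^2 + uy^2 + uz^2)
  if (any(abs(nrm - 1) > 1e-6)) stop("directions must be unit vectors")
  icode <- atoms$icode %||% rep("", n)
  het <- atoms$het %||% rep(FALSE, n)
  occ <- atoms$occupancy %||% rep(1, n)
  bf <- atoms$bfactor %||% rep(0, n)
  element <- atoms$element %||%
    .elementOf(atoms$atomName, rep(NA_character_, n), het)
  lines <- character(0)
  if (!is.null(resolution))
    lines <- c(lines, sprintf("REMARK   2 RESOLUTION.  %6.2f ANGSTROMS.",
                              resolution))
  if (!is.null(ss) && nrow(ss)) {
    for (i in seq_len(nrow(ss))) {
      if (ss$kind[i] == "helix") {
        cls <- if ("class" %in% names(ss)) ss$class[i] else 1L
        lines <- c(lines, sprintf(
          "HELIX  %3d %3s ALA %1s %4d  ALA %1s %4d %2d",
          i, sprintf("H%02d", i), ss$chain[i], ss$from[i], ss$chain[i],
          ss$to[i], cls))
      } else {
        lines <- c(lines, sprintf(
          "SHEET  %3d %3s 1 ALA %1s%4d  ALA %1s%4d  0",
          i, sprintf("S%02d", i), ss$chain[i], ss$from[i], ss$chain[i],
          ss$to[i]))
      }
    }
  }
  nm <- ifelse(nchar(atoms$atomName) < 4L, paste0(" ", atoms$atomName),
               atoms$atomName)
  lines <- c(lines, sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(het, "HETATM", "ATOM"), seq_len(n), nm, "",
    atoms$residueName, atoms$chain, atoms$resno, icode,
    atoms$radius * ux, atoms$radius * uy, atoms$radius * uz, occ, bf,
    ifelse(element == "OTHER", "", element)), "END")
  lines
}

#' Construct pooled predictions with prescribed achievable precisions
#'
#' Emits labeled probabilities block by block, so the multiset of
#' operating points of the resulting score set is known by construction
#' (e.g. a block of 99 positives and 1 negative at the same high score
#' gives an operating point with precision exactly 99/100).
#'
#' @param blocks data.frame with columns `count`, `label`
#'   ("positive"/"negative") and `score` in (0,1).
#' @return data.frame with columns `label`, `pPositive`, shaped like the
#'   output of [crossValidate].
#' @export
makeScoredSet <- function(blocks) {
  stopifnot(all(c("count", "label", "score") %in% names(blocks)))
  if (any(blocks$score <= 0 | blocks$score >= 1))
    stop("scores must lie strictly in (0,1)")
  if (any(blocks$count < 1)) stop("block counts must be >= 1")
  if (!all(c("positive", "negative") %in% blocks$label))
    stop("need at least one positive and one negative block")
  data.frame(
    label = rep(blocks$label, blocks$count),
    pPositive = rep(blocks$score, blocks$count),
    stringsAsFactors = FALSE)
}

#' Two-class Gaussian feature data with controllable separation
#'
#' Positives are drawn from `N(+d'/2 * u, I)` and negatives from
#' `N(-d'/2 * u, I)` along the fixed unit direction
#' `u = (1,...,1)/sqrt(dim)`, so the Mahalanobis separation between the
#' class means is exactly `d'`.  Used to verify that the selection
#' protocol recovers known operating characteristics.
#'
#' @param nPos,nNeg class sizes.
#' @param dim feature dimension (default 480, the descriptor length).
#' @param dPrime separation d' (>= 0).
#' @param seed integer seed; the set is a pure function of the spec + seed.
#' @return A [SiteTrainingSet-class] with feature rows named `f1..fdim`.
#' @export
makeGaussianSites <- function(nPos, nNeg, dim = 480L, dPrime = 8,
                              seed = 1L) {
  stopifnot(nPos >= 1L, nNeg >= 1L, dPrime >= 0)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old), add = TRUE)
  set.seed(seed)
  u <- rep(1 / sqrt(dim), dim)
  X <- rbind(
    matrix(stats::rnorm(nPos * dim), nPos) +
      matrix(dPrime / 2 * u, nPos, dim, byrow = TRUE),
    matrix(stats::rnorm(nNeg * dim), nNeg) -
      matrix(dPrime / 2 * u, nNeg, dim, byrow = TRUE))
  feat <- t(X)
  rownames(feat) <- paste0("f", seq_len(dim))
  SiteTrainingSet(feat,
                  labels = c(rep("positive", nPos), rep("negative", nNeg)),
                  catalogVersion = "synthetic-gaussian",
                  seed = seed)
}
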