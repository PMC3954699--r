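#' The default 80-property catalog
#'
#' Reads the versioned property-definition table shipped with the package
#' (`inst/extdata/property_catalog_v1.tsv`).  Per shell it defines the six
#' property groups of the descriptor: AtomName (6 indicators), ChemicalGroup
#' (6), AtomProperties (5 scalar accumulators plus 25 per-element variants),
#' ResidueName (22), ResidueProperties (6) and SecondaryStructure (10),
#' totaling 80 entries.
#'
#' @return A [PropertyCatalog-class].
#' @export
defaultPropertyCatalog <- function() {
  path <- system.file("extdata", "property_catalog_v1.tsv",
                      package = "SiteScan", mustWork = TRUE)
  readPropertyCatalog(path)
}

#' Read a property catalog definition file
#'
#' The file is tab-separated with columns `group`, `name`, `rule`, `params`
#' and a `# version:` comment line.  Row order fixes the slot order of every
#' feature vector computed with the catalog.
#'
#' @param path path to the TSV definition.
#' @param version version tag; defaults to the `# version:` header in the
#'   file, or the file name.
#' @return A [PropertyCatalog-class].
#' @export
readPropertyCatalog <- function(path, version = NULL) {
  lines <- readLines(path)
  if (is.null(version)) {
    vline <- grep("^#\\s*version:", lines, value = TRUE)
    version <- if (length(vline)) sub("^#\\s*version:\\s*", "", vline[1])
               else basename(path)
  }
  props <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                             stringsAsFactors = FALSE)
  props$params[is.na(props$params)] <- ""
  bad <- setdiff(props$group,
                 c("AtomName", "ChemicalGroup", "AtomProperties",
                   "ResidueName", "ResidueProperties", "SecondaryStructure"))
  if (length(bad))
    stop("unknown property group(s): ", paste(bad, collapse = ", "))
  new("PropertyCatalog", properties = props, version = version)
}

#' Column labels of a catalog ("group.name")
#' @param catalog a [PropertyCatalog-class].
#' @return character vector of length `catalogSize(catalog)`.
#' @export
propertyLabels <- function(catalog) {
  paste(catalog@properties$group, catalog@properties$name, sep = ".")
}

.elementOf <- function(atomName, elesy, isHetero) {
  el <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  known <- el %in% c("C", "N", "O", "S")
  out <- ifelse(known, el, "OTHER")
  miss <- !nzchar(el)
  if (any(miss)) {
    nm <- gsub("[0-9']", "", toupper(atomName[miss]))
    first <- substr(nm, 1, 1)
    guess <- ifelse(first %in% c("C", "N", "O", "S"), first, "OTHER")
    # hetero ions and selenium: the full name is the element symbol
    override <- (nm == "SE") | (isHetero[miss] & nm %in% NON_CNOS_NAMES)
    guess[override] <- "OTHER"
    out[miss] <- guess
  }
  out
}

# per-atom values for every catalog property -> atoms x properties matrix
.atomPropertyMatrix <- function(structure, catalog, solvAcc = NULL) {
  at <- structure@atoms
  n <- nrow(at)
  props <- catalog@properties
  M <- matrix(0, nrow = n, ncol = nrow(props),
              dimnames = list(NULL, propertyLabels(catalog)))
  if (n == 0L) return(M)

  element <- at$element
  res <- at$residueName
  key <- paste(res, at$atomName)
  isStd <- res %in% STANDARD_AA
  sideChain <- isStd & !(at$atomName %in% BACKBONE_ATOMS)

  # per-residue secondary structure, atoms mapped by (chain, resno, icode)
  ss <- structure@ssLabels
  akey <- paste(at$chain, at$resno, at$icode, sep = "\r")
  skey <- paste(ss$chain, ss$resno, ss$icode, sep = "\r")
  ssAtom <- ss$ss[match(akey, skey)]
  ssAtom[is.na(ssAtom)] <- ifelse(at$isHetero[is.na(ssAtom)], "Het",
                                  "Unknown")

  # scalar base values
  vdw <- unname(VDW_VOLUME[ifelse(element %in% names(VDW_VOLUME), element,
                                  "OTHER")])
  charge <- unname(ATOM_CHARGE[key]); charge[is.na(charge)] <- 0
  kd <- unname(KYTE_DOOLITTLE[res]); kd[is.na(kd)] <- 0
  nsc <- unname(SIDECHAIN_COUNT[res]); nsc[is.na(nsc)] <- 0
  hyd <- numeric(n)
  hyd[sideChain & nsc > 0] <- (kd / pmax(nsc, 1))[sideChain & nsc > 0]
  hyd[res == "GLY" & at$atomName == "CA"] <- KYTE_DOOLITTLE[["GLY"]]
  mob <- at$bfactor; mob[is.na(mob)] <- 0
  acc <- if (is.null(solvAcc)) numeric(n) else as.numeric(solvAcc)
  scalars <- list(VDWVolume = vdw, Charge = charge, Hydrophobicity = hyd,
                  Mobility = mob, SolventAccessibility = acc)

  for (j in seq_len(nrow(props))) {
    g <- props$group[j]; nm <- props$name[j]; pp <- props$params[j]
    M[, j] <- switch(g,
      AtomName = switch(nm,
        ANY = rep(1, n),
        OTHER = as.numeric(!element %in% c("C", "N", "O", "S")),
        as.numeric(element == nm)),
      ChemicalGroup = switch(nm,
        Carbonyl = as.numeric((isStd & at$atomName %in% c("C", "O")) |
                              key %in% c("ASN CG", "ASN OD1",
                                         "GLN CD", "GLN OE1")),
        Peptide = as.numeric(isStd &
                             at$atomName %in% c("N", "CA", "C", "O")),
        as.numeric(key %in% CHEM_GROUPS[[nm]])),
      AtomProperties = {
        base <- sub("_[A-Z]+$", "", nm)
        v <- scalars[[base]]
        if (nzchar(pp)) {
          el <- sub("^element=", "", pp)
          v * as.numeric(element == el)
        } else v
      },
      ResidueName = switch(nm,
        OTHER = as.numeric(!res %in% c(STANDARD_AA, "HOH")),
        as.numeric(res == nm)),
      ResidueProperties = as.numeric(res %in% RESIDUE_CLASSES[[nm]]),
      SecondaryStructure = as.numeric(ssAtom == nm),
      stop("unknown property group: ", g))
  }
  M
}

#' Per-atom contributions to the catalog properties
#'
#' Returns, for one atom of a structure, the sparse set of catalog
#' properties it contributes to and the contributed values (1 for matching
#' indicators; the per-atom value for scalar accumulators).
#'
#' @param structure a [ProteinStructure-class].
#' @param atomIndex row index into `atomRecords(structure)`.
#' @param catalog a [PropertyCatalog-class].
#' @return named numeric of the non-zero contributions.
#' @export
atomContributions <- function(structure, atomIndex,
                              catalog = defaultPropertyCatalog()) {
  stopifnot(length(atomIndex) == 1L, atomIndex >= 1L,
            atomIndex <= nrow(structure@atoms))
  sub <- structure
  sub@atoms <- structure@atoms[atomIndex, , drop = FALSE]
  v <- .atomPropertyMatrix(sub, catalog)[1, ]
  v[v != 0]
}
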