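#' Parse a PDB-format structure
#'
#' Reads ATOM/HETATM records (via \pkg{bio3d}), captures the REMARK 2
#' resolution when present, translates HELIX/SHEET header records into
#' per-residue secondary-structure labels, and applies the alternate-location
#' policy: for duplicated (chain, residue, atom name) records the
#' highest-occupancy altloc is kept, ties going to the first in file order.
#'
#' For NMR-style multi-model files only the first model is read.
#'
#' @param x either a path to a PDB file or a character vector of PDB lines
#'   (a single string containing newlines is also accepted).
#' @param id structure identifier; defaults to the file base name or "struct".
#' @return A [ProteinStructure-class].
#' @export
parsePDB <- function(x, id = NULL) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
    if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(x))
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
    if (is.null(id)) id <- "struct"
  }
  if (!any(grepl("^(ATOM  |HETATM)", lines)))
    stop("no ATOM or HETATM records found: empty structure")

  # malformed coordinate fields -> record-level error with line number
  reclines <- grep("^(ATOM  |HETATM)", lines)
  for (i in reclines) {
    fields <- substring(lines[i], c(31, 39, 47), c(38, 46, 54))
    if (anyNA(suppressWarnings(as.numeric(fields))))
      stop(sprintf("malformed coordinate field at line %d: '%s'", i,
                   lines[i]))
  }

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- suppressWarnings(bio3d::read.pdb(tmp, rm.alt = FALSE,
                                          multi = FALSE, verbose = FALSE))
  a <- pdb$atom
  atoms <- data.frame(
    serial = as.integer(a$eleno),
    atomName = as.character(a$elety),
    element = "",
    residueName = as.character(a$resid),
    chain = ifelse(is.na(a$chain), "", as.character(a$chain)),
    resno = as.integer(a$resno),
    icode = ifelse(is.na(a$insert), "", as.character(a$insert)),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    bfactor = ifelse(is.na(a$b), 0, a$b),
    isHetero = a$type == "HETATM",
    altloc = ifelse(is.na(a$alt), "", as.character(a$alt)),
    stringsAsFactors = FALSE
  )
  atoms$element <- .elementOf(atoms$atomName, a$elesy, atoms$isHetero)

  # altloc policy: highest occupancy per (chain, resno, icode, atomName),
  # ties -> first in file order (stable order of ave/max scan)
  if (any(nzchar(atoms$altloc))) {
    grp <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$atomName,
                 sep = "\r")
    keep <- rep(TRUE, nrow(atoms))
    for (g in unique(grp[duplicated(grp)])) {
      idx <- which(grp == g)
      best <- idx[which.max(atoms$occupancy[idx])]
      keep[setdiff(idx, best)] <- FALSE
    }
    atoms <- atoms[keep, , drop = FALSE]
    rownames(atoms) <- NULL
  }
  atoms$altloc <- NULL

  resolution <- NA_real_
  rl <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rl)) {
    tail <- sub("^REMARK\\s+2\\s+RESOLUTION\\.?\\s*", "", rl[1])
    m <- regmatches(tail, regexpr("[0-9]+\\.?[0-9]*", tail))
    if (length(m) && nzchar(m)) resolution <- as.numeric(m)
  }

  struct <- new("ProteinStructure", atoms = atoms,
                ssLabels = .emptySS(), resolution = resolution, id = id)
  struct@ssLabels <- .headerSS(struct, pdb)
  struct
}

.emptySS <- function() {
  data.frame(chain = character(), resno = integer(), icode = character(),
             ss = character(), stringsAsFactors = FALSE)
}

.residueTable <- function(structure) {
  at <- structure@atoms
  key <- paste(at$chain, at$resno, at$icode, sep = "\r")
  first <- !duplicated(key)
  data.frame(chain = at$chain[first], resno = at$resno[first],
             icode = at$icode[first],
             residueName = at$residueName[first],
             isHetero = at$isHetero[first],
             stringsAsFactors = FALSE)
}

# header-derived labels: HELIX class 1 -> 4Helix, 3 -> 3Helix, 5 -> 5Helix,
# other classes -> Coil; SHEET -> Strand.  When any HELIX/SHEET header is
# present, uncovered polymer residues default to Coil, otherwise Unknown.
# HETATM-only residues are always Het.
.headerSS <- function(structure, pdb) {
  res <- .residueTable(structure)
  ss <- ifelse(res$isHetero, "Het", "Unknown")
  hasHeader <- FALSE
  spans <- list()
  if (!is.null(pdb$helix) && length(pdb$helix$start)) {
    hasHeader <- TRUE
    hcode <- c("1" = "4Helix", "3" = "3Helix", "5" = "5Helix")
    for (i in seq_along(pdb$helix$start)) {
      code <- hcode[as.character(pdb$helix$type[i])]
      if (is.na(code)) code <- "Coil"
      spans[[length(spans) + 1L]] <-
        list(chain = pdb$helix$chain[i], from = pdb$helix$start[i],
             to = pdb$helix$end[i], code = code)
    }
  }
  if (!is.null(pdb$sheet) && length(pdb$sheet$start)) {
    hasHeader <- TRUE
    for (i in seq_along(pdb$sheet$start))
      spans[[length(spans) + 1L]] <-
        list(chain = pdb$sheet$chain[i], from = pdb$sheet$start[i],
             to = pdb$sheet$end[i], code = "Strand")
  }
  if (hasHeader) ss[!res$isHetero] <- "Coil"
  for (sp in spans) {
    hit <- res$chain == sp$chain & res$resno >= sp$from &
      res$resno <= sp$to & !res$isHetero
    ss[hit] <- sp$code
  }
  data.frame(chain = res$chain, resno = res$resno, icode = res$icode,
             ss = ss, stringsAsFactors = FALSE)
}

#' Serialize a structure back to PDB text
#'
#' Writes ATOM/HETATM records (plus a REMARK 2 line when the resolution is
#' known) sufficient to round-trip atom names, residues and coordinates to
#' three decimals.
#'
#' @param structure a [ProteinStructure-class].
#' @return character vector of PDB lines.
#' @export
writePDB <- function(structure) {
  at <- structure@atoms
  out <- character(0)
  if (!is.na(structure@resolution))
    out <- c(out, sprintf(
      "REMARK   2 RESOLUTION.  %6.2f ANGSTROMS.", structure@resolution))
  nm <- ifelse(nchar(at$atomName) < 4L, paste0(" ", at$atomName),
               at$atomName)
  out <- c(out, sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(at$isHetero, "HETATM", "ATOM"), at$serial, nm, "",
    at$residueName, at$chain, at$resno, at$icode, at$x, at$y, at$z,
    at$occupancy, at$bfactor,
    ifelse(at$element == "OTHER", "", at$element)))
  c(out, "END")
}

#' Extract a chain's amino-acid sequence
#'
#' One letter per distinct polymer residue of the chain, in file order.
#' A residue belongs to the chain sequence when it has a CA atom and is not
#' water; non-standard residues (e.g. MSE) are encoded as "X".
#'
#' @param structure a [ProteinStructure-class].
#' @param chainId chain identifier.
#' @return A [ChainSequence-class].
#' @export
extractSequence <- function(structure, chainId) {
  at <- structure@atoms
  chains <- unique(at$chain)
  if (!chainId %in% chains)
    stop(sprintf("chain '%s' not found; available chains: %s", chainId,
                 paste(sort(chains), collapse = ", ")))
  sel <- at$chain == chainId & at$atomName == "CA" &
    at$residueName != "HOH" & at$element == "C"
  sub <- at[sel, , drop = FALSE]
  key <- paste(sub$resno, sub$icode, sep = "\r")
  sub <- sub[!duplicated(key), , drop = FALSE]
  letters1 <- unname(AA_321[sub$residueName])
  letters1[is.na(letters1)] <- "X"
  new("ChainSequence", chainId = chainId,
      sequence = paste(letters1, collapse = ""),
      residueKeys = data.frame(resno = sub$resno, icode = sub$icode,
                               stringsAsFactors = FALSE))
}

#' Read a per-residue secondary-structure sidecar table
#'
#' Tab-separated columns `chain`, `resnum`, `icode`, `ss_code`.  `ss_code`
#' may be one of the descriptor codes (3Helix, 4Helix, 5Helix, Bridge,
#' Strand, Turn, Bend, Coil, Het, Unknown) or a DSSP letter, mapped as
#' G->3Helix, H->4Helix, I->5Helix, B->Bridge, E->Strand, T->Turn, S->Bend
#' and ""/"-"/"C"->Coil.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns chain, resno, icode, ss.
#' @export
readSSSidecar <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("chain", "resnum", "ss_code")
  if (!all(need %in% names(tab)))
    stop("sidecar must have columns chain, resnum, icode, ss_code")
  if (is.null(tab$icode)) tab$icode <- ""
  tab$icode[is.na(tab$icode)] <- ""
  dssp <- c(G = "3Helix", H = "4Helix", I = "5Helix", B = "Bridge",
            E = "Strand", T = "Turn", S = "Bend", C = "Coil",
            "-" = "Coil", " " = "Coil")
  ss <- tab$ss_code
  ss[!nzchar(ss)] <- "Coil"
  mapped <- dssp[ss]
  ss <- ifelse(ss %in% SS_CODES, ss, mapped)
  if (anyNA(ss))
    stop("unknown ss_code value(s): ",
         paste(unique(tab$ss_code[is.na(ss)]), collapse = ", "))
  data.frame(chain = tab$chain, resno = as.integer(tab$resnum),
             icode = tab$icode, ss = unname(ss), stringsAsFactors = FALSE)
}

#' Assign per-residue secondary-structure labels
#'
#' Finalizes the structure's labels: header-derived labels (already present
#' from [parsePDB]) are overridden by the sidecar where given; residues with
#' no label get Unknown; HETATM-only residues get Het.  Sidecar entries that
#' reference a residue absent from the structure are skipped with a warning.
#'
#' @param structure a [ProteinStructure-class].
#' @param sidecar optional data.frame as returned by [readSSSidecar].
#' @return The structure with updated `ssLabels`.
#' @export
assignSecondaryStructure <- function(structure, sidecar = NULL) {
  res <- .residueTable(structure)
  cur <- structure@ssLabels
  key <- paste(res$chain, res$resno, res$icode, sep = "\r")
  curKey <- paste(cur$chain, cur$resno, cur$icode, sep = "\r")
  ss <- cur$ss[match(key, curKey)]
  ss[is.na(ss)] <- ifelse(res$isHetero[is.na(ss)], "Het", "Unknown")
  if (!is.null(sidecar) && nrow(sidecar)) {
    scKey <- paste(sidecar$chain, sidecar$resno, sidecar$icode, sep = "\r")
    hit <- match(scKey, key)
    if (anyNA(hit)) {
      bad <- which(is.na(hit))
      warning(sprintf("sidecar references %d unknown residue(s); skipped",
                      length(bad)))
    }
    ok <- !is.na(hit)
    ss[hit[ok]] <- sidecar$ss[ok]
  }
  structure@ssLabels <- data.frame(chain = res$chain, resno = res$resno,
                                   icode = res$icode, ss = ss,
                                   stringsAsFactors = FALSE)
  structure
}
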