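#' Parse a PROSITE-style pattern
#'
#' Standard PROSITE grammar: elements separated by `-`; a single letter is a
#' literal; `x` matches any residue; `[ABC]` matches any of the listed
#' residues; `{ABC}` matches anything but the listed residues; an element
#' may carry a repeat `(n)` or `(n,m)`; `<` anchors the match to the
#' sequence start, `>` to the end; a trailing `.` is ignored.
#'
#' @param text the pattern string, e.g. `"[LIVMFGAC]-x(2)-D-[ST]-G"`.
#' @return list with components `elements` (each a list with `type` in
#'   literal/class/exclusion/any, `residues`, `min`, `max`), `anchorStart`,
#'   `anchorEnd`.
#' @export
parsePrositePattern <- function(text) {
  pat <- sub("\\.$", "", trimws(text))
  anchorStart <- startsWith(pat, "<")
  if (anchorStart) pat <- substring(pat, 2L)
  anchorEnd <- endsWith(pat, ">")
  if (anchorEnd) pat <- substring(pat, 1L, nchar(pat) - 1L)
  if (!nzchar(pat)) stop("empty pattern")
  parts <- strsplit(pat, "-", fixed = TRUE)[[1]]
  elements <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    el <- parts[i]
    if (!nzchar(el)) stop(sprintf("empty element at position %d", i))
    minRep <- 1L; maxRep <- 1L
    repMatch <- regmatches(el, regexpr("\\(([0-9]+)(,[0-9]+)?\\)$", el))
    if (length(repMatch) && nzchar(repMatch)) {
      el <- substring(el, 1L, nchar(el) - nchar(repMatch))
      nums <- as.integer(strsplit(gsub("[()]", "", repMatch), ",")[[1]])
      minRep <- nums[1]
      maxRep <- if (length(nums) > 1L) nums[2] else nums[1]
      if (minRep < 1L || maxRep < minRep)
        stop(sprintf("invalid repeat count in element %d: %s", i,
                     parts[i]))
    }
    if (grepl("[(){}\\[\\]]", substring(el, 2L, nchar(el) - 1L),
              perl = TRUE) &&
        !(startsWith(el, "[") || startsWith(el, "{")))
      stop(sprintf("malformed element %d: %s", i, parts[i]))
    if (el == "x" || el == "X") {
      elements[[i]] <- list(type = "any", residues = character(),
                            min = minRep, max = maxRep)
    } else if (startsWith(el, "[")) {
      if (!endsWith(el, "]"))
        stop(sprintf("unbalanced '[' in element %d: %s", i, parts[i]))
      res <- strsplit(substring(el, 2L, nchar(el) - 1L), "")[[1]]
      if (!length(res)) stop(sprintf("empty class in element %d", i))
      elements[[i]] <- list(type = "class", residues = toupper(res),
                            min = minRep, max = maxRep)
    } else if (startsWith(el, "{")) {
      if (!endsWith(el, "}"))
        stop(sprintf("unbalanced '{' in element %d: %s", i, parts[i]))
      res <- strsplit(substring(el, 2L, nchar(el) - 1L), "")[[1]]
      if (!length(res)) stop(sprintf("empty exclusion in element %d", i))
      elements[[i]] <- list(type = "exclusion", residues = toupper(res),
                            min = minRep, max = maxRep)
    } else if (nchar(el) == 1L && grepl("^[A-Za-z]$", el)) {
      elements[[i]] <- list(type = "literal", residues = toupper(el),
                            min = minRep, max = maxRep)
    } else {
      stop(sprintf("cannot parse element %d: '%s'", i, parts[i]))
    }
  }
  list(elements = elements, anchorStart = anchorStart,
       anchorEnd = anchorEnd)
}

#' Construct a SitePattern
#'
#' @param name site name, e.g. "ASP_PROTEASE".
#' @param pattern PROSITE grammar string.
#' @param conservedIndex 1-based position of the conserved residue within a
#'   matched span.
#' @param residueName 3-letter code of the conserved residue.
#' @param functionalAtom PDB atom name the microenvironment is centered on.
#' @return A [SitePattern-class].
#' @export
SitePattern <- function(name, pattern, conservedIndex, residueName,
                        functionalAtom) {
  parsed <- parsePrositePattern(pattern)
  obj <- new("SitePattern", name = name, pattern = pattern,
             elements = parsed$elements,
             conservedIndex = as.integer(conservedIndex),
             residueName = toupper(residueName),
             functionalAtom = toupper(functionalAtom))
  attr(obj@elements, "anchorStart") <- parsed$anchorStart
  attr(obj@elements, "anchorEnd") <- parsed$anchorEnd
  obj
}

#' Read a site-pattern definition table
#'
#' Tab-separated columns: `name`, `pattern`, `conserved_index`,
#' `residue_name`, `functional_atom`.  Rows whose functional atom cannot
#' occur in the stated residue (e.g. a histidine listed with atom SG) are
#' kept but flagged with a warning, mirroring known defects in published
#' site tables.
#'
#' @param path path to the TSV file.
#' @return named list of [SitePattern-class] objects.
#' @export
readPatternTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "pattern", "conserved_index", "residue_name",
            "functional_atom")
  if (!all(need %in% names(tab)))
    stop("pattern table must have columns ", paste(need, collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(tab))) {
    sp <- SitePattern(tab$name[i], tab$pattern[i], tab$conserved_index[i],
                      tab$residue_name[i], tab$functional_atom[i])
    if (!.atomPlausibleForResidue(sp@residueName, sp@functionalAtom))
      warning(sprintf(
        "site %s: atom %s does not occur in residue %s; row kept as given",
        sp@name, sp@functionalAtom, sp@residueName))
    out[[sp@name]] <- sp
  }
  out
}

# side-chain heavy atoms per standard residue (for validation only)
.atomPlausibleForResidue <- function(res, atom) {
  sidechains <- list(
    ALA = "CB", ARG = c("CB","CG","CD","NE","CZ","NH1","NH2"),
    ASN = c("CB","CG","OD1","ND2"), ASP = c("CB","CG","OD1","OD2"),
    CYS = c("CB","SG"), GLN = c("CB","CG","CD","OE1","NE2"),
    GLU = c("CB","CG","CD","OE1","OE2"), GLY = character(),
    HIS = c("CB","CG","ND1","CD2","CE1","NE2"),
    ILE = c("CB","CG1","CG2","CD1"), LEU = c("CB","CG","CD1","CD2"),
    LYS = c("CB","CG","CD","CE","NZ"), MET = c("CB","CG","SD","CE"),
    PHE = c("CB","CG","CD1","CD2","CE1","CE2","CZ"), PRO = c("CB","CG","CD"),
    SER = c("CB","OG"), THR = c("CB","OG1","CG2"),
    TRP = c("CB","CG","CD1","CD2","NE1","CE2","CE3","CZ2","CZ3","CH2"),
    TYR = c("CB","CG","CD1","CD2","CE1","CE2","CZ","OH"),
    VAL = c("CB","CG1","CG2"))
  if (!res %in% names(sidechains)) return(TRUE)
  atom %in% c(BACKBONE_ATOMS, sidechains[[res]])
}

# all (start, end) spans of the element list matching seq, overlaps allowed
.matchSpans <- function(elements, seqChars, anchorStart, anchorEnd) {
  n <- length(seqChars)
  elMatch <- function(el, ch) {
    switch(el$type,
      any = TRUE,
      literal = ch == el$residues,
      class = ch %in% el$residues,
      exclusion = !(ch %in% el$residues))
  }
  spans <- list()
  starts <- if (anchorStart) 1L else seq_len(n)
  for (s in starts) {
    # ends[k] = set of positions after consuming elements 1..k
    frontier <- s
    for (el in elements) {
      nxt <- integer(0)
      for (p in frontier) {
        # consume between el$min and el$max residues starting at p
        q <- p
        ok <- TRUE
        for (r in seq_len(el$min)) {
          if (q > n || !elMatch(el, seqChars[q])) { ok <- FALSE; break }
          q <- q + 1L
        }
        if (!ok) next
        nxt <- c(nxt, q)
        if (el$max > el$min) {
          for (r in seq_len(el$max - el$min)) {
            if (q > n || !elMatch(el, seqChars[q])) break
            q <- q + 1L
            nxt <- c(nxt, q)
          }
        }
      }
      frontier <- unique(nxt)
      if (!length(frontier)) break
    }
    for (q in frontier) {
      if (anchorEnd && q != n + 1L) next
      spans[[length(spans) + 1L]] <- c(s, q - 1L)
    }
  }
  spans
}

#' Match a site pattern against a chain sequence
#'
#' Reports every distinct matched span (overlaps allowed; with
#' variable-length elements one start offset can yield several spans).  For
#' each span the conserved position (the `conservedIndex`-th residue of the
#' span) is resolved to its residue key; spans whose conserved residue does
#' not carry the pattern's residue type are dropped with a warning.
#'
#' @param pattern a [SitePattern-class].
#' @param chainSeq a [ChainSequence-class].
#' @return data.frame with one row per match: chain, start (0-based), end
#'   (0-based, inclusive), span, resno, icode.
#' @export
matchSitePattern <- function(pattern, chainSeq) {
  seqChars <- strsplit(chainSeq@sequence, "")[[1]]
  anchorStart <- isTRUE(attr(pattern@elements, "anchorStart"))
  anchorEnd <- isTRUE(attr(pattern@elements, "anchorEnd"))
  spans <- .matchSpans(pattern@elements, seqChars, anchorStart, anchorEnd)
  out <- data.frame(chain = character(), start = integer(),
                    end = integer(), span = character(), resno = integer(),
                    icode = character(), stringsAsFactors = FALSE)
  expected <- unname(AA_321[pattern@residueName])
  nDropped <- 0L
  for (sp in spans) {
    consPos <- sp[1] + pattern@conservedIndex - 1L
    if (consPos > sp[2]) next  # span shorter than the conserved index
    if (!is.na(expected) && seqChars[consPos] != expected) {
      nDropped <- nDropped + 1L
      next
    }
    out[nrow(out) + 1L, ] <- list(
      chainSeq@chainId, sp[1] - 1L, sp[2] - 1L,
      paste(seqChars[sp[1]:sp[2]], collapse = ""),
      chainSeq@residueKeys$resno[consPos],
      chainSeq@residueKeys$icode[consPos])
  }
  if (nDropped)
    warning(sprintf(
      "%s: %d match(es) dropped; conserved residue was not %s",
      pattern@name, nDropped, pattern@residueName))
  out
}
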