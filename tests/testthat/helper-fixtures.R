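# Shared toy builders and independent oracles for the test suite.

# a minimal three-residue peptide-ish structure around the origin
toyThreeAtoms <- function() {
  data.frame(atomName = c("CA", "N", "O"),
             residueName = c("ALA", "GLY", "SER"),
             chain = "A", resno = 1:3, radius = c(0.5, 2.0, 7.6))
}

# random toy structure spec: nAtoms at random radii/directions
randomToySpec <- function(nAtoms, maxRadius = 10) {
  dir <- matrix(rnorm(3 * nAtoms), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  data.frame(atomName = sample(c("CA", "CB", "N", "O", "SG"), nAtoms,
                               replace = TRUE),
             residueName = sample(c("ALA", "CYS", "ASP", "HIS"), nAtoms,
                                  replace = TRUE),
             chain = "A", resno = seq_len(nAtoms),
             radius = runif(nAtoms, 0, maxRadius),
             ux = dir[, 1], uy = dir[, 2], uz = dir[, 3])
}

# --- PROSITE oracle: expand the grammar to a regular expression and test
# every substring (all starts, all lengths) for a full anchored match.
prositeToRegex <- function(text) {
  pat <- sub("\\.$", "", trimws(text))
  anchorStart <- startsWith(pat, "<")
  if (anchorStart) pat <- substring(pat, 2L)
  anchorEnd <- endsWith(pat, ">")
  if (anchorEnd) pat <- substring(pat, 1L, nchar(pat) - 1L)
  parts <- strsplit(pat, "-", fixed = TRUE)[[1]]
  rx <- vapply(parts, function(el) {
    rep <- ""
    m <- regmatches(el, regexpr("\\(([0-9]+)(,[0-9]+)?\\)$", el))
    if (length(m) && nzchar(m)) {
      el <- substring(el, 1L, nchar(el) - nchar(m))
      rep <- sub("\\(", "{", sub("\\)", "}", m))
    }
    core <- if (el %in% c("x", "X")) "."
      else if (startsWith(el, "[")) el
      else if (startsWith(el, "{"))
        paste0("[^", substring(el, 2L, nchar(el) - 1L), "]")
      else el
    paste0(core, rep)
  }, character(1))
  list(regex = paste0(rx, collapse = ""), anchorStart = anchorStart,
       anchorEnd = anchorEnd)
}

oracleMatchSpans <- function(patternText, seqString) {
  o <- prositeToRegex(patternText)
  n <- nchar(seqString)
  spans <- list()
  starts <- if (o$anchorStart) 1L else seq_len(n)
  for (s in starts) {
    ends <- if (o$anchorEnd) n else s:n
    for (e in ends) {
      if (e < s) next
      sub <- substr(seqString, s, e)
      if (grepl(paste0("^(?:", o$regex, ")$"), sub, perl = TRUE))
        spans[[length(spans) + 1L]] <- c(s, e)
    }
  }
  spans
}

randomPrositePattern <- function() {
  nEl <- sample(2:4, 1)
  els <- vapply(seq_len(nEl), function(i) {
    core <- switch(sample(3, 1),
      sample(c("A", "C", "D", "G", "H", "K"), 1),
      paste0("[", paste(sample(c("A", "C", "D", "G", "H", "K"),
                               sample(2:3, 1)), collapse = ""), "]"),
      "x")
    rep <- switch(sample(3, 1), "",
      sprintf("(%d)", sample(1:2, 1)),
      sprintf("(%d,%d)", 1, sample(2:3, 1)))
    paste0(core, rep)
  }, character(1))
  paste(els, collapse = "-")
}

randomSequence <- function(len)
  paste(sample(c("A", "C", "D", "G", "H", "K"), len, replace = TRUE),
        collapse = "")

# --- naive Bayes oracle: literal Bayes computation with explicit loops,
# independent of the package's binning/likelihood code path.
nbOracle <- function(X, y, xNew, prior, nBins = 5L) {
  nf <- nrow(X)
  pPosNum <- log(prior); pNegNum <- log(1 - prior)
  for (f in seq_len(nf)) {
    v <- X[f, ]
    lo <- min(v); hi <- max(v)
    binOf <- function(val) {
      if (hi == lo) return(3L)
      b <- 1L
      for (k in 1:(nBins - 1L))
        if (val >= lo + (hi - lo) * k / nBins) b <- b + 1L
      b
    }
    b <- binOf(xNew[f])
    for (cls in c("positive", "negative")) {
      idx <- which(y == cls)
      cnt <- 0L
      for (i in idx) if (binOf(v[i]) == b) cnt <- cnt + 1L
      lp <- log((cnt + 1) / (length(idx) + nBins))
      if (cls == "positive") pPosNum <- pPosNum + lp
      else pNegNum <- pNegNum + lp
    }
  }
  1 / (1 + exp(pNegNum - pPosNum))
}

# --- confusion-matrix oracle: explicit counts at a threshold
confusionOracle <- function(labels, p, threshold) {
  call <- p >= threshold
  pos <- labels == "positive"
  c(tp = sum(call & pos), fp = sum(call & !pos),
    fn = sum(!call & pos), tn = sum(!call & !pos))
}

fixturePath <- function(name) test_path("fixtures", name)
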