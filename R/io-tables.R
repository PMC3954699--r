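#' Export / import a training set as TSV
#'
#' One row per example: provenance columns, `label`, then one column per
#' feature slot.  The catalog version and recorded seed travel in `#`
#' header comments.
#'
#' @param train a [SiteTrainingSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrainingSet <- function(train, path) {
  df <- cbind(train@provenance, label = train@labels,
              as.data.frame(t(train@features), check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# catalogVersion: ", train@catalogVersion),
               paste0("# seed: ", train@seed)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrainingSet
#' @param path path to a TSV written by [writeTrainingSet].
#' @return [readTrainingSet] returns a [SiteTrainingSet-class].
#' @export
readTrainingSet <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getTag <- function(tag, default) {
    m <- grep(paste0("^#\\s*", tag, ":"), hdr, value = TRUE)
    if (length(m)) trimws(sub(".*:", "", m[1])) else default
  }
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                          check.names = FALSE, stringsAsFactors = FALSE)
  provCols <- c("structureId", "chain", "resno", "icode", "atom")
  featCols <- setdiff(names(df), c(provCols, "label"))
  feat <- t(as.matrix(df[, featCols, drop = FALSE]))
  seed <- suppressWarnings(as.integer(getTag("seed", NA)))
  SiteTrainingSet(feat, labels = df$label,
                  provenance = df[, provCols, drop = FALSE],
                  catalogVersion = getTag("catalogVersion", "unversioned"),
                  seed = seed)
}

#' Write chain sequences as FASTA
#'
#' @param chainSeqs list of [ChainSequence-class] objects.
#' @param path output path.
#' @param id structure id used in the headers.
#' @return `path`, invisibly.
#' @export
writeChainFasta <- function(chainSeqs, path, id = "struct") {
  lines <- unlist(lapply(chainSeqs, function(cs)
    c(sprintf(">%s_%s", id, cs@chainId), cs@sequence)))
  writeLines(lines, path)
  invisible(path)
}

#' Write an evaluation report row
#'
#' TSV with columns site, method, param, threshold, precision, recall,
#' ci_low, ci_high, tp, fp, fn, tn; the confidence interval is the Wilson
#' interval on the recall.
#'
#' @param site site name.
#' @param method classifier kind.
#' @param param selected parameter value.
#' @param op operating point (single-row data.frame from
#'   [selectThreshold]).
#' @param path output path.
#' @param level confidence level for the recall interval.
#' @return the report data.frame, invisibly.
#' @export
writeEvaluationReport <- function(site, method, param, op, path,
                                  level = 0.95) {
  ci <- recallCI(op$tp, op$tp + op$fn, level = level)
  rep <- data.frame(site = site, method = method, param = param,
                    threshold = op$threshold, precision = op$precision,
                    recall = op$recall, ci_low = ci[["lower"]],
                    ci_high = ci[["upper"]], tp = op$tp, fp = op$fp,
                    fn = op$fn, tn = op$tn)
  utils::write.table(rep, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(rep)
}

#' Write a run manifest beside an output file
#'
#' Records the inputs, package version, seed and parameters of a run as
#' JSON at `<out>.manifest.json`.
#'
#' @param out the output file the manifest describes.
#' @param inputs named list of input paths / descriptions.
#' @param seed integer seed used.
#' @param params named list of parameters.
#' @return the manifest path, invisibly.
#' @export
writeRunManifest <- function(out, inputs = list(), seed = NA_integer_,
                             params = list()) {
  path <- paste0(out, ".manifest.json")
  jsonlite::write_json(list(
    output = out, inputs = inputs, seed = seed, params = params,
    package = "SiteScan",
    version = as.character(utils::packageVersion("SiteScan")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
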