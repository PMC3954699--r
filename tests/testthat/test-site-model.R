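# a small structure whose CYS SG microenvironments are the scan candidates
scanFixture <- function() {
  spec <- data.frame(
    atomName = c("CA", "SG", "CA", "SG", "CA", "SG", "CA", "OD2"),
    residueName = c("CYS", "CYS", "CYS", "CYS", "CYS", "CYS", "ASP", "ASP"),
    chain = "A", resno = c(1, 1, 2, 2, 3, 3, 4, 4),
    radius = c(1, 2, 10, 11, 20, 21, 30, 31))
  assignSecondaryStructure(parsePDB(makeToyPDB(spec), id = "scanToy"))
}

# tiny descriptor-space training set: positives near the shell-1 signature
# of a CYS SG site, negatives elsewhere
descriptorTrainingSet <- function(structure, nNoise = 40, seed = 71) {
  at <- atomRecords(structure)
  sg <- at[at$atomName == "SG", ]
  centers <- as.matrix(sg[, c("x", "y", "z")])
  M <- featurize(structure, centers)
  set.seed(seed)
  # jittered copies of the first SG environment as positives, flat noise
  # vectors as negatives
  pos <- t(M[rep(1, 20), ] + matrix(abs(rnorm(20 * ncol(M), 0, 0.01)),
                                    20))
  neg <- matrix(abs(rnorm(480 * nNoise, 0, 0.01)), nrow = 480)
  feats <- cbind(pos, neg)
  rownames(feats) <- colnames(M)
  SiteTrainingSet(feats, c(rep("positive", 20), rep("negative", nNoise)),
                  catalogVersion = "v1")
}

test_that("trainSiteModel wires grid search, thresholding and refit together", {
  ts <- makeGaussianSites(25, 100, dim = 8, dPrime = 7, seed = 31)
  m <- trainSiteModel(ts, "TOY_SITE", "nb", grid = c(0.2, 0.5),
                      targetPrecision = 0.99, seed = 2,
                      residueName = "CYS", functionalAtom = "SG")
  expect_s4_class(m, "SiteModel")
  expect_true(m@param %in% c(0.2, 0.5))
  expect_gt(decisionThreshold(m), 0)
  expect_lt(decisionThreshold(m), 1)
  expect_gte(m@recall, 0.9)        # separable toy
  expect_s4_class(m@classifier, "NBModel")
  expect_equal(nrow(attr(m, "gridSummary")), 2L)
})

test_that("scanStructure hits carry probabilities, calls and sorted order", {
  s <- scanFixture()
  ts <- descriptorTrainingSet(s)
  model <- trainSiteModel(ts, "CYS_TOY", "nb", grid = 0.5, seed = 3,
                          residueName = "CYS", functionalAtom = "SG")
  hits <- scanStructure(s, model)
  expect_equal(nrow(hits), 3L)               # one per CYS with an SG
  expect_equal(hits$atomName, rep("SG", 3))
  expect_true(all(diff(hits$pPositive) <= 0))  # sorted descending
  expect_equal(hits$call, hits$pPositive >= decisionThreshold(model))
  # the residue whose environment matches training positives is called
  expect_true(hits$call[1])
  expect_equal(hits$resno[1], 1L)

  # no residues of the model's type -> empty hit list
  other <- assignSecondaryStructure(parsePDB(makeToyPDB(
    data.frame(atomName = "CA", residueName = "GLY", chain = "A",
               resno = 1, radius = 1)), id = "none"))
  expect_equal(nrow(scanStructure(other, model)), 0L)

  # residues missing the functional atom are skipped with a message
  noSG <- assignSecondaryStructure(parsePDB(makeToyPDB(
    data.frame(atomName = c("CA", "CB"), residueName = "CYS", chain = "A",
               resno = 1, radius = c(1, 2))), id = "noSG"))
  expect_message(h2 <- scanStructure(noSG, model), "lacks atom")
  expect_equal(nrow(h2), 0L)

  # catalog version mismatch refuses to scan
  wrongCat <- defaultPropertyCatalog()
  wrongCat@version <- "v999"
  expect_error(scanStructure(s, model, catalog = wrongCat), "mismatch")
})

test_that("site models round-trip through JSON byte-faithfully", {
  ts <- makeGaussianSites(20, 60, dim = 8, dPrime = 7, seed = 37)
  probe <- t(featureMatrix(ts)[, 1:10])
  for (kind in c("nb", "svm")) {
    m <- trainSiteModel(ts, "RT_SITE", kind,
                        grid = if (kind == "nb") 0.5 else 1, seed = 5,
                        residueName = "CYS", functionalAtom = "SG")
    f <- withr::local_tempfile(fileext = ".json")
    saveSiteModel(m, f)
    m2 <- loadSiteModel(f)
    expect_equal(m2@site, "RT_SITE")
    expect_equal(m2@kind, kind)
    expect_equal(decisionThreshold(m2), decisionThreshold(m))
    expect_equal(m2@param, m@param)
    p1 <- predictProba(m, probe)[, "positive"]
    p2 <- predictProba(m2, probe)[, "positive"]
    expect_equal(p1, p2, tolerance = 1e-9)
  }
  # version guard on load
  m <- trainSiteModel(ts, "RT_SITE", "nb", grid = 0.5, seed = 5)
  f <- withr::local_tempfile(fileext = ".json")
  saveSiteModel(m, f)
  wrongCat <- defaultPropertyCatalog()
  wrongCat@version <- "v999"
  expect_error(loadSiteModel(f, catalog = wrongCat), "mismatch")
  # corrupted payload
  f2 <- withr::local_tempfile(fileext = ".json")
  writeLines("{\"format\": \"something-else\"}", f2)
  expect_error(loadSiteModel(f2), "not a SiteScan model")
})

test_that("training sets round-trip through their TSV export", {
  ts <- makeGaussianSites(5, 7, dim = 6, dPrime = 3, seed = 41)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeTrainingSet(ts, f)
  ts2 <- readTrainingSet(f)
  expect_equal(featureMatrix(ts2), featureMatrix(ts), tolerance = 1e-12)
  expect_equal(exampleLabels(ts2), exampleLabels(ts))
  expect_equal(catalogVersion(ts2), catalogVersion(ts))
})

cliPath <- system.file("scripts", "sitescan.R", package = "SiteScan")

runCLI <- function(...) {
  out <- tempfile()
  status <- system2("Rscript", c(cliPath, ...), stdout = out, stderr = out)
  list(status = status, log = readLines(out, warn = FALSE))
}

test_that("the CLI trains, evaluates and scans with reproducible output", {
  skip_if(cliPath == "", "CLI script not installed")
  dir <- withr::local_tempdir()
  # training data from the packaged generator, exported as TSV
  s <- scanFixture()
  ts <- descriptorTrainingSet(s)
  trainTSV <- file.path(dir, "train.tsv")
  writeTrainingSet(ts, trainTSV)
  modelFile <- file.path(dir, "model.json")
  repFile <- file.path(dir, "report.tsv")
  res <- runCLI("train", "--training", trainTSV, "--site", "CYS_TOY",
                "--classifier", "nb", "--grid", "0.5", "--seed", "3",
                "--residue", "CYS", "--atom", "SG",
                "--model", modelFile, "--out", repFile)
  expect_equal(res$status, 0L)
  expect_true(file.exists(modelFile))
  rep <- read.delim(repFile)
  expect_equal(rep$site, "CYS_TOY")
  expect_true(rep$precision >= 0 && rep$precision <= 1)
  expect_true(file.exists(paste0(repFile, ".manifest.json")))

  # scan the toy structure with the trained model
  pdbFile <- file.path(dir, "scan.pdb")
  writeLines(writePDB(s), pdbFile)
  hitsFile <- file.path(dir, "hits.tsv")
  res2 <- runCLI("scan", "--pdb", pdbFile, "--model", modelFile,
                 "--out", hitsFile)
  expect_equal(res2$status, 0L)
  hits <- read.delim(hitsFile)
  expect_equal(nrow(hits), 3L)
  expect_true(all(c("pPositive", "call") %in% names(hits)))

  # identical invocation -> byte-identical hits TSV
  hitsFile2 <- file.path(dir, "hits2.tsv")
  res3 <- runCLI("scan", "--pdb", pdbFile, "--model", modelFile,
                 "--out", hitsFile2)
  expect_identical(readLines(hitsFile), readLines(hitsFile2))

  # failure paths exit non-zero with a diagnostic
  resBad <- runCLI("scan", "--pdb", "missing.pdb", "--model", modelFile,
                   "--out", file.path(dir, "x.tsv"))
  expect_gt(resBad$status, 0L)
  resCmd <- runCLI("frobnicate")
  expect_gt(resCmd$status, 0L)
})
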