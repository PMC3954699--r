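Package: SiteScan
Title: Atom-Centered Microenvironment Models for Protein Functional Site
    Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Annotates functional sites in protein structures from
    atom-centered physicochemical microenvironments.  Each candidate site
    is summarized as a 480-element descriptor (80 properties accumulated
    in six concentric 1.25 Angstrom shells around a functional atom),
    training examples are derived by matching PROSITE-style sequence
    patterns to chains of PDB structures, and two probabilistic
    classifiers (a binned naive Bayes model with a tunable class prior,
    and a linear support vector machine with calibrated posterior
    probabilities) are selected by stratified cross-validation to
    maximize recall at a target precision near 99 percent.  Includes
    tools to scan unannotated structures and report predicted site
    locations with posterior probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'catalog-data.R'
    'catalog.R'
    'classifiers-nb.R'
    'classifiers-svm.R'
    'evaluation.R'
    'fixtures.R'
    'io-tables.R'
    'microenvironment.R'
    'patterns.R'
    'site-examples.R'
    'site-model.R'
    'structure-io.R'
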