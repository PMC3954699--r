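---
title: "Microenvironment models for functional-site annotation: methods and design"
author: "SiteScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microenvironment models for functional-site annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SiteScan)
```

# The model

SiteScan treats a functional site as the physicochemical microenvironment
of one atom. The descriptor is purely geometric and additive: six
concentric shells of 1.25 Å around a center, and within each shell the sum
of 80 per-atom property contributions. Two consequences follow directly
and are enforced by tests: the descriptor is invariant under rigid motion
of the whole structure, and atoms at or beyond the 7.5 Å outer radius are
invisible to it. Shell boundaries are half-open, `[k·t, (k+1)·t)`, so every
distance below the outer radius falls in exactly one shell and a distance
of exactly 7.5 Å falls outside; an atom coinciding with the center sits in
shell 1, which keeps featurization a pure function of geometry.

Classification is two-class and probabilistic. The naive Bayes path
models each feature independently with five-bin histograms per class and
combines them with a tunable positive-class prior `P`; the decision
assigns the class with the larger posterior, and `P` is treated as the
model's top-level parameter rather than an estimate of prevalence —
prevalence in deployment (scanning all candidate residues of a structure)
is unknowable from the training design, which fixes the number of
negatives by fiat. The maximum-margin path is a soft-margin *linear* SVM
with cost parameter `C`; posterior probabilities come from the solver's
sigmoid calibration. Linearity is a deliberate restriction: with 480
partially redundant count features and a few hundred positives, a linear
decision boundary plus probability calibration is the highest-capacity
model the data support.

# Parameters that matter

| parameter | default | meaning |
|---|---|---|
| shells × thickness | 6 × 1.25 Å | descriptor support, outer radius 7.5 Å |
| catalog | v1, 80 properties | per-shell property roster (versioned TSV) |
| bins | 5 per feature | naive Bayes histogram resolution |
| prior grid | 0.01, 0.05, 0.1–0.9, 0.99 | candidate values of P |
| cost grid | 2^−5, 2^−3, …, 2^15 | candidate values of C |
| folds | 5 | stratified cross-validation |
| target precision | 0.99 | operating constraint for threshold selection |
| negatives | 50,000 | per-site negative sample size |

The 80-property catalog deserves comment. The property *groups* and their
member names are standard (atom types, chemical groups, atom scalars,
residue types, residue classes, secondary structure), but enumerating them
gives 55 names, not 80. The catalog resolves this by carrying per-element
variants of the five atom-level scalars (5 scalars × 5 element classes =
25 additional entries), which preserves the documented total of 80 per
shell while keeping every entry individually meaningful. Because the
precise roster is a convention, it is shipped as a versioned data file
rather than hard-coded: every feature vector and every trained model
records the catalog version, vector length is asserted against the catalog
size (never against a literal 480), and scanning refuses to mix versions.

The atom-level lookup tables behind the scalar properties are likewise
declared conventions: van der Waals sphere volumes from Bondi radii,
formal side-chain charges spread evenly over the charged group's atoms,
Kyte–Doolittle residue hydropathy divided evenly over side-chain heavy
atoms (glycine's value rides on its CA), mobility read from the B-factor
column, and solvent accessibility defaulting to zero unless a per-atom
sidecar supplies it — no geometric accessibility computation is attempted.
Accumulation is raw summation with no per-shell normalization; scale
handling belongs to the classifiers (the SVM standardizes features with
training-fold statistics, which travel with the model; naive Bayes bins
are scale-adaptive by construction).

# Secondary structure

No assignment method is prescribed by the descriptor. The parser
translates HELIX/SHEET header records when present (helix classes 1/3/5 to
4Helix/3Helix/5Helix, other classes to Coil, SHEET to Strand; covered
files default uncovered polymer residues to Coil, headerless files to
Unknown), and a DSSP-style per-residue sidecar table overrides header
labels wherever supplied (G/H/I/B/E/T/S/blank mapping). HETATM-only
residues are always Het. This makes the secondary-structure source an
explicit, replaceable input rather than a hidden dependency.

# The selection protocol

Model selection and threshold selection are both driven by pooled
cross-validation: stratified 5-fold assignment (per-fold class counts
within one example of each other — at a 1:100 imbalance unstratified folds
can easily lose all positives from a fold), one model per fold trained on
the remaining folds, and the held-out posteriors of all folds pooled and
evaluated as a single experiment. Pooling mixes probability scales from
five differently-trained models; the alternative (per-fold evaluation and
averaging) was rejected because per-fold positive counts are too small to
place a 99%-precision threshold at all.

On the pooled precision–recall curve (one operating point per distinct
predicted probability, calls at `p ≥ threshold`), exact 99% precision is
generally unattainable; the point minimizing `|precision − 0.99|` is
selected, with ties preferring precision at or above the target, then
higher recall, then higher threshold. The grid value whose selected point
has the highest recall wins; recall ties go to the smaller parameter
value. Where a selection rule based on minimum misclassifications would
disagree with recall-at-target-precision, the latter governs — it is the
operating constraint the system exists for — and misclassification counts
are recorded alongside for diagnostics. Recall uncertainty is reported as
a Wilson score interval, chosen over the normal approximation because the
recalls of interest live near 1, where the Wilson interval remains inside
[0, 1] and non-degenerate.

# Numerical choices

* Naive Bayes bins are equal-width over the pooled training range of each
  feature; out-of-range test values clamp into the outer bins. A constant
  feature receives a degenerate scheme whose middle bin catches the
  constant; its likelihood ratio is then 1 and the feature is inert, which
  is the desired behavior. Equal-frequency binning was considered and
  rejected: most descriptor features are zero-inflated counts, where
  quantile edges collapse.
* Laplace (+1) smoothing on bin counts prevents zero likelihoods from
  annihilating the 480-term product.
* Posteriors are computed in log space; the test suite exercises the case
  where both class products underflow double precision but their ratio is
  moderate.
* The SVM path keeps the complete parameter set (weights, offset, sigmoid
  coefficients, scaling statistics) extracted from the solver, so
  prediction is reproducible linear algebra and models serialize to plain
  JSON. The solver's probability calibration consumes the R random number
  stream, so a seed argument makes fits bit-reproducible; permuting
  training-example order changes results only within the solver's
  convergence tolerance.
* Posterior probabilities can saturate to exactly 0 or 1 in floating
  point; the stored decision threshold is clamped to (0, 1) by 1e-12
  without changing any `≥` comparison.
* Deduplication of "100% sequence similarity" is exact string equality of
  extracted chain sequences — the strictest deterministic reading. Best
  resolution wins within a group; unknown resolution loses to any numeric
  value; remaining ties go to the lexicographically smallest id, making
  the output independent of input order.
* Alternate locations keep the highest-occupancy copy (ties to file
  order); only the first NMR model is read.
* The conserved position of a pattern is resolved as the k-th residue of
  each matched span. Overlapping matches, and multiple spans from one
  start under variable-length elements, all become examples; spans whose
  conserved residue is not the site's residue type are dropped with a
  warning. Pattern rows whose functional atom cannot occur in the stated
  residue (a known defect class in published site tables) are kept as
  given but flagged at load time.

# What the synthetic generators emulate

Three generators make every contract testable without downloads. Toy PDB
builders place atoms at prescribed radii and directions, exercising
parsing, shell geometry and invariances against known geometry.
Constructed score sets realize prescribed operating points exactly — a
block of 99 positives and 1 negative sharing a score makes "precision
exactly 99.0%" a counting fact, not a model outcome. Two-class Gaussian
feature sets with separation `d′` along a fixed unit direction drive the
end-to-end protocol: at `d′ = 8` with 200 positives and 2,000 negatives
(the class imbalance flavor of real training sets, at a size that keeps
the full grid search to about a minute), both classifier paths must
recover near-total recall at the 99% target; at `d′ = 0` recall collapses
to the prevalence-driven floor.

What passing these tests does *not* show: real microenvironment features
are not Gaussian (they are sparse, discrete, heavy-tailed and correlated),
real positives are not i.i.d. (homology survives 100% deduplication),
and real negative pools are contaminated at an unknown rate by
unannotated true sites. Performance numbers on synthetic data validate
the machinery, not the biology.

# Known limitations

* Sequence-pattern matching operates per chain; sites spanning chain
  boundaries are invisible.
* Solvent accessibility is an input, not a computation; with the default
  of zero that descriptor block is inert.
* The Pfam-style comparison scorer implements only the mapping confusion
  logic; producing domain predictions is out of scope.
* mmCIF files, multi-model ensembles beyond the first model, and homology
  clustering below 100% identity are not supported.
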