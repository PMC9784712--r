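---
title: "Methods: three-class GBM subtyping from small gene panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-class GBM subtyping from small gene panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliotype)
```

`gliotype` classifies glioblastoma specimens into the classical (CL),
mesenchymal (MES) and proneural (PN) transcriptional subtypes from the
log-expression of a small gene panel. This vignette is the package's own
account of the statistical machinery: what each stage assumes, which knobs
matter, and where a design was genuinely open and a choice had to be made.

## The measurement model

The universal currency between stages is a genes × samples matrix of
log-scale expression (a wide tibble with a `gene` column). Array and
RNA-seq data arrive on this scale already; qPCR data arrive as CT values
(cycles to threshold, inversely related to abundance) and are converted by

$$\mathrm{ref}(s) = \Big(\prod_{r \in R} CT_{r,s}\Big)^{1/|R|}, \qquad
  \Delta CT_{g,s} = CT_{g,s} - \mathrm{ref}(s), \qquad
  x_{g,s} = -\Delta CT_{g,s},$$

with $R$ = \{ACTB, GAPDH, YWHAZ\}, three endogenous controls that are
stable in glioma tissue. $-\Delta CT$ is the log2 of the familiar
$2^{-\Delta CT}$ fold change; keeping the log scale (rather than the fold
change itself) matters because the classifiers are trained on log-space
array data, and because on this scale one extra PCR cycle is exactly one
log2 unit — a property the tests exercise. Whether centering should act on
$\Delta CT$ or on $2^{-\Delta CT}$ is genuinely ambiguous in practice;
centering the log scale is this package's documented choice, for scale
compatibility with the training data.

Replicate CT measurements (three per gene per sample on a typical plate)
are aggregated by their arithmetic mean (`replicate_policy = "median"` is
available). A replicate standard deviation above 0.5 cycles flags the
gene/sample pair in a QC report but never drops it: high scatter is a
signal for the bench, and no principled exclusion rule exists at this
stage. A single replicate aggregates to itself.

## Normalisation and its two modes

Models are trained on per-gene standard scores with the population
($n$-denominator) convention, so training rows have mean 0 and sd 1
exactly; the $(\mu_g, \sigma_g)$ pairs are stored inside the model. At
prediction time two modes exist:

* **cohort** (default): the new cohort is re-standardised by its own
  per-gene statistics. This is the right mode when an entire cohort is
  profiled together, because it absorbs assay-wide location/scale shifts —
  a per-gene additive shift of the input provably cannot change any
  prediction (a tested invariant).
* **stored**: the training-time $(\mu, \sigma)$ are applied. This is the
  only option for single samples, and it presumes the new measurements sit
  on the training scale; the caveat is documented on
  `predict_cohort()`.

Cohort mode fails loudly for single-sample input and for zero-variance
genes rather than producing silently meaningless scores.

## Feature selection

**Reproducibility filter.** When the same specimens are measured on two
platforms, each gene's between-platform Pearson $r$ is computed across
samples; genes with $r$ *strictly below* the threshold (default 0.65) are
eliminated, so a gene exactly at the threshold survives. Zero-variance
genes have no defined $r$ and are eliminated with a recorded reason. The
filter is monotone in the threshold (tested property).

**Six rankers.** ANOVA F (one-way, between/within variance ratio); ReliefF
(k = 10 nearest hits/misses, Manhattan distance on min–max scaled features,
all instances, miss terms weighted by class prior); and four
information-theoretic scores on discretised expression: Gini impurity
decrease, gain ratio (IG divided by the feature's own entropy), FCBF's
symmetrical uncertainty, and greedy mRMR (additive variant, relevance minus
mean redundancy, with the selection order mapped to scores
$p - \mathrm{rank}$ so earlier-selected genes score higher). Discretisation
is equal-frequency with 4 right-closed bins — deterministic and robust to
sample size; input that is already discrete (at most 4 distinct values)
keeps its own categories, since quantile breaks on skewed discrete data
would collapse levels. The discrete rankers are verified against an
independent brute-force entropy/contingency implementation on small
instances.

Degenerate cases are kept finite by contract: an infinite F (zero
within-group variance) is capped at 10× the largest finite F in the cohort,
so that **mean-normalisation** — dividing each method's raw scores by the
method mean, making methods with different units summable — stays defined.
The cumulative score is the sum of the six mean-normalised scores;
cumulative ties break by the higher ANOVA score, then gene symbol. The
aggregation is invariant to rescaling any single method's raw scores by a
positive constant (tested property).

**Exhaustive panel search.** All $\binom{|C|}{k}$ combinations of the
candidate pool (default: the aggregated top 20, from which the compact
five-gene panel is drawn) are evaluated by stratified cross-validated
accuracy, with fold standardisation re-estimated inside each training fold.
Evaluating 15,504 combinations with a full penalised multinomial fit per
fold is prohibitively slow, so the default search learner (`"lsq"`) is a
ridge-stabilised least-squares indicator discriminant: class indicators are
regressed on the panel plus intercept and samples assigned to the largest
fitted score. Its linear decision boundaries track the logistic model's
closely, and the per-fold Gram matrix can be precomputed once so that each
combination costs a single small solve — the full C(20, 5) search runs in
seconds. The winning panel is then refitted and reported with the genuine
L1 logistic model. `learner = "logreg_l1"` or `"linear_svm"` evaluate the
full classifiers inside the search for small pools. Accuracy ties break by
mean one-vs-rest AUC of the pooled out-of-fold scores, then
lexicographically; a configurable cap (default $10^6$ combinations) guards
the search space.

A caution on *exact* panel recovery: if two candidate genes carry the same
expression pattern (as two CL-up genes do in the default block structure),
they are statistically exchangeable, and at saturated accuracy the search
can swap one of them for a noise gene at no cost. Recovery experiments in
the test suite therefore plant five mutually non-redundant contrasts
(CL+, MES+, PN+, CL−, MES−); with redundant patterns only set-level
enrichment, not exact identity, is a well-posed expectation.

## Classifiers

The primary model is a multinomial (softmax) logistic regression with L1
penalty, fitted by glmnet on the standardised panel. The exposed
regularisation strength is sklearn-style $C$ (default 1, larger = weaker
penalty), mapped to the glmnet penalty by $\lambda = 1/(nC)$; the fit
descends a short $\lambda$ path ending at the target for stability. L1
induces exact zeros at strong penalties (tested). The alternative linear
SVM is one-vs-rest with Platt-calibrated probabilities: per class a binary
linear SVM is reduced to its explicit weight vector, a logistic sigmoid is
fitted to the training decision values, and the three calibrated scores are
normalised to a simplex. Both learners therefore reduce to a linear score
per class, and a fitted model serialises completely to JSON (panel, class
order CL/MES/PN everywhere, coefficient matrix, intercepts, Platt
parameters, training normalisation statistics, seed). Numbers are written
with 17 significant digits, which round-trips IEEE doubles exactly:
save → load → predict is bit-identical (tested).

Cross-validation is stratified (per-class counts within one of exact
proportionality, tested at the 151/140/128 class mix), seeded, and
leak-free: standardisation parameters are re-estimated within each training
fold and applied to the held-out fold. Metrics are pooled over folds.
Under label permutation the pooled CV accuracy collapses to the 1/3 chance
level (tested over 20 shuffles).

## Evaluation battery

* **Confusion/accuracy**: 3×3 matrix (reference rows), overall accuracy =
  trace/total, per-class accuracy = diagonal/row-sum, `NA` for a class
  absent from the reference. Overall accuracy equals the count-weighted
  mean of per-class accuracies (tested identity).
* **One-vs-rest ROC/AUC**: positives = the subtype, negatives = the pooled
  other two, score = the subtype's probability. AUC is the trapezoid over
  all thresholds with ties grouped, which equals the Mann–Whitney pairwise
  estimator $P(s_+ > s_-) + \tfrac12 P(=)$ — asserted against a brute-force
  pairwise oracle and against pROC.
* **MDS**: classical (Torgerson) scaling of the pairwise Euclidean sample
  distances, refined by Sammon stress minimisation initialised from the
  classical solution. Both steps are deterministic, so no seed is needed;
  the refinement only ever lowers stress, and falls back to the classical
  solution when it cannot run (e.g. duplicate points). Two points embed
  exactly. Standardised expression is the intended input. Subtype centroids
  are means of embedded points; their pairwise distances are returned.
* **Bi-clustering**: independent average-linkage hierarchical clusterings
  of genes and samples on Euclidean distances; the two leaf orders feed the
  heatmap. Deterministic given the input.
* **Proportion comparison**: pooled two-proportion z test, no continuity
  correction — the simplest reading of a "z-score test" for comparing
  subtype proportions between cohorts; degenerate pooled proportions (0 or
  1) return `NA` rather than an arbitrary statistic.

## The synthetic cohort generator

`generate_cohort()` draws
$x_{g,s} = \mathrm{baseline}_g + \mathrm{pattern}_{g,\mathrm{subtype}(s)}\cdot\delta + \mathcal N(0, \sigma^2)$
on the log2 scale. The default pattern encodes the subtype-specific blocks
of the 20-gene panel: BCAS1, GPR17, ERBB3, PDGFRA, SNAP91, DNM3, KLRC3,
PFN2 up in PN; MET, FCGR2B, DAB2, PTPRC up in MES; EGFR, SPRY2, VAV3, CDH4,
NR2E1, NES up in CL; CHI3L1 down in PN; CSPG5 down in MES. Defaults: cohort
sizes CL 140 / MES 151 / PN 128 (the development-cohort class mix), effect
size $\delta = 2$ log2 units, noise $\sigma = 1$ log2 unit — a
signal-to-noise regime in which the five-gene classifier lands in the
high-80s-to-mid-90s accuracy range rather than saturating. Baselines are
drawn once from Uniform(4, 12) log2 units under `baseline_seed` (default:
the cohort seed); cohorts that emulate repeated measurements on the same
assay must share a `baseline_seed`, otherwise only cohort-mode
normalisation is meaningful on them. Reference genes are emitted
pattern-free (the housekeeping assumption); `expression_to_ct()` inverts
the ΔCT transform with per-replicate Gaussian noise, and
`emulate_second_platform()` applies per-gene affine distortion plus noise,
with designated genes corrupted at 3× their signal sd — driving expected
cross-platform correlation to $1/\sqrt{1+9} \approx 0.32$, safely below
the 0.65 filter.

What the generator does **not** emulate: probe-level effects and
probe-to-gene mapping, batch structure, tumor-purity gradients,
heavy-tailed or count-distributed noise (no negative-binomial RNA-seq
layer), correlated genes within a block beyond the shared mean shift, and
reference-gene instability (available only via explicit configuration).
Passing tests on these cohorts therefore demonstrates the correctness of
the machinery — normalisation algebra, leak-free CV, search behaviour,
metric identities — not the field accuracy of the classifier on real
tumors, which depends on biology the generator deliberately omits.

## Problem sizes and numerical choices

The test suite and the acceptance script run cohorts of 140–151 samples per
subtype for the headline metrics (the development-cohort scale) and 15–60
per subtype for unit-level properties; the exhaustive search is exercised
at its full C(20, 5) size. Further numerical contracts: probability vectors
sum to 1 within $10^{-9}$; the softmax subtracts the row maximum before
exponentiating; the least-squares search solve adds $10^{-8}$ to the Gram
diagonal; Platt fitting on separable folds tolerates glm's saturation
warnings; a fold-constant gene gets $\sigma = 1$ (carrying no information)
rather than aborting a cross-validation mid-run, while the user-facing
`zscore_genes()` errors on zero variance by name.

## Known limitations

* Input is gene-level: no probe mapping, no vendor raw formats.
* The published coefficients of the original TCGA-trained models are not
  re-derived (training data and solver settings are not public); models
  here are trained on the user's or the generator's cohorts.
* Single-sample classification relies on stored-mode normalisation and is
  only as good as the scale agreement between the new measurement and the
  training cohort; amplification-efficiency correction and inter-plate
  calibrators are out of scope.
* The neural subtype is excluded by design (three-class mode); a
  four-class model is intentionally not provided.
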