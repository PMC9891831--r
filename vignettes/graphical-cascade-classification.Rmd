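---
title: "Graphical sequence features and cascade forests for binary protein classification"
author: "fegsForest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graphical sequence features and cascade forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fegsForest)
```

## The problem

Immunoglobulins (antibodies) are glycoproteins central to adaptive immunity;
recognizing whether an unannotated protein sequence is an immunoglobulin is a
recurring binary classification task, and wet-lab confirmation is slow and
expensive. `fegsForest` implements a sequence-only route: a *graphical*
featurization that embeds each protein as a curve in 3D space and summarizes
the curve spectrally, combined with classical composition descriptors, fed
into a cascade deep-forest classifier. Nothing in the machinery is specific
to immunoglobulins — any two-class protein problem with cleaned sequences
over the 20-letter alphabet fits.

## The FEGS featurization

For one physicochemical property of the 20 amino acids:

1. **Ranking.** The amino acids are ordered by their property value, lowest
   first; ties break alphabetically so the ordering is a deterministic
   permutation, and a property with all 20 values identical is rejected
   outright (it induces no ordering).
2. **Cone geometry.** The residue with rank $i$ is placed at
   $\Phi(A_i) = (\cos\frac{2\pi i}{20}, \sin\frac{2\pi i}{20}, 1)$ — the
   base circle of a right circular cone of height 1. Each ordered dipeptide
   maps to $\Phi(A_iA_j) = \Phi(A_i) + \frac{1}{4}\Phi(A_j)$, which lies at
   height $z = 1.25$. Ordered pairs matter:
   $\Phi(A_iA_j) \ne \Phi(A_jA_i)$ for $i \ne j$.
3. **Curve.** A sequence $s_1 \dots s_N$ unrolls from the origin: the first
   step adds the vertex point of $s_1$; step $i \ge 2$ adds the pair point
   of the trailing dipeptide $s_{i-1}s_i$. Each residue contributes exactly
   one new point, every step has positive $z$, so the curve never stalls or
   self-intersects in $z$.
4. **Distance-quotient matrix.** Over the residue points $P_1 \dots P_N$
   (the synthetic origin is excluded), $M_{ij}$ is the Euclidean distance
   between $P_i$ and $P_j$ divided by the along-curve path length between
   them — the classic ED/GD construction. Entries lie in $(0, 1]$, adjacent
   pairs score exactly 1, and the diagonal is 0.
5. **Spectral summary.** The feature for this property is
   $\lambda_1(M)/N$, the leading eigenvalue scaled by sequence length. $M$
   is symmetric and nonnegative, so $\lambda_1 \ge 0$ (Perron–Frobenius);
   the $1/N$ scaling removes gross length dependence so long and short
   proteins are comparable.

With the default table of $P = 158$ properties, the final vector is

$$ \big[\lambda^{(1)}, \dots, \lambda^{(158)} \,\|\, \mathrm{AAC}_{1..20}
   \,\|\, \mathrm{DPC}_{1..400}\big] \in \mathbb{R}^{578}, $$

where AAC is the normalized amino-acid composition (alphabetical order) and
DPC the normalized ordered-dipeptide composition (lexicographic order). The
code is written for any $P \ge 1$: a user table of $P$ properties yields
$P + 420$ dimensions, and the effective $P$ after degenerate-row removal is
what counts.

```{r fegs-example}
v <- fegsVector("MKVLACDEFGHIKLMNPQRSTVWYAC")
length(v)
head(v, 3)
```

### The property table

The published FEGS work fixes 158 physicochemical indices but does not list
them. The bundled default is a deterministic stand-in: the AAindex
collection shipped with `seqinr` is filtered to complete, non-constant
entries, sorted by accession, and the first 158 are kept
(`defaultPhysChemTable()`). Users with a preferred index set supply it as a
TSV via `readPhysChemTable()`; every downstream dimension adapts.

### Two implementations, one contract

The granular route (`buildCurve()` → `distanceQuotientMatrix()` →
`eigenFeature()`, dense eigensolver) is exported for inspection and testing;
the production route is a C++ kernel that accumulates all $P$ curves and
extracts leading eigenvalues by power iteration (small diagonal shift, 10%
of the max row sum, to guard the bipartite-like tie case without flattening
the spectral gap; relative tolerance $10^{-12}$). The test suite asserts
agreement between the routes to $10^{-8}$ and against an independent
R-side power-iteration oracle. Memory is $O(N^2)$ per sequence — the
documented limit for very long proteins.

## Baseline descriptors

**DPC** and **AAC** are available standalone. **APAAC** (amphiphilic pseudo
amino-acid composition) appends to the 20 frequencies $2\lambda$
sequence-order factors $\tau_k$: tier-$k$ autocorrelations of standardized
hydrophobicity (Tanford-style) and hydrophilicity (Hopp–Woods) profiles,
weighted by $w$ and jointly normalized so the vector sums to 1. Defaults
$\lambda = 5$, $w = 0.05$ are the classic PseAAC settings; published
immunoglobulin predictors rarely state their APAAC parameters, so these
defaults are documented assumptions, not a reproduction surface. Because
the scales are
standardized to zero mean, $\tau_k$ — and hence the tail entries — can be
negative; only the sum-to-one normalization is guaranteed.

## The cascade forest classifier

Each layer holds 18 learners: six XGBoost boosted-tree models (20 rounds,
depth 3, learning rate 0.3), six random forests and six extremely
randomized tree forests (20 trees each), the six copies within a type
differing by seed. The layer emits 36 class-probability columns (18
learners × 2 classes) which are appended to the *original* feature matrix
as the next layer's input.

Two details are deliberate choices where the architecture description is
silent:

* **Out-of-fold augmentation.** During training, the probability columns a
  deeper layer consumes are produced by internal stratified 3-fold
  cross-fitting, never by a model predicting its own training rows. Naive
  in-sample probabilities saturate to 0/1 and starve the cascade of
  gradient; out-of-fold generation is standard deep-forest practice.
* **Stopping.** Each layer's score is the accuracy of its averaged
  out-of-fold probabilities. Training stops the first time a layer fails to
  improve on the best score so far (patience 1) or at `maxLayers`
  (default 10), and the model is truncated at the best-scoring layer.

At prediction time the kept layers are traversed with the same
augmentation, and the final probabilities are the arithmetic mean of the
last layer's 18 learner distributions — rows sum to 1 by construction, and
summing versus averaging cannot change the argmax. Ties predict the
positive class. All learners run single-threaded with derived seeds, so a
fixed master seed makes fits and predictions bit-reproducible.

## Evaluation

`classificationMetrics()` computes ACC, SN, SP, MCC and F1 from confusion
counts, with any zero-denominator metric defined as 0 (the formulas are
undefined there; a fixed convention keeps degenerate folds comparable).
AUC is the Mann–Whitney statistic with midranks, so it is invariant under
strictly monotone transforms of the scores and equals exactly 0.5 when all
scores tie. `kfoldCrossVal()` uses stratified folds — with ~110/192 class
imbalance at a few hundred samples, unstratified folds are needlessly noisy
— and averages metrics per fold by default (`pooled = TRUE` pools
predictions instead; both aggregations are legitimate readings of
"averaged results" and are provided because published tables rarely say
which they used). `independentTest()` enforces disjoint train/test
identifiers.

## The synthetic generator

`generateDataset()` draws sequences from a first-order Markov chain with
Swiss-Prot-like background composition; the positive class mixes the
background transition law with a *signature* law concentrating each row's
mass on its successors among 30 fixed signature dipeptides, with weight
$w = 1 - e^{-\mathrm{effect}}$. The parametrization was designed once
against the generator's stated semantics: `effect = 0` makes the classes
identically distributed (downstream AUC ≈ 0.5), small `effect` perturbs
proportionally, and `effect = 0.5` is a strong, clearly separable signal.
A first-order chain (rather than i.i.d. letters) is used so that
order-sensitive features — DPC and the FEGS curves — carry signal that
composition alone cannot, which is exactly the claim the graphical features
exist to exercise. Default lengths are uniform on [50, 400] residues,
covering typical immunoglobulin-domain scales while keeping the $O(N^2)$
matrices small.

What the generator does *not* emulate: homology structure, domain
architecture, length/composition coupling, or any biophysical realism.
Passing the simulation benchmarks therefore demonstrates that the pipeline
recovers a planted dipeptide-level signal and is honest at the null — not
that real immunoglobulin data will reach any particular accuracy.

## Problem sizes and numerical choices

The shipped checks run at: null benchmark 500 + 500 sequences, 5-fold CV,
single-layer cascade on DPC features; strong-signal benchmark 200 + 200
sequences (`effect = 0.5`), 5-fold CV on both FEGS and DPC features with
the full cascade. These sizes give stable estimates (binomial SE on 400
held-out predictions is about 1.5 points) while a full run stays in the
minutes range on one core. Curve features use power iteration to relative
$10^{-12}$; fold assignment, learner seeds and layer seeds all derive
deterministically from one master seed kept below $2^{31}$.

Degenerate inputs are policed at the boundaries: sequences shorter than 2
residues after cleaning are dropped with a warning (every descriptor is
undefined on them), all-identical property rows are rejected, single-class
label vectors refuse to fit, and classes smaller than $k$ refuse to fold.

## Known limitations

* The published 158-index selection is unknown; the default table is a
  reproducible stand-in, so absolute eigen-feature values are not
  comparable with the original software's.
* Curated immunoglobulin reference datasets and their train/test splits
  are not redistributable here; published headline accuracies on such data
  are therefore not a desk-reproducible target. The file-based harness
  (`runCrossval()`, `runIndependentTest()`) accepts any user-supplied
  FASTA + label pair for that comparison. Redundancy
  filtering (CD-HIT at 60% in the original protocol) is an external
  preprocessing step users should apply themselves.
* One widely printed form of the MCC formula contains a typographic `FT`
  where `FP` is meant; the standard MCC is implemented.
* $O(N^2)$ memory per curve matrix; multi-grained scanning and multiclass
  problems are out of scope.
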