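---
title: "Predicting PTM sites with multiple kernels: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting PTM sites with multiple kernels: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmkernels)
```

## The model

A candidate post-translational modification (PTM) site is a serine,
threonine or tyrosine residue together with its 21-residue local
sequence window (10 residues each side). Two similarity measures over
sites feed a binary support vector machine:

**Local sequence kernel.** The raw similarity between windows is the
positionwise BLOSUM62 sum, an exact integer. Because a Gram matrix
should be non-negative, it is min-max normalised into $[0,1]$:
$K_{seq} = (S_{seq} - \min S_{seq}) / (\max S_{seq} - \min S_{seq})$.
This captures the conserved-motif signal that almost all site
predictors use.

**Gaussian interaction-profile (GIP) kernel.** The known
site-modification relationships form a bipartite network, encoded as a
binary adjacency matrix $A$ (sites $\times$ PTM types). The GIP kernel,
borrowed from drug-target interaction prediction, is an RBF kernel on
the rows: $K_{GIP}(t_i,t_j) = \exp(-\gamma\,\lVert A_{t_i} -
A_{t_j}\rVert^2)$. For binary rows the squared Euclidean distance is
the Hamming distance, so the kernel measures how many modifications two
sites disagree on. It is positive semidefinite with unit diagonal by
construction.

**Combination and classifier.** The Gram matrix passed to the SVM is
$K = \beta_1 K_{seq} + \beta_2 K_{GIP}$, $\beta_d \ge 0$. The C-SVM
(L1 soft margin) is solved in the dual by `kernlab::ksvm` with the
kernel supplied as a precomputed matrix; after every fit the package
verifies dual feasibility ($\sum_i a_i y_i = 0$ and the box
constraints). Probabilities come from a Platt sigmoid,
$P(y{=}1\,|\,s) = 1/(1+e^{As+B})$ with $A<0$, fitted by Newton's method
on decision values obtained by stratified 3-fold cross-validation
inside the training set, so the sigmoid never sees resubstitution
scores.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `flank` | 10 | residues each side of the site; window width $2\cdot10+1=21$ |
| `gamma` | 0.001 | GIP bandwidth; at this value profiles differing in $d$ annotations score $e^{-0.001d}$, a gentle decay suited to networks with few PTM categories |
| `betas` | (0.5, 0.5) | kernel weights; an uninformative half-half prior. `tune_betas()` scans $\beta_1 \in \{0, 0.1, \ldots, 1\}$, $\beta_2 = 1-\beta_1$ by cross-validated AUC when data should decide |
| `C` | 1 | SVM regularization (the solver default) |
| `balanced` | TRUE | per-class penalties $C_\pm = C\,N/(2N_\pm)$, the inverse-class-frequency scheme; reduces to uniform $C$ on balanced data |
| `tol` | 0.001 | dual solver convergence tolerance (solver default) |

## Leakage control under cross-validation

Evaluation is stratified ten-fold cross-validation repeated ten times;
metrics are computed on the scores pooled within a repeat and averaged
over repeats (per-fold averaging is available via
`aggregate = "per_fold"`). Two details keep held-out information out of
training:

* **Normalisation scope.** The min/max of $S_{seq}$ are taken over the
  training block only; train-test cross blocks are mapped with the same
  constants and clamped to $[0,1]$. Computing the constants jointly
  would let test similarities shift training kernel values; since the
  map is monotone, the training-only choice changes no ordering.
* **GIP masking.** Before the fold's GIP kernel is computed, the
  target-PTM column of every test site is zeroed. Test sites keep their
  *other* annotations — those cross-PTM relationships are exactly the
  information the GIP kernel is meant to exploit — and training sites
  keep everything, including the target column. The fold-level test
  suite verifies bitwise that scrambling held-out target annotations
  changes neither the training kernel nor any test score.

Two choices here were genuinely open. First, whether negatives'
profiles should be all-zero rows or carry their other-PTM annotations:
the data model supports both, and the readers preserve whatever the
site table says. Second, stratification: folds are stratified by class
(rather than fully random) to guarantee both classes in every training
fold on strongly unbalanced tasks.

## Numerical choices and degenerate inputs

* Windows running past a protein terminus are padded with `X` and
  scored through the extended BLOSUM62 `X` column ($X$–$X = -1$): the
  least-informative published score, keeping the sequence kernel
  defined at every site. `U`/`O` (absent from BLOSUM62) map to `X` on
  read.
* A constant similarity matrix makes min-max normalisation undefined
  and is an error, not a silent fallback.
* Metrics with zero denominators are reported `NA` with an `undefined`
  flag; coercing them to 0 would corrupt averages across repeats.
* ROC curves have one vertex per distinct score (ties grouped);
  trapezoidal AUC then equals the Mann-Whitney concordance with ties
  counted one half — the unique tie convention with that property.
* The specificity-anchored threshold is the smallest observed score
  whose "score $\ge$ threshold" rule reaches the target; if all
  negatives share the maximum score the threshold is $+\infty$ with an
  `unreachable` flag.
* Ties at decision score exactly 0 are predicted positive; candidate
  ranking breaks probability ties by site id, so outputs are
  deterministic.
* Min-max normalised BLOSUM62 similarity is not guaranteed positive
  semidefinite. The solver tolerates small negative eigenvalues; a
  projection onto the PSD cone (`nearest_psd`, eigenvalue clipping) is
  available behind `psd_repair = FALSE` for strict use. The GIP kernel
  and any non-negative combination of PSD components are PSD and need
  no repair.
* All stochastic steps (fold assignment, Platt inner CV, data
  generation) draw from explicit seeds through isolated RNG scopes;
  per-repeat fold seeds derive deterministically from one master seed.

## What the synthetic generator does and does not emulate

`generate_dataset()` draws positive windows from a consensus motif
(each specified position matches with probability `match_prob`,
otherwise background) and negatives from background, both with the
correct central residue; helper annotations are Bernoulli with
probability `co_occurrence_prob` for positives and `background_prob`
for negatives, emulating the co-modification structure of the bipartite
network. Background residue frequencies default to uniform, which makes
analytic checks simplest; a natural-abundance table
(`aa_background("swissprot")`) is available. Setting `match_prob = 0`
and equal annotation probabilities yields an exact null in which every
kernel configuration should sit at AUC 0.5 — the calibration property
the acceptance suite checks at $n = 400$ over 10 seeds. The strong
condition (fully specified consensus at `match_prob = 0.9`,
co-occurrence 0.6 vs background 0.05, $n = 400$) is near-separable by
construction and checks both signal recovery (combined AUC > 0.9) and
synergy (combined within 0.02 of the best single kernel or better).

The generator deliberately does **not** mimic real PTM databases'
class imbalance, homology-induced redundancy between windows, or
kinase-family-specific motif catalogs; positives within a synthetic
dataset are independent draws, whereas real positive sets contain
near-duplicate windows from homologous proteins. Passing the synthetic
checks therefore demonstrates that the machinery is correct and
calibrated, not that any particular real-data accuracy will be reached;
on real data, redundancy between training and test windows must be
handled by homology-aware grouping, which is out of scope here.

Problem sizes throughout the test and acceptance material (tens to a
few hundred sites, 10 seeds) were chosen as the smallest at which the
statistical properties under test are stable.

## Known limitations

* Only sequence windows and site-modification profiles are used; no
  structural, disorder or conservation features.
* The GIP kernel is informative only where site-modification
  relationships are already recorded; for a site with an empty profile
  it reduces to a near-constant and the sequence kernel carries the
  prediction.
* $\gamma$ is a configuration constant, not learned.
* Each PTM or kinase group is an independent binary task; there is no
  joint multi-label model.
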