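---
title: "Predicting lysine acetylation sites: models, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lysine acetylation sites: models, features and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The prediction problem

Lysine acetylation is a reversible post-translational modification: an
acetyl group is transferred to the epsilon-amino group of a lysine side
chain.  Experimentally mapping which lysines of a proteome are acetylated
is slow and expensive, so sequence-based classifiers are used to triage
candidate sites.  `acetylsite` frames the task as binary classification of
individual lysines: each candidate site is represented by the fragment of
`2L + 1` residues centred on it (the *sliding window*, default `L = 6`,
window length 13) together with optional per-residue annotations produced
by external predictors, and a radial-basis-function support vector machine
(RBF-SVM) separates acetylated from non-acetylated sites.  Because the
sequence context of acetylation differs between organisms, a model is
trained per species: species specificity is a property of the training
data, not of the code.

```{r, eval = FALSE}
library(acetylsite)
d <- generate_dataset(synthetic_spec(seed = 1))
model <- acetyl_fit(d$proteins, d$sites, profiles = d$profiles,
                    subtypes = c("LC", "PWAA", "EBGW", "HSE"), seed = 1)
summary(model)
```

## Feature subtypes

Fourteen feature subtypes are encoded per window and kept separate
throughout ranking and selection.  Eight derive from the sequence alone:

* **LC** — a one-hot 3-vector recording whether the window crosses the
  N-terminus, the C-terminus, or neither.
* **PWAA** — position-weight amino-acid composition: for each amino acid
  `i`, `C_i = 1/(L(L+1)) * sum_{j=-L..L} x_{i,j}(j + |j|/L)`.  Downstream
  occurrences carry positive weight, upstream ones negative weight, so the
  composition keeps sequence-order information.  For a homopolymer window
  the weights telescope to `1/L`; the sharp per-feature bound is
  `(L+1)/(2L)`, attained by a residue filling the downstream flank.
* **EBGW** — the window is projected onto three binary sequences from
  hydropathy/charge group unions (hydrophobic + polar, hydrophobic +
  positive, hydrophobic + negative), each summarised by `K = 5` growing
  prefixes of length `Int(N k / K)` with round-half-up rounding: at
  `N = 13` the prefix lengths are 3, 5, 8, 10, 13.
* **CKSAAP** — normalised counts of the 400 ordered residue pairs at
  spacing `k` (default 0, adjacent pairs).
* **KNN** — for each of five neighbourhood fractions (1/2 … 1/32 of the
  reference size), the fraction of positive labels among the nearest
  reference fragments under the normalised BLOSUM62 window distance
  `D = 1 - sum_i sim(a_i, b_i)/(2L+1)`,
  `sim(a,b) = (M(a,b) - min M)/(max M - min M)`.
* **ACC** — auto- and cross-covariances of the five Atchley factor
  profiles at lags 1 and 2.
* **PC-PseAAC** — Chou-type parallel-correlation pseudo amino-acid
  composition (20 composition terms plus `lambda = 2` correlation tiers,
  weight 0.05).
* **AAindex** — ten classical property scales averaged over the window,
  plus the five Atchley factors encoded per position.

Six subtypes encode per-residue channels parsed from external predictor
output files (the package parses the file dialects; it never runs the
predictors): secondary structure (**SS**, one-hot per position), relative
solvent accessibility with backbone torsions (**RSA**), disorder calls
(**Disorder**), half-sphere exposure (**HSE**: HSEAU/HSEAD/HSEBU/HSEBD per
position), and two evolutionary profiles — the PSI-BLAST-style scoring
matrix (**PSSM**: 20 log-odds + 20 probabilities + entropy per position)
and an HMM-profile emission table (**HH**: 20 probabilities + entropy).
The entropy conservation score of a probability vector is
`ECS = -sum_j p_j log2 p_j` with `0 log 0 = 0`, ranging from 0 (conserved)
to `log2 20 ≈ 4.32` bits (uniform).

Half-sphere exposure — the number of C-alpha neighbours in the upper and
lower half-spheres around a residue — is the structurally motivated
channel: an acetylated lysine needs a sparsely packed upper half-sphere
(where its side chain points) for the acetyltransferase to reach the
epsilon-amino group, so lower HSE-up values at a site favour acetylation.

### Windows at the termini

Windows crossing a terminus are padded with a gap symbol and the padded
positions masked invalid.  Every encoder treats invalid positions as
contributing nothing: they are excluded from counts and denominators where
a count is defined (PWAA, CKSAAP, ACC, PC-PseAAC, averaged properties) and
encoded as zeros where a fixed-length block is defined (per-position
encoders).  In the nearest-neighbour distance an invalid position scores
maximal dissimilarity.  A window touching both termini is classed
N-terminal — an arbitrary but deterministic tie-break, relevant only for
proteins shorter than the window.

## Feature selection

Features are selected per subtype, never across subtypes:

1. **Ranking.**  Each feature is ranked by the absolute Pearson
   correlation between its column and the 0/1 class vector.  Absolute
   correlation is used because a strong negative correlate is exactly as
   informative as a positive one; constant features get correlation 0 and
   sort last; ties break by feature name, then column order.
2. **Greedy stepwise pass.**  Walking the ranked list once, a candidate is
   accepted iff the 5-fold cross-validated SVM accuracy of the incumbent
   set plus the candidate *strictly* increases.  The first-ranked feature
   is accepted unconditionally (the empty model is given baseline accuracy
   0), so the procedure is well-founded and the accuracy trajectory is
   strictly increasing by construction.  One stratified fold plan, fixed
   by the run seed, is shared by every evaluation in a run.
3. **Assembly.**  The accepted per-subtype lists are concatenated in the
   fixed subtype order; per-subtype counts are recorded so the composition
   of the final set can be audited.

The SVM cost and gamma used inside the stepwise pass are tuned by grid
search once per subtype on the full subtype block and then held fixed;
re-tuning at every candidate evaluation would multiply the cost of the
pass by the lattice size for little benefit, and nesting the tuning inside
the pass is a genuinely open design point.  An optional
`max_evaluations` cap bounds the pass on very wide subtypes (the PSSM
block has 533 columns at `L = 6`).

## Classifier, scaling and evaluation

The classifier is libsvm's C-classification RBF-SVM (via `e1071`).  Every
feature is linearly scaled to `[-1, 1]` using minima and maxima computed
on training data only — per training fold during cross-validation, so
validation folds never leak into the scaling; a feature constant in
training maps to 0 everywhere, also for unseen test values.  Cost and
gamma are selected on an exponential lattice (`svm_grid()` defaults to
cost `2^-5 … 2^15`, gamma `2^-15 … 2^3`, step 4x); ties resolve toward
the smaller cost, then the smaller gamma.  `acetyl_fit()` defaults to a
coarser 5 x 5 lattice appropriate for the desk-scale datasets the package
targets; both lattices are configurable.

Performance is reported as MCC, ACC, SEN, SPE, PRE from pooled
out-of-fold confusion counts, plus AUC from a threshold sweep over the
out-of-fold SVM decision values (ties grouped into diagonal ROC segments,
trapezoidal integration — numerically identical to the Mann-Whitney
statistic).  Decision values rather than calibrated probabilities feed the
ROC: they are deterministic and rank-equivalent to any monotone
calibration.  MCC with a zero denominator is defined as 0; undefined
precision is reported as 0 with a warning.

## The synthetic data generator

Real training data for this problem require curated acetylation databases
and six external prediction tools.  The generator instead produces
datasets with the statistical structure the method assumes, so the whole
pipeline can run and be tested self-contained:

* sequences drawn from proteome-like background frequencies (lengths
  uniform on 80–200; 200 proteins and one planted site per protein by
  default, with a balanced negative sample of the remaining lysines —
  the balanced 1:1 design used for training);
* compositional bias around positive sites: within the window radius,
  glycine is enriched and glutamate/aspartate depleted on both flanks and
  lysine additionally enriched upstream — the qualitative human-like bias
  pattern;
* a planted half-sphere exposure effect: at site centers the "up"
  channels are drawn with class-dependent means (HSEAU 8.15 positive vs
  9.21 negative; HSEBU 9.72 vs 11.07), shared sd 3.0 (our choice — the
  class means are reported values, their spread is not), truncated at
  zero; down channels and non-site positions carry no class signal;
* profile channels drawn consistently: scoring-matrix and HMM-profile
  probability rows concentrated on the true residue (Dirichlet-like,
  concentration 10), secondary-structure and disorder run structure from
  two-state Markov chains, solvent accessibility uniform on `[0, 1]`,
  torsions in plausible ranges.

The emitted files use exactly the dialects the parsers read, values are
quantised exactly as the files store them (so parsing a generated tree
reproduces the in-memory dataset), and two runs from the same spec are
byte-identical.

What the generator does **not** model: real within-protein correlation
beyond short Markov runs, genuine evolutionary conservation patterns,
homology between proteins, and the class imbalance of real proteomes
(negatives vastly outnumber positives; the generator emits the balanced
sample directly).  A pipeline that passes the planted-signal tests
therefore demonstrates mechanical and statistical correctness of the
method, not expected accuracy on real proteomes.

## Numerical choices

* Nearest-neighbour ranking operates on exact integer BLOSUM similarity
  totals (the distance is a fixed monotone transform of them), so distance
  ties are exact and broken by reference insertion order — immune to
  floating-point summation order.  When encoding training sites the query
  is excluded from its own reference (leave-one-out) to avoid label
  leakage; the published procedure leaves this unstated.
* `Int()` in the grouped-weight encoder rounds half up, and the
  fraction-to-K rule of the nearest-neighbour encoder uses
  `max(1, round-half-up(f * n))` — R's own `round()` is banker's rounding
  and would be a surprising convention here.
* Probability rows parsed from profile files are renormalised to sum to 1
  (integer-percentage output makes rows sum to ~0.98–1.02); an all-zero
  row becomes uniform.
* Feature matrices are written at full `%.17g` precision so a write/read
  round trip is bit-exact.
* Fold plans are stratified by class and fixed by the run seed; every
  artifact embeds an FNV-1a hash of the run configuration, and equal
  hashes imply byte-identical matrices, manifests and predictions.

## Problem sizes used by the test suite

The planted-signal study runs 20 seeds at 200 proteins (~400 sites,
window 13) with the sequence subtypes LC/PWAA/EBGW plus HSE and a coarse
3 x 3 tuning lattice; the chance-level control fits HSE-only models on 20
datasets with the exposure shift zeroed.  These sizes give stable
pass/fail behaviour for the planted effects while keeping a full test run
in the minutes range; they are scaled-down study conditions, not tuning
choices.

## Known limitations

* Only the Pearson-correlation ranker ships; the selection interface
  accommodates alternative rankers (redundancy-aware methods such as mRMR
  are natural extensions) but none are implemented.
* The package parses external predictor outputs; it cannot produce them,
  and it does not compute half-sphere exposure from 3D coordinates.
* Greedy per-subtype selection cannot remove a feature once accepted and
  never considers cross-subtype redundancy.
* The SVM decision threshold is fixed at 0; cost-sensitive thresholds for
  the heavily imbalanced real-world screening setting are out of scope.
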