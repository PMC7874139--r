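---
title: "Methods: feature encoding, balancing, selection and evaluation in cwlytic"
author: "cwlytic authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature encoding, balancing, selection and evaluation in cwlytic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwlytic)
```

# The problem

Cell wall lytic enzymes — endolysins and autolysins that hydrolyse bacterial
peptidoglycan — are of growing interest as alternatives to conventional
antibiotics, and screening candidate proteins experimentally is slow.
`cwlytic` is a sequence-based prediction toolkit for this binary
classification problem: given a protein's primary sequence, optionally its
evolutionary profile (a PSSM from an iterative profile search) and its
predicted three-state secondary structure, decide whether it is a cell wall
lytic enzyme. The package implements the complete modelling chain —
four feature encoders, minority-class oversampling, univariate feature
ranking with incremental selection, an RBF-kernel support vector machine,
and leave-one-out evaluation — together with parsers for the standard input
formats and a synthetic-data generator so that every stage is testable with
no external downloads.

# Feature encoders

All encoders use one canonical residue order (alphabetical,
`A C D E ... Y`) for naming; files in PSI-BLAST's column order are permuted
on read. Sequences must be over the 20 standard residues; the ambiguity
letters B, J, O, U, X, Z are rejected at load time, mirroring the curation
rule used to build benchmark datasets in this field.

**Amino acid composition (AAC).** The 20-vector $x_a = n_a / L$ of residue
frequencies. Always a probability vector.

**Dipeptide composition (DC).** The 400-vector of adjacent ordered pair
frequencies $f_{ab} = m_{ab}/(L-1)$, in lexicographic pair order. Requires
$L \ge 2$.

**PSSM auto-covariance (PSSM-AC).** For profile column $j$ and lag
$\ell = 1..lg$:
$$\mathrm{AC}(j,\ell) = \frac{1}{L-\ell}\sum_{i=1}^{L-\ell}
  (R_{i,j}-\bar R_j)(R_{i+\ell,j}-\bar R_j),$$
a $20 \times lg$ vector capturing along-sequence correlation of the
evolutionary profile. The default maximum lag is $lg = 28$, the value
selected for the final published model of this method. Sequences with
$L \le lg$ raise an error rather than being padded: the sum is empty or
ill-defined there, and silent padding would make feature values
incomparable across records.

**Average chemical shift auto-covariance (acACS).** Each residue is
replaced by an empirical average backbone chemical shift conditioned on its
secondary-structure state (H/E/C), separately for the four nuclei
$^{15}\!N$, $^{13}C_\alpha$, $^1\!H_\alpha$, $^1\!H_N$; the resulting real
series $A^i_k$ is summarized per nucleus by a lag profile for
$\ell = 0..\lambda$ (default $\lambda = 17$, all four nuclei, hence
$4 \times 18 = 72$ features). Two formula variants exist because the
printed description of this encoder uses a *signed mean difference*
$$\varphi^i_\ell = \frac{1}{L-\ell}\sum_{k=1}^{L-\ell}(A^i_k - A^i_{k+\ell}),$$
which is not a covariance (and is identically zero at $\ell = 0$), while
the encoder's name suggests the conventional mean-centered product. We
implement the printed difference form as the default (`"difference"`) and
provide the conventional one behind `acacs_variant = "covariance"`,
endorsing neither: the $\ell = 0$ entry is kept in both so the vector
layout is identical. Under the default form the lag-0 feature is a constant
zero; F-score ranks it last, so it is harmless, and dropping it would
change the documented dimensionality.

**The ACS table.** The numeric shift values are delegated to an external
server by the method's description and are not published. The package
therefore ships `acs_shifts_synthetic.tsv`: random-coil backbone shifts
(approximate literature consensus values, in ppm) plus fixed helix/sheet
secondary-shift offsets. The file is labelled synthetic because it is a
constructed stand-in, not measured reference data; `read_acs_table()`
accepts a user table with columns `residue state nucleus value`. Proline
has no amide proton; its $^1\!H_N$ entry is a conventional placeholder
(8.30 ppm) so the table is total, which matters only if a user weights the
$^1\!H_N$ nucleus on proline-rich sequences.

# SMOTE balancing

Benchmark datasets for this problem are imbalanced (~4.5 negatives per
positive: 68 versus 307 in the deposited set). `smote_balance()` oversamples
the minority class to exact parity: repeatedly pick a minority sample
$x_i$, one of its $k$ nearest minority neighbours $x_{nn}$ (Euclidean
distance; $k = 5$ by default, the technique's canonical value — the source
description leaves $k$ unstated), and a uniform $\alpha \in (0,1)$, and add
$x_{new} = x_i + \alpha(x_{nn} - x_i)$. The published step "select $x_i$
samples from the k nearest neighbors" is garbled as printed; we use the
canonical reading (one neighbour chosen uniformly per synthetic point,
base points sampled with replacement until parity). Synthetic rows carry a
`synthetic` provenance flag and ids that embed their base sample, which is
what makes the leakage diagnostics below possible. The stage requires an
explicit seed.

# F-score ranking and incremental feature selection

The per-feature F-score is the squared separation of class means over the
pooled within-class variance. The printed form of this statistic in parts
of the literature applies the Bessel factor $1/(n-1)$ only to the
negative-class sum; we default to the symmetric Chen–Lin form (both
factors) and expose the asymmetric one as `variant = "printed"`, treating
the asymmetry as typographical. Features constant in both classes score 0;
a feature with zero within-class variance but separated means is a perfect
separator and receives `Inf` so the ranking remains total.

IFS evaluates nested top-$d$ subsets ($d = 1, 1+s, 1+2s, \dots$) with a
caller-supplied evaluator (by default k-fold cross-validated SVM accuracy)
and selects the smallest $d$ attaining the maximum.

# The SVM

No SVM implementation is available in the package's dependency budget, so
the binary C-SVC with RBF kernel is implemented natively: a sequential
minimal optimization solver with first-order maximal-violating-pair working
set selection (the classic libsvm strategy), full kernel matrix caching
(problem sizes here are hundreds of samples), stopping tolerance $10^{-3}$
on the duality-gap surrogate, and no randomness anywhere — training is
bit-reproducible. Features are min-max scaled to $[0,1]$ with statistics
fitted on the training data only (configurable off); grid search over the
canonical grid $C \in 2^{-5..15}$, $\gamma \in 2^{-15..3}$ uses stratified
k-fold CV with scaling refitted inside each fold, ties broken toward
smaller $C$ then smaller $\gamma$.

# Evaluation protocols and their biases

`compute_metrics()` reports Sn, Sp, Acc (percent) and MCC from pooled
confusion counts. Two printed-formula discrepancies are handled explicitly:
specificity is TN/(TN+FP) (the printed TN/(TN+FN) variant is available as
`sp_variant = "printed"`), and the MCC denominator carries the square root
(without it the reported values could not lie in $[-1,1]$). MCC is defined
as 0 when a denominator factor vanishes and clamped against floating-point
overshoot at the $\pm 1$ corners.

`jackknife()` and `kfold()` make the placement of SMOTE part of the
protocol, because it changes what the numbers mean:

* `outside` — balance once, then cross-validate. Synthetic points derived
  from a held-out sample remain in its training set, which inflates
  minority-class accuracy. This mirrors the balance-then-validate protocol
  under which this method's headline numbers were reported. Held-out
  synthetic points are excluded from the counts by default
  (`include_synthetic = TRUE` mimics metrics over the whole balanced set).
* `inside` — re-balance each training fold after removing the test
  samples; no synthetic point can derive from a test sample (this is
  asserted structurally in the test suite).
* `none` — no balancing.

Two numerical regimes deserve a warning. First, with a near-zero RBF
$\gamma$ the kernel is almost constant and the decision reduces to a
majority vote over the training set; in leave-one-out evaluation the
held-out sample's class is then always one vote short, producing dramatic
*anti-learning* (accuracy far below chance on null data). Bandwidths around
the median-pairwise-distance heuristic ($\gamma \approx 1$ on $[0,1]$-scaled
features of this dimensionality) avoid the regime. Beware that when many
grid pairs tie on cross-validated accuracy (common on small balanced
datasets), the deterministic tie rule — smallest $C$, then smallest
$\gamma$ — can resolve to exactly this degenerate corner of the full
canonical grid; restrict the grid to sane ranges for small problems. Second, ranking and IFS
performed once on the full dataset before cross-validation leak information
into every fold: on null data with many features this selection bias alone
can push leave-one-out accuracy to extremes. `run_pipeline()` retains the
single-pass stage order (extract, balance, rank, IFS, grid search,
evaluate) because that is the protocol whose artifacts users of this method
expect; `make_pipeline_trainer()` packages the sound alternative, nesting
SMOTE, ranking, IFS and training inside every fold, and is what the
package's own closed-loop calibration uses.

# The synthetic world

`gen_records()` writes FASTA/PSSM/ss2/manifest fixtures that re-enter the
package through its own parsers. Class separation is injected at the
residue-composition level (the first ten alphabet letters up-weighted by
$e^{\pm s/2}$ for positives/negatives), as a mean shift $\pm s$ on the
matching PSSM columns (integer scores clamped to $[-10, 10]$), and
indirectly into acACS through composition; secondary structure follows a
sticky three-state Markov chain (stay probability 0.8) in both classes.
`gen_feature_matrix()` produces unit-variance Gaussian classes with a
configurable mean shift. At `separation = 0` the classes are exchangeable
by construction — the null world used for calibration. What a green
closed-loop test establishes is that the chain recovers a composition-level
signal and stays at chance under the null; it says nothing about
performance on real proteins, whose composition, profile and structure
statistics the generator does not emulate.

Desk-scale defaults chosen once for the calibration tests: 15 positive /
25 negative sequences of length 50–70, AAC features ($p = 20$, so the null
calibration is not dominated by $p \gg n$ selection effects), separation 3
for the signal arm and 0 for the null arm over 20 seeds, fixed
$C = 1$, and the null band asserted on the mean across seeds (per-seed
accuracy on 40 samples has a binomial spread of roughly $\pm 16$ points,
so a per-seed band would be violated by chance regularly).

# Worked example

```{r example, eval = FALSE}
dir <- tempfile()
ds <- gen_records(synth_spec(n_pos = 12, n_neg = 28,
                             length_range = c(50, 70),
                             separation = 2.5, seed = 7), dir)

cfg <- pipeline_config(
  file.path(dir, "positive.fasta"), file.path(dir, "negative.fasta"),
  manifest = file.path(dir, "manifest.tsv"),
  encoder = encoder_config(lg = 8, lambda = 4),
  svm = svm_config(c_grid = 2^(0:4), gamma_grid = 2^(-5:0)),
  ifs_step = 50, seed = 7)
res <- run_pipeline(cfg, out_dir = file.path(dir, "run"))
res$report
```

# Known limitations

* The package parses PSSM and secondary-structure files but never runs
  PSI-BLAST or PSIPRED; profile quality (search database, iterations) is
  entirely the caller's responsibility.
* The shipped ACS table is a constructed stand-in; results using the acACS
  block depend on the table supplied.
* The single-pass pipeline protocol is optimistically biased by design
  (see above); use `make_pipeline_trainer()` for honest error estimates.
* Grid search and jackknife are $O(\text{grid} \times \text{folds})$ and
  $O(n)$ SVM fits respectively; with the full kernel-matrix SMO this is
  comfortable for hundreds of samples, not tens of thousands.
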