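---
title: "Methods: sequence features and models for SSB/DSB classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence features and models for SSB/DSB classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandbind)
```

## The problem

DNA-binding proteins divide into single-stranded DNA binders (SSBs), which
recognise unwound or irregular DNA, and double-stranded DNA binders (DSBs),
which bind the duplex. Telling the two apart from sequence alone is useful
wherever structures are unavailable: dsDNA carries a denser negative charge
and a regular helix, and this is mirrored in sequence-level signals —
DSBs tend to be enriched in the positively charged residues Arg, Lys and
His, while SSBs show elevated Asn, Gly, Phe, Tyr and Val. `strandbind`
turns those signals into a binary classifier built from four feature
families, two classifier types, and a majority-voting ensemble.

## Feature families

All features are computed over the *cleaned* sequence: non-standard
letters (X, B, Z, J, U, O, stops, gaps) are deleted, never imputed,
because every composition formula below is defined over the 20 standard
residues and deletion keeps all denominators well defined. One global
residue ordering (alphabetical one-letter codes, `aa_alphabet()`) fixes
the layout of every vector: OAAC slots, dipeptide indexing, PSSM columns
and AAindex columns.

**Square-root overall composition (OAAC, 20 dims).** Occurrence
frequencies $p_i = n_i / L$ transformed to $f_i = \sqrt{p_i}$. The
transform projects every protein onto the unit sphere
($\sum_i f_i^2 = 1$), a normalisation known to help composition-based
classifiers. The square root is applied *only* here, not to dipeptide
frequencies.

**Gapped dipeptide composition (3 × 400 dims).** For interval
$s \in \{0,1,2\}$, ordered residue pairs separated by $s$ positions are
counted and divided by $N - 1$:
$f_s(i,j) = D_s(i,j) / (N-1)$. The denominator is deliberately the same
for all three intervals even though only $N-1-s$ pairs exist at interval
$s$; the three blocks therefore share one scale, and the interval-$s$
block sums to $(N-1-s)/(N-1)$ rather than exactly 1. The concatenation of
the three blocks is the 1200-dimensional "all intervals" family; in the
classifier each interval is its own family, matching the per-family
model/ensemble design.

**Split amino acid (SAA) partition.** Local composition is captured by
partitioning each sequence into six parts: four N-terminal windows
(N1–N4), a middle region (M) and a fixed C-terminal window (C) of
$d_C = 10$ residues. The partition is length-conditional:

| case | condition | N windows | M | C |
|------|-----------|-----------|---|---|
| A | $L \ge 4\cdot 25 + 20 + 10 = 130$ | 4 × 25 | $L - 110$ | 10 |
| B | $90 \le L < 130$ | 4 × 20 | $L - 90$ | 10 |
| C | $12 \le L < 90$ | one undivided N of $\lfloor (L-10)/2 \rfloor$ | remainder | 10 |

The case boundaries are the only disjoint, exhaustive reading of the
length conditions; the boundary $L = 130$ belongs to case A. In case C
the four N slots all alias the single undivided N region, so every
protein yields six region slots and the feature dimension is constant
across proteins — a requirement for any single model. Two deliberate
numerical choices: the case-C N length uses `floor` with the remainder
going to M, and at exactly $L = 90$ (case-B lower boundary) the middle
region is empty, whose mean is defined as 0 so no feature cell is ever
missing. Sequences shorter than 12 cannot form three non-empty regions
and are rejected.

**SAA-partitioned physicochemical encoding (28 × 6 = 168 dims).** Each
of 28 AAindex properties is mapped over the residues and averaged within
each SAA region. The arithmetic mean (not the sum) is used so that
region length does not confound the encoding; the pooling operator is a
genuinely open design point and is therefore isolated in one helper.
Raw table values are used by default, with an optional per-property
z-scaling flag — scaling is the minimal-assumption default left off.

**SAA-partitioned PSSM encoding (20 × 6 = 120 dims).** A
position-specific scoring matrix (L × 20 log-odds from iterative profile
search, e.g. three PSI-BLAST iterations against nr with BLOSUM62 and
e-value 0.001) is averaged per column within each SAA region. The
package parses precomputed ASCII profiles; it does not run PSI-BLAST.
The log-odds block is used rather than the weighted-percentage block —
log-odds is the conventional meaning of the "scoring matrix" — and the
parser exposes `block = "percent"` as the switchable alternative.

### The AAindex table

The 28-accession property set (net charge, several hydrophobicity and
hydropathy scales, mean polarity, side-chain partition energies, contact
energies, secondary-structure propensities …) is keyed by real AAindex
accessions. The numeric values shipped in
`inst/extdata/aaindex28_synthetic.tsv` are, however, a **synthetic
stand-in**: the AAindex database itself is not redistributed with the
package, and no test or acceptance quantity depends on the stand-in's
numeric content — only on the table's shape, finiteness and the code
paths it exercises. Production analyses should supply a conforming
extract of AAindex1 via `load_aaindex_table(path, strict = FALSE)`.

## Classifiers

The runtime environment this package targets provides no SVM or random
forest implementation, so both are implemented natively (C++ via Rcpp)
behind the same interface:

* **Random forest** — bagged CART trees grown on bootstrap samples with
  the Gini criterion, `mtry = floor(sqrt(p))` candidate features per
  split, nodes grown to purity. The default 3000 trees matches the
  reference configuration; tests and the acceptance profile use 300,
  which changes AUC by well under the stochastic tolerances involved.
  Scores are the fraction of trees voting positive. Importance is mean
  decrease in Gini impurity, averaged over trees, and can be aggregated
  over cross-validation folds with `gini_importance_summary()`.
* **SVM** — an RBF-kernel C-SVM trained by sequential minimal
  optimisation with the standard library defaults ($C = 1$,
  $\gamma = 1/(p \cdot \mathrm{Var}(X))$). Decision values are mapped to
  $[0,1]$ by Platt sigmoid calibration fitted on the training decision
  values, so both model types emit comparable scores for the voting tie
  rule and for AUC. The solver was validated against an independent
  reference implementation during development (test-set AUC agreed to
  seven digits on a shared fixture).

Both are deterministic given the seed: tree bootstraps consume a C++
RNG seeded from R, and the SMO working-set selection is fully
deterministic.

## Training protocol

The reference dataset is heavily imbalanced (873 DSBs vs 183 SSBs), so
training uses **majority-class down-sampling**: all minority proteins
plus an equally sized uniform random subset of the majority class.
Inside cross-validation this happens *per training fold*; test folds are
never down-sampled (down-sampling evaluation data would corrupt
sensitivity/specificity). Folds are stratified by class — with a
183-member minority class, unstratified "ten equal parts" risks
near-empty-class folds. Leave-one-out is available as `k = n`.

One model per feature family is trained per fold; the **"All features"**
row is the majority vote over the six family predictions. An even
ensemble can tie 3–3; the tie is broken by the mean positive-class score
(positive iff ≥ 0.5). When no PSSM profiles are available the family is
dropped and five models vote, making the tie rule moot. The positive
class is DSB by default (configurable): with the majority class
positive the reference operating point (high SN, lower SP, F1 ≈ 0.93)
is reproducible, which is not the case with SSB positive.

Metrics: ACC, SN, SP, MCC (0 by convention when a confusion-matrix
marginal is 0), F1, and AUC by the rank/Mann–Whitney statistic with
midranks — provably equal to trapezoidal ROC integration with tied
scores grouped, which the test suite verifies against an independent
trapezoid implementation.

The **permutation baseline** repeats the exact protocol with training
labels uniformly permuted within each fold (test labels untouched). It
is the package's negative control: near-chance AUC on signal-bearing
data certifies that no information leaks from test folds into training.

## The synthetic world

`generate_dataset()` states the world the tests operate in, mirroring
the reference data where the reference states values:

* class imbalance 873 : 183 by default (scalable);
* lengths uniform on [60, 400], chosen so all three SAA cases occur in
  every dataset;
* class signal: i.i.d. residues from a perturbed uniform distribution —
  DSB adds $\delta/3$ to each of {R, K, H}, SSB adds $\delta/5$ to each
  of {N, G, F, Y, V} (then renormalised), the enrichment directions
  observed in real data; $\delta = 0.08$ is the stated recovery effect
  size and $\delta = 0$ the exchangeable null.

Synthetic PSSMs give the matching residue a high log-odds score (6),
others −2, plus rounded Gaussian noise, and are written in the
PSI-BLAST ASCII dialect so the parser is exercised end to end.

What a green test establishes: that the pipeline recovers a known
composition signal (family and ensemble AUC ≥ 0.85 at $\delta = 0.08$
with n = 400/100) and is honest under the null (all AUC within
[0.4, 0.6] at $\delta = 0$, and the permutation baseline near chance on
signal-bearing data). What it does **not** establish: performance on
real proteins. Real sequences are not i.i.d. — they carry domains,
repeats, disorder and phylogenetic correlation — and real PSSMs encode
conservation structure the generator does not model. The reference
headline numbers (ACC 0.887, AUC 0.919 on the curated UniProt set)
require the original sequence sets and nr-scale profile computation and
are out of scope here.

## Analysis statistics

`residue_frequency_contrast()` and `dipeptide_frequency_contrast()`
compare per-class means of the *raw* frequencies (no square root — the
transform is a modelling device, not a descriptive one); the dipeptide
report keeps entries with |difference| ≥ 0.003 by default, the reporting
cut used for the reference contrast figures.
`property_difference_rate()` computes, per property and SAA part, the
relative difference rate
$X = |\bar K_1 - \bar K_2| / \max(\bar K_1, \bar K_2)$, which is 0 for
equal means, symmetric in the classes, and in $[0,1]$ for non-negative
means. Signed AAindex scales can produce negative means, where the
ratio loses its meaning; the package then computes $X$ on magnitudes and
warns. Which properties differ "significantly" has no stated cutoff in
the reference analysis; `top_difference_properties()` operationalises it
as an upper quantile (default top 25 % per part), explicitly
configurable.

## Worked example

```{r example, eval = FALSE}
ds  <- generate_dataset(n_dsb = 400, n_ssb = 100, delta = 0.08, seed = 11)
pss <- generate_pssm_profiles(ds, seed = 11)
fs  <- featurize(ds, aaindex = load_aaindex_table(), pssms = pss)
cv  <- run_cv(ds, fs, model_config("RF", rf_trees = 300), k = 10, seed = 11)
metrics_table(cv)
```

The README shows the table this run prints. Every number in it is
recomputed by `scripts/acceptance.R` and asserted (at the stated
tolerances) by `tests/testthat/test-acceptance.R`.

## Known limitations

* The i.i.d. sequence generator cannot certify performance on real
  proteins (see above); the vendored AAindex values are a labelled
  synthetic stand-in.
* Eq.-faithful dipeptide normalisation ($N-1$ for all intervals) makes
  interval blocks sum to slightly less than 1; this is by design and
  documented, but differs from per-interval renormalisation used by some
  other tools.
* The SMO solver holds the full kernel matrix in memory — fine for the
  thousands-of-proteins scale this method targets, not for much larger
  corpora.
* No hyperparameter search: the reference method uses library defaults,
  and so does this package.
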