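---
title: "amyforest: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{amyforest: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amyforest)
```

`amyforest` classifies protein sequences as amyloid-forming or not, from
sequence alone. This vignette records the models it implements, the
parameters that matter, and the choices made where the design was genuinely
open. It states no empirical result that the test suite or the acceptance
script does not itself compute.

## The feature system

### 188-D CTD descriptor

The main encoding concatenates amino-acid composition with
composition/transition/distribution (CTD) statistics over eight
physicochemical properties, each a fixed three-class partition of the
20-letter alphabet:

```{r}
names(default_partitions())
length(extract_188d(strrep("ACDEFGHIKLMNPQRSTVWY", 3)))
```

Per property: 3 class-composition values, 3 transition frequencies
(adjacent unordered class pairs normalized by $L-1$), and 15 distribution
values (positions of the 1st, $\lceil 0.25n \rceil$-th,
$\lceil 0.50n \rceil$-th, $\lceil 0.75n \rceil$-th and $n$-th occurrence of
each class, divided by $L$; an absent class contributes five zeros). Totals:
$20 + 8 \times 21 = 188$.

Three conventions had to be fixed because the descriptor family is often
described only loosely:

* **Residue-to-class tables.** The property *names* are standard but their
  class memberships are rarely printed. We ship the canonical CTD
  partitions used by the SVMProt-style 188-D descriptor (see
  `default_partitions()`), and every CTD function accepts an override
  table, so the tables are a documented default rather than a claim.
* **Transition semantics.** Unordered adjacent-pair counts over $L-1$ —
  the standard CTD-T definition.
* **Distribution index rule.** `ceiling(q * n)` with 1-based positions
  normalized by the full length $L$. This makes the block well defined for
  every input including singleton and absent classes, and forces the five
  values within an occupied class to be nondecreasing (a property test
  enforces this).

Feature order is frozen (composition block, then the eight property blocks
in the order above) so serialized models remain valid across sessions.

### Sequence-only Pse-in-One encoders

Of the 22 catalogued methods in five groups, the three sequence-only groups
(11 methods) are implemented; the profile-based group needs PSI-BLAST
PSSMs and the predicted-structure group needs structure predictors, so
those are catalog entries with `supported = FALSE` — selecting one is an
error naming the reason, never a silent omission.

Substrate for the correlation-type encoders is a physicochemical index
table standardized to mean 0, population SD 1 over the 20 residues. The
default triple — hydrophobicity, hydrophilicity, side-chain mass — is the
classical pseudo-AAC choice; any index matrix can be supplied, which also
yields the "General" PseAAC variants.

Definitions as implemented (all means over the $L-g$ valid position pairs):

* AC$(u,g)$: autocovariance of profile $P_u$ about its sequence mean;
* CC$(u_1,u_2,g)$: the analogous cross moment for ordered pairs of
  distinct indices; ACC concatenates AC then CC;
* PDT$(u,g)$: mean of $(P_u(i) - P_u(i+g))^2 / 2$;
* PC-PseAAC: type-I pseudo-AAC with
  $\theta_j$ = lag-$j$ mean of the squared profile differences averaged
  over indices, weight $w$, vector normalized to sum 1;
* SC-PseAAC: type-II, keeping one correlation factor per index per lag. We
  use the squared-difference correlation per index, which makes the
  single-index case reduce *exactly* to PC-PseAAC (a test pins this).

The DR layout is under-specified in the literature we follow, so we define
it and pin it with oracle tests: block $d = 0$ is the 20 single-residue
frequencies; each block $d \ge 1$ holds the 400 ordered residue pairs at
separation $d$, normalized by $L - d$ (length $20 + 400\,d_{max}$).
`distance_pair()` is the unordered variant ($20 + 210\,d_{max}$). The
400-D skip-gram baseline pools ordered adjacent-and-gapped dipeptide counts
uniformly over gaps $0..max\_skip$; "adaptive" gap weighting in the
published variant is unspecified, so uniform weighting is our documented
choice.

Defaults — $k = 2$, $d_{max} = 3$, $lag_{max} = 2$, $\lambda = 2$,
$w = 0.05$, $max\_skip = 3$ — follow common Pse-in-One practice; none is
stated by the source publication, and all are exposed as parameters. The
default combined profile (`default_pse_config()`) is Kmer(2) + AC + PDT +
PC-PseAAC = 434 dimensions; with the 188-D block the recommended
`"188d+pse"` encoder has 622. Which methods the original predictor actually
concatenated is not published; this profile is a reproducible default, not
a reproduction claim.

## Classifier

The random forest is implemented in C++ (Rcpp) following the textbook
recipe: for each of $m$ trees draw a bootstrap sample of size $n$, grow a
CART tree to purity choosing each split from $k$ of the $q$ features by
Gini gain, and predict by majority vote; the vote fraction is the
class-probability score. Defaults $m = 500$, $k = \lfloor\sqrt q\rfloor$,
$n$ = training-set size; the source describes all three only symbolically.
All randomness is drawn from R's RNG, so `set.seed()` (or the `seed`
arguments, which restore the caller's RNG state) makes training
bit-reproducible — a tested contract, not an aspiration.

Numerical details worth knowing: splits are placed at midpoints between
distinct sorted values, never between tied values; a split must improve
Gini by more than $10^{-12}$; leaves tied 50/50 vote negative. A no-network
constraint motivated implementing the forest rather than wrapping an
existing package, which had the side benefit of an exactly specified,
seed-stable algorithm.

The comparison classifiers (`clf_decision_tree`, `clf_naive_bayes`,
`clf_nearest_neighbors`, `clf_logistic`) are deliberately simple pluggable
specs for the paired benchmark harness; they are not tuned and not meant to
reproduce any published comparison table.

## Evaluation protocol

* **Metrics** from pooled confusion counts: SE, SP, ACC, MCC, Precision,
  Recall, F-measure. Zero-denominator cases return 0 and are listed in a
  `flagged` attribute — this avoids NaN propagation in report tables and
  cannot occur in a well-populated two-class evaluation. Fold-averaged
  metrics and the mean CV error are also reported because the field's
  tables are ambiguous about pooling.
* **Folds** are stratified (shuffle within class, deal round-robin with a
  running offset), keeping the class ratio within one example per fold and
  leaving no fold empty up to $K = n$ (leave-one-out). Plain unstratified
  folding was rejected: with a 165/382 imbalance it can produce
  single-class test folds.
* **External validation**: per-class `floor(0.8 n_c)` training split, the
  rest held out; indices are returned.
* **Balancing**: seeded undersampling of the majority class to the
  minority size.
* **ROC/AUC**: a threshold sweep over unique scores with trapezoidal area,
  which equals the tie-corrected Mann–Whitney statistic (tested against a
  brute-force pair count). Vote fractions from an $m$-tree forest have
  granularity $1/m$, which is ample for the curve.

## Synthetic data: what a green test establishes

`generate_dataset()` draws negatives i.i.d. from a background distribution
(uniform by default; a SwissProt-like table is shipped) and positives from
the same distribution with a residue set multiplied by an enrichment
factor and renormalized; an optional first-order smoothing repeats the
previous residue with probability $\rho$. Defaults state the world the
pipeline targets: 165 positives / 382 negatives (the published class
imbalance), lengths uniform on 50–400 (clearing the ≥ 50 filter), and the
hydrophobic set {C, L, V, I, M, F, W} enriched 5-fold — hydrophobic
composition bias is the kind of signal amyloid predictors exploit and the
188-D descriptor is built to detect, and 5× makes it unambiguous.

Under these defaults the acceptance suite requires 10-fold CV with the
622-D encoder and a 500-tree forest to reach ACC ≥ 0.9 and AUC ≥ 0.95, and
the null world (factor 1) to give |mean MCC| < 0.05 over 20 replicates.
The null replicates run at reduced scale (100 sequences, 100 trees, 5
folds) purely for time budget; centering on zero does not depend on scale.

A green run establishes that the encoders expose compositional signal and
that the pipeline neither leaks labels nor invents signal from noise. It
does **not** establish accuracy on real amyloid data: real positives differ
by motif and ordering structure, not just composition, and the curated
benchmark dataset behind the published accuracy figures is not
redistributable, so those figures are out of reach at desk scale and are
not asserted anywhere in this package.

## Redundancy removal

The dataset-construction pipeline the package mirrors used CD-HIT, an
external tool. `greedy_identity_cluster()` is a documented fallback only:
longest-first greedy clustering on an alignment-free identity proxy (exact
column identity for equal lengths, shared 5-mer Jaccard otherwise). Its one
guarantee — no two representatives at or above the threshold under that
proxy — is brute-force tested; it is *not* CD-HIT-equivalent, and the 0.9
default threshold is a configuration value, not a claim about how the
published dataset was built.

## Known limitations

* Profile- and structure-based encoders are catalog stubs by design.
* The identity proxy underestimates similarity between frame-shifted
  homologs of different length.
* Gaussian naive Bayes on 622 correlated dimensions is a weak baseline;
  it is present for harness completeness.
* The forest grows trees to purity; there is no out-of-bag error or
  feature-importance reporting.
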