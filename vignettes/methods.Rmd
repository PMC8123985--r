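---
title: "Predicting protein structural classes with RI-ranked features: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein structural classes with RI-ranked features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strucclass)
```

## The problem

A protein's *structural class* — all-α, all-β, α/β (helices and strands
interspersed), or α+β (helices and strands segregated) — is a coarse but
useful summary of its fold, and for low-similarity sequences it must be
inferred from sequence-derived information rather than by homology.
`strucclass` implements a complete prediction pipeline: four feature
families extracted from the amino-acid sequence and a predicted
three-state secondary-structure string, a random-forest
relative-importance (RI) ranking that selects a small informative subset,
and a one-vs-one RBF-SVM evaluated by the jackknife (leave-one-out) test.

## Feature families

**Sequence content features (PSF).** For word length $k$, the overlapping
$k$-word counts $c(w)$ of a sequence of length $m$ are normalized to
frequencies $c(w)/(m-k+1)$. With $k \in \{1,2\}$ over the 20-letter
alphabet this gives $20 + 400 = 420$ columns, each block summing to 1.

**Sequence position features (PPF).** For each $k$-word, the gaps between
successive (1-based) start positions define an empirical interval
distribution with semi-mean $E = \sum_t t\,p(t)$ and semi-variance
$D = \sum_t t^2 p(t) - E^2$; the feature is the ratio $E/D$. Words with
fewer than two occurrences, or zero semi-variance, get 0: the ratio is
undefined there, and 0 is the least-informative finite convention. The
source material is ambiguous about whether the intended statistic is
$E/D$ or its reciprocal; we use $E/D$ exactly as its defining formula is
printed. Another 420 columns.

**Reduced combined features (RCF).** Residues are mapped by
hydrophobicity to a three-letter alphabet: internal {F,I,L,M,V} → I,
external {D,E,H,K,N,Q,R} → E, ambivalent {A,C,G,P,S,T,W,Y} → A. The
printed definition of the third group in the source material repeats the
external group — a typographical slip; the ambivalent set used here is
the complement of the other two and is the unique choice consistent with
the worked example `ESHFTCISLNEYAMQ → EAEIAAIAIEEAAIE`, which the test
suite pins exactly. Content and position features of the reduced
sequence give $3 + 9 + 3 + 9 = 24$ columns.

**Secondary-structure features (PSSF).** From an H/E/C string of length
$N$: per-element content; first- and second-order composition moment
vectors $\mathrm{CMV}^k_{SE} = \sum_j p_j^k / \prod_{d=1}^{k}(N-d)$ over
the element's positions $p_j$; longest and average maximal-run lengths,
raw and divided by $N$; and the normalized helix/strand alternation
frequency (delete coil runs, collapse to the H/E segment order, count
adjacent unequal pairs, divide by $N$). Two readings required a choice:
the "average segment length" denominator is taken as the *number* of
segments (so the statistic is the mean run length, matching its name),
and alternation is counted on the coil-removed *segment* sequence, not on
residue adjacencies. The proportion of parallel/antiparallel sheets is
excluded: it is not computable from an H/E/C string and no formula for it
exists. The full family has 22 columns; a `"eleven"` preset restricts to
the H/E-only content, CMV1, CMV2, MaxSeg and NMaxSeg plus the alternation
frequency, our best reading of the commonly cited 11-feature set, which
is not enumerated anywhere we could verify — hence the 22-column default.

The default matrix therefore has $420+420+24+22 = 886$ named columns.
The total of 857 features sometimes quoted for this layout cannot be
reconciled with any enumeration of the blocks above; the package reports
its own dimension.

## RI feature selection

Candidate features are shuffled once and partitioned into $s$ contiguous
subsets of $m = \lceil d/s \rceil$ features (default $s = \lceil d/30
\rceil$, i.e. ~30 features per subset; the construction only requires
"large enough", and ~30 per subset keeps every feature in play while
letting each tree see enough candidates to split usefully). For each
subset, $t = 50$ times: half the samples train an entropy/information-gain
binary threshold tree and the other half score it by the *weighted
classification rate* $w$ (macro-averaged recall, which re-balances
unequal class sizes). A feature's RI accumulates, over every node of
every tree that splits on it, $w \cdot IG \cdot n_{\text{node}} /
n_{\text{root}}$ — no normalization by the number of trees, following the
defining sum.

Tree growth details not fixed by the defining description and decided
here once: candidate thresholds are midpoints between consecutive
distinct sorted values; the best (feature, threshold) is chosen by IG
with ties broken toward the lower feature name, then the smaller
threshold; growth stops at purity, at fewer than 2 samples, or when no
split has positive gain. "Recursive" selection is implemented as
rank-once-then-sweep: features are ranked by RI (ties stable by name) and
nested prefixes of sizes from a grid are each scored by jackknife overall
accuracy; the chosen size is the smallest grid value attaining the
maximum. A re-rank-per-round variant was considered and rejected as the
default because no recursion step is defined anywhere; the sweep exactly
reproduces the published size-sweep protocol.

## Classifier and evaluation

The classifier is a one-vs-one RBF-SVM. No SVM implementation is
available in the supported dependency set, so the package ships a compact
SMO (sequential minimal optimization) dual solver with maximal-violating-
pair working-set selection — the same algorithm family that underlies
LIBSVM. Its correctness is certified in the test suite by checking the
KKT optimality conditions of the SVM dual on random problems (a solution
satisfying them to tolerance *is* the SVM solution, so no reference
library is needed).

$(C, \gamma)$ are tuned over the dyadic grid $2^{-10} \dots 2^{10}$
(integer exponents, 441 cells) by stratified 10-fold cross-validation
overall accuracy. **Tie-breaking matters.** On separable data dozens of
cells tie at CV accuracy 1.0, and the tied cells are not equivalent
downstream: with a very loose soft margin (tiny $C$) the dual mass is
capped by the box constraint, the decision function degenerates toward a
constant, and in leave-one-out folds — whose training sets are exactly
one sample short of class balance — every pairwise vote collapses to the
majority class, scoring 0 while balanced CV folds score 1. We therefore
break ties toward the smallest $\gamma$ (smoothest kernel), then the
*largest* $C$: the hard-margin end of the tied region is the one whose
jackknife behaviour matches its CV estimate. Features are standardized
inside every fold using training-fold statistics only (the content and
position blocks live on very different scales, and the RBF kernel
degenerates without it); since centering cancels in kernel distances,
only the per-feature scale matters.

Tuning on the full dataset and then reporting jackknife accuracy — the
published protocol — leaks the held-out label into the tuning step; the
package replicates it by default and offers `nested = TRUE` to re-tune
inside every jackknife fold. In the selection sweep, every candidate
subset is re-tuned by its own grid search: $\gamma$'s useful scale grows
with dimension, so a single tuning made on 886 columns is systematically
wrong for a 10-column subset.

Evaluation reports the 4×4 confusion matrix, per-class accuracy
$TP_i/|C_i|$, overall accuracy $\sum TP_i / \sum |C_i|$, and one-vs-rest
sensitivity, specificity and F1; 0/0 ratios are reported as 0 and
flagged. A singleton class is predicted by a model trained without it —
the prediction is still recorded and the class flagged.

## Synthetic benchmark

Real benchmark sets require external downloads plus a secondary-structure
predictor, so the package ships a generator that emulates labelled
(sequence, structure, class) triples. Secondary structure is drawn from
per-class segment grammars with geometric run lengths: all-α cycles
coil(mean 3)/helix(mean 10); all-β cycles coil(3)/strand(6); α/β strictly
alternates H and E blocks with short (mean 2) coils; α+β emits a helix
region followed by a strand region. The α and β grammars admit a 5%
minority segment of the opposite type so classes are not trivially pure.
Amino acids are then emitted per state from a fixed propensity table
(helix formers enriched under H, β-branched residues under E, flexible
residues under C). Sequence lengths are uniform on 100–300 by default,
matching typical domain lengths in the benchmark collections.

What the generator does and does not establish: it reproduces the
*direction* of every class contrast the features are designed around
(helix content separates all-α from all-β; alternation frequency
separates α/β from α+β — both asserted by simulation in the tests), but
its classes are far better separated than real low-similarity benchmarks,
its residue emission has no positional correlation, and it cannot emulate
prediction noise from a real secondary-structure predictor. A green
end-to-end test therefore establishes that the pipeline recovers planted
class structure, not that it attains any published benchmark accuracy —
those numbers need the external datasets and are deliberately out of
scope.

The planted-matrix generator for selection benchmarks uses unit-variance
Gaussian columns; informative columns receive class means spaced `effect`
SD apart with the class order permuted per column, so planted columns
carry complementary rather than redundant signal.

## Numerical and degenerate-input conventions

- SPF and segment statistics of absent elements: 0 (documented above).
- Entropy uses $0 \log 0 = 0$; IG of an executed split is $\ge 0$.
- SMO tolerance $10^{-3}$ (KKT gap), iteration cap $10^5$; constant
  feature columns get scale 1 during standardization.
- All stochastic stages draw from one seeded generator
  (`withr::with_seed`), and every writer formats numbers at full
  precision, so a config plus seed reproduces every artifact
  byte-identically.
- The one-vs-one vote breaks ties toward the smaller class index, and a
  decision value of exactly 0 votes for the smaller class of the pair —
  both deterministic.

## Known limitations

- The RBF-SVM solver is O(n²) per fit and the jackknife refits n models;
  a few hundred samples is the comfortable regime (the 200-sample
  end-to-end run takes ~2–3 minutes on one CPU).
- The `"eleven"` secondary-structure preset is a documented best guess.
- `read_ss2` assumes three-state input; no 8→3 state mapping is applied.
- Config files are JSON rather than YAML to stay within the declared
  dependency set.
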