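# strucclass

Protein structural class prediction for low-similarity sequences, with
random-forest relative-importance (RI) feature selection.

## The problem

A protein's structural class — **all-α**, **all-β**, **α/β** (helices and
strands interspersed), or **α+β** (helices and strands segregated) — is a
coarse fold descriptor that is hard to predict from sequence alone when no
close homolog exists. Combining many feature families helps, but naive
concatenation piles up redundant columns that dilute the classifier.
`strucclass` implements the full pipeline for this setting:

1. **Feature extraction** from the amino-acid sequence and a predicted
   H/E/C secondary-structure string, four families, 886 named columns:
   - *PSF* — overlapping k-word frequencies, k ∈ {1,2}: entries
     c(w)/(m−k+1) (420 columns);
   - *PPF* — k-word position features: for each word, the ratio
     Semi-E/Semi-D of the semi-mean to the semi-variance of the gaps
     between successive occurrences (420 columns);
   - *RCF* — the same content/position features on the hydrophobicity-
     reduced alphabet {I, E, A} (24 columns);
   - *PSSF* — secondary-structure descriptors: per-element content,
     composition moment vectors CMV¹ and CMV², longest/average segment
     lengths (raw and normalized), and the helix/strand alternation
     frequency NAlt (22 columns).
2. **RI feature selection**: s·t entropy/information-gain decision trees
   on random feature subsets and random half-samples; each feature's
   relative importance is RI(g) = Σ_trees w · Σ_nodes IG·n_node/n_root,
   where w is the tree's macro-averaged recall on its held-out half.
   Features are ranked by RI and nested prefix sizes are swept.
3. **Classification**: one-vs-one RBF-SVM (in-package SMO solver), with
   (C, γ) tuned on the dyadic grid 2⁻¹⁰…2¹⁰ by stratified 10-fold CV, and
   **jackknife** (leave-one-out) evaluation reporting per-class
   sensitivity/specificity/F1 and overall accuracy.
4. A **synthetic benchmark generator** (class-dependent secondary-structure
   grammars + per-state residue propensities), so the whole pipeline is
   testable offline with no downloads.

## Worked example

```r
library(strucclass)

# the hydrophobicity reduction (I = internal, E = external, A = ambivalent)
reduce_sequence("ESHFTCISLNEYAMQ")
#> [1] "EAEIAAIAIEEAAIE"

# full pipeline on a simulated benchmark: 4 classes x 50 records
cfg <- run_config(simulate = list(n_per_class = 50, length_range = c(100, 300)),
                  seed = 11, out_dir = "run1")
res <- run_pipeline(cfg)
#> stage simulate: 50 records/class
#> stage extract: families PSF+PPF+RCF+PSSF
#> stage select: RI forest over 886 features
#> ...
#> done: chosen 10/886 features, accuracy 1.0000 (full 0.5600)

print(res$report_chosen)
#> eval_report: overall accuracy 1.0000
#>       class  n accuracy    sens    spec      f1
#>   all-alpha 50  100.00% 100.00% 100.00% 100.00%
#>    all-beta 50  100.00% 100.00% 100.00% 100.00%
#>  alpha+beta 50  100.00% 100.00% 100.00% 100.00%
#>  alpha/beta 50  100.00% 100.00% 100.00% 100.00%

head(sort(res$ri$ri, decreasing = TRUE), 4)
#> ss_content_H  ss_cmv1_H  ss_cmv2_H  ss_cmv1_E
#>        41.97      35.67      34.57      28.80
```

Read the numbers this way: the RI ranking put the secondary-structure
descriptors on top (helix content first — exactly the features the
synthetic classes are built around), the size sweep found that the top 10
of 886 columns suffice, and the jackknife on those 10 columns classified
all 200 simulated proteins correctly while the un-selected 886-column
matrix managed only 56% — the redundancy-removal effect the selection
stage exists for. Accuracies on *real* low-similarity benchmarks are much
lower and require external datasets plus a secondary-structure predictor
(out of scope here); see the methods vignette for what the synthetic
result does and does not establish.

Real data go in the same way: a FASTA file, per-protein `.ss2` files (or a
FASTA of H/E/C strings), and a two-column TSV of id → class
(`a`, `b`, `a/b`, `a+b` accepted):

```r
ds <- assemble_dataset("seqs.fasta", "ss.fasta", "labels.tsv")
fm <- build_feature_matrix(ds)                     # 886 named columns
ri <- ri_scores(fm$X, ds$label, seed = 1)          # RI forest
sel <- select_feature_subset(fm$X, ds$label, ri, size_grid = c(10, 25, 50))
params <- svm_grid_search(fm$X[, sel$chosen], ds$label, seed = 1)
report <- jackknife_evaluate(fm$X[, sel$chosen], ds$label, params)
```

A command-line front end with subcommands `simulate`, `extract`,
`select`, `evaluate`, `run` is installed at
`system.file("cli", "strucclass", package = "strucclass")`.

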