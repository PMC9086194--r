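# repsel

Ensemble feature selection for short, wide binary-classification
problems — in particular V/J gene usage derived from adaptive immune
receptor repertoire (AIRR) sequencing, where a few dozen subjects face
hundreds of correlated VJ-combination features and any single
feature-selection method is unstable.

## What it does

The pipeline has two stages:

1. **Aggregation.** Several base selectors run on the data —
   information gain, correlation-based feature selection (CFS),
   SVM-RFE, Boruta-style shadow-feature screening, Vita-style
   cross-validated permutation importance, and the lasso.  Their
   outputs are put on a common rank scale (subset selectors: selected
   features tied at rank 1, unselected at rank G) and aggregated by
   *best position*: `aggRank_j = min` over selectors of feature *j*'s
   rank.  The union of selected features, expanded with features whose
   absolute correlation with a selected one exceeds ρ, forms the
   candidate set.

2. **Permutation-assisted group lasso.** Candidates are partitioned
   into blocks with all pairwise |correlation| > ρ (complete-linkage
   clustering cut at 1 − ρ) and fitted with the logistic group lasso

       Q_λ(β) = −ℓ(β) + λ Σ_b s_b ‖β_b‖₂ ,
       s_b = (min aggregated rank in block b) · √L_b ,

   on an augmented design `X_A = (X, X_π)` containing a row-permuted
   copy of the candidate matrix.  Each block's importance is its entry
   value `R_b = sup{λ : β_b ≠ 0}` along a 100-point path; the largest
   pseudo-block entry value `T_π = max_{b>B} R_b` is the noise
   benchmark, and a round selects `Ŝ_π = {b : R_b > T_π}`.  Over
   `K = 50` independently drawn permutations, blocks selected in at
   least a fraction `τ = 0.5` of rounds are reported.

The package also ships the surrounding apparatus: an AIRR rearrangement
reader and VJ-usage/log2-ratio matrix builder, a synthetic-data
generator with correlated causal groups and a logistic outcome (eight
registered scenarios), selection-quality metrics (FDR, sensitivity, F1,
Jaccard stability, empirical power, weighted relative frequency), eight
reference classifiers, a cross-validated selection wrapper, and a
benchmark harness.  A thin command-line front-end lives in
`inst/cli/repsel.R`.

## Worked example

```r
library(repsel)

sc  <- scenario_registry()[["n100_G600_eta0.5"]]   # n=100, G=600, 30 causal
sim <- simulate_dataset(sc, seed = 1)
res <- ensemble_select(sim$X, sim$y, seed = 1)
res
#> <repsel_ensemble>
#>   77 candidate(s) in 43 block(s); K = 50, tau = 0.5
#>   selected 8 block(s) / 24 feature(s)
#>   features: 1 2 3 4 5 6 7 8 9 11 12 13 14 15 16 17 18 19 20 191 ...

m <- selection_metrics(res$selected, which(sim$causal), sc$G)
sprintf("FDR %.3f  sensitivity %.3f  F1 %.3f", m$fdr, m$sensitivity, m$f1)
#> "FDR 0.208  sensitivity 0.633  F1 0.704"
```

The selected set recovers 19 of the 30 causal features (columns 1–30
are the three causal groups) with a handful of false positives; a plain
lasso on the same draw keeps far fewer causal features and is much less
stable across replicates (see the benchmark harness,
`run_benchmark()`).

For repertoire data, build the feature matrix first:

```r
tabs <- lapply(list.files("airr_dir", full.names = TRUE),
               read_airr_rearrangements)
M <- compute_vj_usage(tabs)        # samples x "TRBV19/TRBJ2-1"-style columns
res <- ensemble_select(unclass(M), labels, seed = 1)
```

## Documentation

The methods vignette (`vignettes/ensemble-methods.Rmd`) describes the
model and its assumptions, the default parameters, what the synthetic
generator does and does not emulate, the numerical choices in the path
solver, and known limitations.
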