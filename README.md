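# bnstability

Boolean-network stability analysis of gene expression time series from two
phenotype groups. The package is aimed at systems biologists who want to
ask, from short ordered expression series (for example muscle biopsies of
young versus aged donors), whether the modeled signaling pathway of one
group is measurably less robust to perturbations than that of the other.

## What it computes

The pipeline has four stages, each exposed as ordinary R functions
returning classed S3 objects:

1. **Binarization** (`binarize_matrix()`): each gene's real-valued series
   is thresholded at the strongest discontinuity of its
   dynamic-programming-optimal step functions (one shared threshold over
   all samples of both groups), with a seeded bootstrap significance test;
   genes that are not significantly binarizable (p ≥ 0.05) are dropped.
2. **Inference** (`reconstruct()`): per group, the best-fit extension of
   partially defined Boolean functions returns, for every gene, all
   Boolean rules of minimal error and smallest input-set size explaining
   the observed transitions x(t) → x(t+1); ties and don't-cares are
   handled deterministically. The result is a probabilistic-network-style
   candidate set with equal weight per rule.
3. **Perturbation** (`stability_experiment()`): concrete synchronous
   networks are sampled uniformly from the candidate sets; states drawn
   from three classes (random, successor of random, attractor member) are
   given a temporary single-bit flip, and the damage after h transitions
   is the normalized Hamming distance

       Hn(x, x') = (1/n) * sum_i |x_i - x'_i|

   evaluated at horizons h = 1 and h = 5, averaged per network.
4. **Comparison** (`compare_stability()`): the two groups' per-network
   mean distances are compared per (state class, horizon) with two-sided
   Wilcoxon rank-sum tests.

`run_study()` chains all four stages behind one master seed and returns a
`bn_study` object with `print()`, `summary()` and `plot()` methods;
`write_study_outputs()` emits rule files, adjacency tables, the stability
table and a JSON manifest that makes the run recomputable. A synthetic
two-group study generator (`generate_study()`) provides seeded
ground-truth data so the whole pipeline is testable offline.

## Worked example

```r
library(bnstability)

study_src <- generate_study(synthetic_study_spec(seed = 7))
study <- run_study(study_src$expression, study_src$groups,
                   n_bootstrap = 300, n_networks = 50, n_states = 50,
                   seed = 11)
study
```

```
Two-group Boolean network stability study
  genes: 22 -> 22 significantly binarizable (p < 0.05 )
  young: 101 dependencies, mean inputs/function 1.864
  aged: 88 dependencies, mean inputs/function 1.736

Mean normalized Hamming distance per (class, horizon):
     class horizon  young   aged
 attractor       1 0.0501 0.0451
 attractor       5 0.0768 0.0538
    random       1 0.0493 0.0431
    random       5 0.0720 0.0545
 successor       1 0.0515 0.0457
 successor       5 0.0765 0.0565

Group comparison (Wilcoxon rank-sum):
     class horizon p_value
    random      h1 0.00173
 successor      h1 0.00466
 attractor      h1 0.00468
    random      h5 0.00124
 successor      h5 0.00413
 attractor      h5 0.00161
```

All 22 synthetic genes pass the binarization filter, both groups'
candidate rule sets explain their series without error, and the mean
damage of a single temporary bitflip — about 0.05 of the 22 bits after one
transition, growing by horizon 5 — differs significantly between the two
generated groups at every start-state class. On real data the same object
is produced from a gene-by-sample matrix: preprocess with
`preprocess_expression()` (geometric-mean collapse of duplicate gene rows,
arithmetic-mean collapse of duplicate-age samples, age ordering, optional
gene-panel restriction; `nfkb_gene_panel()` ships a 22-gene NF-κB signaling
panel), then call `run_study()` with per-column group labels.
`read_series_matrix()` parses GEO series-matrix files, and
`fetch_geo_series_matrix()` can download one when a network connection is
available.

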