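# torsioncda

Torsion-weighted graph learning for circRNA–drug association prediction.

Circular RNAs (circRNAs) modulate drug response and resistance, and mapping
which circRNA affects sensitivity to which drug is central to biomarker and
therapeutic-target discovery. Known associations form a bipartite graph of
circRNAs and drugs; `torsioncda` ranks the unobserved pairs by learning from
that graph's local geometry.

## The method

For every association edge `(u, v)` the package extracts the subgraph within
`P` BFS hops of either endpoint, builds its clique complex up to dimension
`Q`, and computes the **log analytic torsion** from the pseudo-determinants
of the complex's Hodge Laplacians `Z_g = B_gᵀB_g + B_{g+1}B_{g+1}ᵀ`:

    log T = ½ log|Z₁|              (Q = 1)
    log T = ½ log|Z₁| + log|Z₂|    (Q = 2)

where `|Z|` is the product of non-zero eigenvalues. For triangle-free
subgraphs the matrix-tree theorem ties this to spanning-tree counts
(`|Z₁| = n·τ`), which the tests verify by brute-force enumeration. The
torsion then weights graph-neural message propagation:

    h_a ← σ( Σ_{b ∈ N(a)∪{a}}  log T(S_{a,b}) / √(d_a d_b) · W h_b )

with GCN (default), GAT (torsion as an attention-logit bias) and GIN
(torsion as a neighbor weight) variants. An MLP decoder scores each pair
from `[h_u + h_v, h_u ⊙ h_v, h_u, h_v]`, trained with binary cross-entropy
under stratified k-fold cross-validation with balanced negative sampling.
Setting `torsion_enabled = FALSE` reduces every encoder to its standard
unweighted form (the ablation arm).

## A worked example

```r
library(torsioncda)

tbl <- generate_block_model(block_model_spec(60, 40, n_blocks = 2,
                                             p_in = 0.5, p_out = 0.03,
                                             seed = 7))   # 606 positives
g     <- cda_graph(tbl)
cache <- torsion_weights(g, order_p = 1, max_dim_q = 1)
head(torsion_table(cache, g), 3)
#>   circ_id drug_id log_torsion
#> 1 circ_1  drug_1         22.2
#> 2 circ_1  drug_11        19.3
#> 3 circ_1  drug_13        23.3

cfg <- cda_config(hidden_dim = 32, out_dim = 16, lr = 1e-2,
                  epochs = 300, folds = 5, seed = 7, min_epochs = 150)
cv <- cda_cv(tbl, cfg)
glance(cv)
#>     auc  aupr    f1 accuracy recall  auc_sd ...
#> 1 0.790 0.718 0.793    0.773  0.871  0.0332 ...

fit <- cda_train(tbl, cfg)
rank_candidates(fit, "circ_1", top_k = 5)
#>   drug_id score
#> 1 drug_5  0.712
#> 2 drug_21 0.712
#> ...
```

The `log_torsion` column measures how structurally entangled each
association's neighborhood is (an isolated edge scores `½·ln 2 ≈ 0.35`;
dense neighborhoods score in the tens). `glance(cv)` reports held-out
metrics averaged over folds — here the model recovers the planted block
structure with AUC 0.79 on a generator whose information-theoretic ceiling
is itself well below 1 (see the vignette). `rank_candidates()` scores all
drugs not already linked to the query circRNA in training, highest first.

`tidy(cv)` gives per-fold metrics, `autoplot(cv)` a metric overview plot,
and `autoplot(fit)` the training-loss trace.

## Command line

A thin CLI wraps the same functions:

```sh
inst/cli/torsioncda simulate --out assoc.tsv --n-circ 100 --n-drug 80 --seed 1
inst/cli/torsioncda torsion  --associations assoc.tsv --out torsion.tsv
inst/cli/torsioncda cv       --associations assoc.tsv --out metrics.json --folds 5 --seed 1
inst/cli/torsioncda train    --associations assoc.tsv --out model.rds
inst/cli/torsioncda predict  --checkpoint model.rds --query circ_1 --out top.tsv --top-k 20
```

Logs go to stderr, results to files; `--no-torsion` runs the ablation arm.

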