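# comtop

Consensus protein residue–residue contact prediction by mixed integer
linear optimization.

## What it does, and for whom

Residue–residue contact predictors (coevolution analysis, classical machine
learning, deep networks) make partially independent errors, and combining
them beats any one of them — if the combination weights are chosen well.
`comtop` is for structural bioinformaticians who have per-protein contact
confidence scores from several upstream predictors (CASP RR files or plain
score tables) plus native contact maps for a training set, and who want a
principled consensus predictor and the standard top-kL evaluation machinery
around it.

The consensus score of a residue pair (i, j) of protein p is the weighted
sum of the methods' min-max-normalized confidences,

    S(p,(i,j)) = Σ_m λ_m · confS(p,(i,j),m),     Σ_m λ_m = 1,  λ_m ≥ 0,

and the top-kL pairs by S are reported as contacts (k ∈ {5, 3, 2, 1, ½, ⅕};
one weight vector is learned per cutoff). The weights are **not** fit by
regression: they solve the mixed integer linear program

    max  Σ_p y_p − Σ_p ε_p
    s.t. wrong(p) − correct(p) + s·ε_p ≤ 1 − y_p − δ     for every pair p
         Σ_m λ_m = 1,  λ_m ≥ 0,  y_p ∈ {0,1},  ε_p ≥ 0

where correct(p) = Σ_m λ_m·confS·predSS and wrong(p) its complement over
the binary label matrix predSS, so the objective maximizes the number of
pairs whose correct score mass outweighs their incorrect score mass by
more than δ. Missing (pair, method) cells — methods return different
truncated candidate lists — are filled by the scheme's imputation rules
before training. Both slack conventions are implemented (`soft_margin`,
the default, where ε buys constraint slack; and `hard_count`, where ε
is inert and the objective is a pure count).

The optimization core is self-contained: a dense two-phase simplex LP
solver, an exact cutting-plane solve of the soft-margin formulation (which
reduces to maximizing a concave piecewise-linear function of λ), and
branch-and-bound for the hard-count formulation, with every returned solution
re-verified against the constraints by direct arithmetic and a brute-force
simplex-grid oracle for independent checking. A synthetic corpus generator
with controllable predictor reliability and inter-method overlap makes the
whole pipeline testable without running any upstream predictor. See the
vignette (`vignettes/consensus-contact-prediction.Rmd`) for the full
methods account.

## Worked example

```r
library(comtop)

## a synthetic corpus: 6 proteins, 3 predictors of reliability 0.85/0.55/0.30
corpus <- generate_corpus(synth_config(n_proteins = 6, seed = 2))

fit <- comtop(corpus, specs = c("2L", "L", "L/5"))
fit
#> Consensus contact predictor (MILP-weighted)
#>   methods: mA, mB, mC
#>   margin mode: soft_margin, delta = 0.0001, impute = literal
#>   weights per sub-model:
#>         mA     mB     mC
#> 2L  0.4440 0.3756 0.1804
#> L   0.6201 0.2390 0.1409
#> L/5 0.3333 0.3333 0.3333

preds <- predict(fit, corpus)
evaluate_suite(preds, corpus$truths)[, 1:6]
#>   spec accuracy coverage specificity   npv   mcc
#> 1   2L    0.487    0.973       0.948 0.999 0.668
#> 2    L    0.932    0.932       0.997 0.997 0.929
#> 3  L/5    1.000    0.196       1.000 0.961 0.434
```

The weight rows are the learned λ per sub-model: the reliable predictor mA
dominates where the instance still contains hard pairs (2L, L), while at
the smallest cutoff every retained pair is already discriminated and the
objective is flat, so the solver returns the uniform point. In the
evaluation table, accuracy is the fraction of predicted contacts that are
native (macro-averaged over proteins) — here 93.2% of top-L consensus
predictions are true contacts, against 86.0% / 57.7% / 30.1% for the three
methods alone (`method_baseline(corpus, "mA", "L")` etc.) — and the
accuracy/coverage columns show the usual trade-off as the prediction
budget grows.

File-based workflows use `read_rr()` / `write_rr()` (CASP RR format),
`read_pair_list()` for truth files, `contacts_from_structure()` to derive
native maps from PDB files (Cβ–Cβ ≤ 8 Å, Cα for glycine, separation ≥ 6 by
default), and `write_weights()` / `read_weights()` for the versioned JSON
weights document. The same pipeline is scriptable from the shell:

```sh
inst/cli/comtop pipeline --config run.yaml --out results/
inst/cli/comtop train --scores scores/ --truth truth/ --specs 5L,3L,2L,L,L/2,L/5 --out model/
inst/cli/comtop predict --scores scores/ --weights model/weights.json --specs L/5 --out preds/
```

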