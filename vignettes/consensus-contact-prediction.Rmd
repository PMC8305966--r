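---
title: "Consensus residue–residue contact prediction by mixed integer linear optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus residue-residue contact prediction by mixed integer linear optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comtop)
```

## The problem

A residue–residue contact is a pair of sequence-separated residues whose
representative atoms (Cβ; Cα for glycine) lie within a distance threshold —
conventionally 8 Å with sequence separation at least 6 — in a protein's
native structure. Predicted contact maps are the standard scaffold for
template-free structure modelling, and predictions are conventionally
assessed on the top-kL highest-confidence pairs for a protein of length L,
with k ∈ {5, 3, 2, 1, 1/2, 1/5}.

Individual contact predictors (coevolution-based, classical machine
learning, deep learning) make partially independent errors. `comtop`
implements a consensus scheme that learns one weight per upstream predictor
and scores each candidate pair by the weighted sum of the predictors'
confidence scores. What distinguishes the scheme from averaging or
regression-style stacking is the training criterion: the weights maximize
the **number of residue pairs that are correctly discriminated**, i.e. pairs
for which the weighted score mass of correct predictions exceeds that of
incorrect predictions. That count objective over simplex-constrained weights
with per-pair binary indicators is a mixed integer linear program (MILP).

## Score preparation

For each protein and method, raw confidence scores are min-max normalized,

$$ z_{ij} = \frac{x_{ij} - \min x}{\max x - \min x}, $$

so every method speaks on a common [0, 1] scale. When all scores are equal
the mapping is undefined; the package returns all zeros, the conservative
"no ranking signal" choice. Each method then contributes its top candidate
pairs — `floor(min(k, 4.5) · L)` pairs for the sub-model at cutoff kL, so
the 5L sub-model uses a 4.5L trim of each method's top-5L list and smaller
cutoffs use their own kL. The training universe for a protein is the
**union** of the methods' retained pairs: the missing-value rules below only
exist because methods disagree about which pairs they return, which is
only possible under a union universe.

Two matrices are built per protein over (pairs × methods):

* `confS`, the normalized confidence scores, and
* `predSS`, binary labels — for a returned pair, 1 exactly when the pair is
  a native contact (the method's claim was correct).

Cells where a method did not return the pair are *missing* and are filled
by two rules:

* **Scores.** A missing score on a native contact becomes
  `(x_p − x_p)/y_p · 1000`, with `x_p`, `y_p`, `z_p` the per-protein
  minimum, maximum and mean of the observed scores. This expression is
  self-cancelling — it evaluates to exactly 0 — and the package implements
  it literally as the default (`impute_mode = "literal"`). Because the
  ×1000 factor suggests a non-zero value was intended, a `"floor"`
  alternative substituting `x_p` for the contact branch is provided and
  tested; both keep every imputed value inside [0, 1], which the MILP's
  big-M reasoning relies on. A missing score on a non-contact becomes
  `z_p`.
* **Labels.** A method's silence about a non-contact counts as a correct
  negative (label 1); silence about a native contact counts as a miss
  (label 0). This is the only self-consistent reading of the stacked
  imputation rule: not returning a pair *is* a prediction that it is not in
  contact.

At **prediction time** the contact status of a pair is unknown, so the
truth-dependent rules cannot apply; a missing cell is filled with 0 — a
method that did not return a pair lends it no support.

## The training MILP

Let `M` index methods, `p` residue pairs pooled over the training proteins,
and write for pair `p` at weights λ

$$ \mathrm{correct}(p) = \sum_m \lambda_m\,\mathrm{confS}_{pm}\,\mathrm{predSS}_{pm}, \qquad
   \mathrm{wrong}(p) = \sum_m \lambda_m\,\mathrm{confS}_{pm}\,(1 - \mathrm{predSS}_{pm}). $$

The program is

$$ \max_{\lambda, y, \epsilon}\; \sum_p y_p - \sum_p \epsilon_p
   \quad\text{s.t.}\quad
   \mathrm{wrong}(p) - \mathrm{correct}(p) + s\,\epsilon_p \le 1 - y_p - \delta,
   \qquad \sum_m \lambda_m = 1,\ \lambda \ge 0,\ y_p \in \{0,1\},\ \epsilon_p \ge 0. $$

Design decisions embedded here:

* **δ (default 1e-4).** The discrimination rule is a strict inequality
  ("correct mass exceeds wrong mass"), which no LP solver can express; the
  standard conversion subtracts a small positive δ from the right-hand
  side. δ is far below any meaningful score margin; it is configurable.
* **The sign `s` of the slack.** With `s = +1` (`margin_mode =
  "hard_count"`) the slack only *tightens* the constraint while the
  objective penalizes it, so every optimal solution has ε = 0 and the
  objective is a pure discrimination count. With `s = −1`
  (`"soft_margin"`, the default) ε buys constraint slack at objective
  cost — the standard behaviour of a soft margin variable, which is what
  the slack is evidently meant to be. Both modes are implemented and
  tested; the hard-count mode is also what the brute-force oracle checks.
* **Big-M = 1.** Since Σλ = 1 and all scores (including imputed ones) lie
  in [0, 1], |wrong − correct| ≤ 1, so the `1 − y` right-hand side is a
  valid big-M linearization.
* **Per-protein aggregate indicators** (a protein-level counterpart of
  `y_p` with its own slack) are a natural extension, but no constraint ties
  them to the rest of the model, so the package deliberately does not
  invent one; the pair-level program above is complete as stated.
* Six **sub-models** are trained independently, one per reporting cutoff
  kL ∈ {5L, 3L, 2L, L, L/2, L/5}, each on candidate lists of its own size;
  weights are reported per sub-model. The fit's overall method ranking is
  the ordering of the mean weight across sub-models.

## Solving it exactly without an external solver

The package carries its own optimization core; both paths end with the
returned solution re-verified against every constraint by direct
arithmetic, independent of the solver.

**Soft-margin mode reduces to a linear program.** For fixed λ the program
separates by pair, and the per-pair optimum of `y − ε` is
`min(1, 1 − δ − a_p(λ))` with `a_p = wrong − correct` linear in λ. The
training objective is therefore a concave piecewise-linear function of λ
over the simplex, which Kelley's cutting-plane method maximizes exactly:
each evaluation yields an exact supporting hyperplane, the master LP (a
dense two-phase simplex on at most |M|+2 variables) gives an upper bound,
and the loop stops when the bound meets the best evaluated point (relative
tolerance 1e-8). The unit weight vectors and the uniform vector are seeded
as initial cuts, so the solved objective dominates every single-method
weighting *by construction*, not merely by convergence.

**Hard-count mode is a genuine combinatorial problem** — maximize the number
of satisfiable discrimination constraints — and gets branch-and-bound over
the binary `y`: node relaxations are LPs in (λ, y ∈ [0,1]) solved by the
same simplex core, best-bound node selection, branching on the most
fractional indicator, incumbents from evaluating the node relaxation's λ.
It is guard-railed to 400 pairs (configurable), which covers verification
and small training runs; large-scale training uses the soft-margin mode.

A brute-force oracle (`brute_force_train`) enumerates the full simplex grid
at step ≥ 0.01 and evaluates the discrimination count at every point; the
test suite requires the branch-and-bound objective to be at least the grid
optimum on randomized instances, with exact agreement whenever the grid
attains the optimal discrimination set.

One boundary subtlety: the MILP constraint admits `y_p = 1` when the margin
equals δ exactly (closed inequality), while the count oracle uses the
strict reading; LP vertices sit exactly on that boundary, so the solver
counts with the closed rule plus a 1e-9 numerical slack. The two readings
differ only on ties at exactly δ.

## Prediction and evaluation

Prediction is closed-form — no optimization runs: the consensus score of a
pair is `S = Σ_m λ_m confS_m` over the assembled candidate universe (the
union of the methods' top-4.5L lists), and the top-kL pairs by `S` are
reported, ties broken by (smaller i, smaller j) everywhere for platform
independence.

Evaluation follows the standard contact-prediction metrics: accuracy
(TP/(TP+FP)), coverage (TP/(TP+FN)), specificity (TN/(TN+FP)), NPV
(TN/(TN+FN)) and MCC, with the 0/0 MCC convention of returning 0. The
negative universe — which specificity and NPV require but top-kL reporting
never delimits — is taken to be all pairs with separation ≥ 6 and j ≤ L.
Corpus metrics are macro-averaged (computed per protein, averaged over
proteins), the CASP convention; pooled counts are reported alongside.
Method redundancy is summarized by pairwise Jaccard coefficients of
returned pair sets, and pairwise method comparison by Bland–Altman
analysis with limits of agreement at bias ± 2·SD (the convention used in
this literature, not ±1.96·SD).

## The synthetic corpus generator

Real upstream predictors are expensive and external, so testing and
benchmarking run on a synthetic corpus (`generate_corpus`) that emulates
the relevant *structure* of the real data:

* contact maps with `round(density · L)` contacts biased toward short
  separations (weight ∝ 1/(j−i)) for near-diagonal banding;
* per-method scores `ρ · 1[contact] + (1−w) · private + w · shared` with
  `private, shared ~ U(0,1)`: reliability ρ tunes ranking quality smoothly
  (ρ = 0 is uninformative, ρ = 1 essentially perfect), and the shared
  noise weight `w` tunes inter-method Jaccard overlap — the redundancy
  structure that makes similar methods share weight. The noise term keeps
  full amplitude at every ρ; attenuating it by (1−ρ) would make every
  predictor with ρ > 0.5 perfectly separable and the reliability dial
  vacuous;
* each method returns only its top-5L pairs, reproducing the truncated,
  mutually disagreeing candidate lists that force the imputation rules;
* scores are quantized to the 6 decimals that the RR text format prints,
  so a corpus written to disk and read back is bit-identical — this is
  what makes the end-to-end pipeline byte-reproducible.

Defaults are the study conditions used throughout the tests: 10 proteins,
L ∈ [40, 80], contact density 1 per residue, three methods of reliability
0.85/0.55/0.30 with independent errors. What the generator does **not**
emulate: physically consistent geometry (transitivity of contacts,
secondary-structure patterns), sequence content, or realistically
heavy-tailed score distributions. Passing tests demonstrate the
correctness of the machinery and the qualitative behaviour of the
consensus (dominance over single methods, weight-reliability recovery, the
accuracy/coverage trade-off across cutoffs) — not accuracy levels
transferable to real predictor ensembles.

```{r weights-demo}
corpus <- generate_corpus(synth_config(seed = 1))
fit <- comtop(corpus)
round(coef(fit), 3)
```

The large-cutoff sub-models, whose instances contain many hard pairs,
spread informative weight; at the smallest cutoffs nearly every retained
pair is already discriminated by any reasonable weighting, the objective
is flat, and the solver legitimately returns the uniform point — weight
values at small cutoffs are only weakly identified, which is why the
overall method ranking uses the mean across sub-models.

## Numerical choices and problem sizes

* Tie-breaks: (score descending, i ascending, j ascending) in every
  selection; duplicate pairs in an RR file keep the maximum confidence.
* Degenerate inputs: all-equal scores normalize to zeros; a protein whose
  tensor is entirely missing is an error (its statistics are undefined);
  an empty prediction yields NaN accuracy with a warning rather than a
  silent 0.
* The test suite and the acceptance script train six sub-models on
  10-protein corpora (a few thousand candidate pairs per sub-model, a few
  seconds per corpus) and verify the solver on 20 random 5–30-pair
  instances against full grid enumeration; these sizes exercise every code
  path while keeping the whole suite under a minute.
* Training guardrails (200 proteins by default, overridable) reflect that
  the cutting-plane solve scales linearly per iteration in the number of
  pairs, while hard-count branch-and-bound is exponential in the worst
  case and capped at 400 pairs.

## Limitations

* Weights are global, not per-protein or per-separation-band; a method
  that excels only on long-range contacts is averaged over.
* The prediction-time imputation (0 for missing cells) is a package
  choice; the training-time rules cannot be applied without truth, and
  alternatives (e.g. per-protein mean) would reward methods for silence.
* The soft-margin objective awards partial credit `1 − δ − a_p` to
  near-discriminated pairs; its optimal value is therefore not an integer
  count. The hard-count mode preserves count semantics exactly and is the
  mode compared against the enumeration oracle.
* Bland–Altman limits assume approximately symmetric differences; with 10
  proteins the ±2SD limits are descriptive, not inferential.
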