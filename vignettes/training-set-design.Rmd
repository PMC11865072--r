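---
title: "Training-set design for gBLUP: model, criteria, and exchange search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training-set design for gBLUP: model, criteria, and exchange search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gblupdesign)
```

## The model and what is assumed known

gBLUP is a linear mixed model with one random effect per individual,
`y = X beta + Z gamma + e`, `gamma ~ N(0, sigma_g^2 G)`,
`e ~ N(0, sigma_e^2 I)`, with `Z = I` on the phenotyped units. The genomic
relationship matrix `G` over all `N` candidates and the variance ratio
`lambda = sigma_e^2 / sigma_g^2` are treated as known; estimating them (REML
or otherwise) is out of scope, as are multi-environment fixed effects,
genotype-by-environment random effects and multi-trait extensions. `G` is
assumed nonsingular; `grm()` enforces a smallest-eigenvalue floor (default
`1e-8`) and offers an identity-blending hook `(1 - eps) G + eps I` because
marker-derived GRMs are routinely rank-deficient.

Everything the design problem needs follows from the mixed-model-equation
covariance. All of it is computed on the proportional (sigma-free) scale —
`M(xi) = D'D + lambda B` instead of the sigma-weighted version, and
`V = G(xi) + lambda I` in the projection — because no design quantity in the
package depends on `sigma_g^2` and `sigma_e^2` except through `lambda`, and
the coefficient of determination is a variance ratio, hence scale-free. The
random-effect block `H22` of `M^{-1}` is the prediction error variance (PEV)
matrix on the support set.

Two deliberately different routes compute the same quantities and are tested
against each other:

* `build_mme()` forms `M` and inverts it (the only place an explicit inverse
  is kept, because the four blocks are the product); `h22_via_schur()`
  reaches `H22` through the Schur complement
  `(I + lambda G(xi)^{-1} - X(X'X)^{-1}X')^{-1}` without ever forming `M`.
* `cd_matrix()` computes CDs from the projection
  `P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}`; on support units the same
  numbers follow from the PEV identity `CD_i = 1 - lambda (H22)_ii / G_ii`.
  The definition in the literature writes the CD equivalently as
  `Var(pred)/Var(true)` and as `1 - Var(true | pred)/Var(true)`; rather than
  adjudicating notation, the package adopts the PEV identity as the MME-side
  route and verifies it numerically against the projection route across
  `lambda` spanning two orders of magnitude.

Elsewhere inversions go through factorizations (`chol`, `solve` with a
right-hand side). CD values are clamped to `[0, 1]`, with a warning when the
floating-point excursion exceeds `1e-8`. A support design occupying all `N`
units is admissible for the model machinery (useful for oracle checks on tiny
populations); the searches additionally require a nonempty candidate set.

## Criteria

Both shipped criteria act on the random-effect block, since breeders select
on predicted breeding values:

* **D-criterion** `-ln|H22(xi)|` (maximized): minimizes the generalized
  prediction variance. Computed as the log-determinant of the Schur form to
  avoid under/overflow and an unnecessary full inverse.
* **CDMin** `min_t CD(t | xi)` (maximized): guards the worst-predicted
  individual. The default target set is all `N` individuals, support
  included, matching the criterion's printed definition over the whole design
  space; a `target_set` argument covers the variant that scores only
  untrained candidates. **CDMean** (the average instead of the minimum) is
  provided as an optional criterion but is not part of the benchmark
  protocol.

There are no incremental (rank-one) criterion updates: the information matrix
is not additive in the units — swapping one individual changes `G(xi)^{-1}`
wholesale — so every evaluation is a full recomputation. That makes
evaluation counts a fair, hardware-independent cost metric, and the package
threads an `eval_counter()` through every search for exactly that purpose
(wall-clock comparisons would be dominated by implementation and hardware).

## Search algorithms

All searches move through single exchanges between the support set and its
complement, accept only strict improvements (threshold `1e-12`, guarding
float-noise cycles; the literature never quantifies its own tolerance), and
share the natural stopping rule: stop when no exchange improves, which makes
the returned design swap-local optimal by construction and verifiable by an
independent re-scan (`is_swap_local_optimum()`).

* **Classical Fedorov exchange** evaluates all `n (N - n)` swaps per pass and
  applies the best improving one; ties break on the lowest (support position,
  candidate position) pair so runs are deterministic given the start. Each
  pass costs exactly `n (N - n)` evaluations.
* **Modified Fedorov exchange** applies the first improving swap found while
  scanning in a heuristic order, then recomputes scores and restarts the
  scan. Scores come from the model: prediction variances for the D-criterion
  (observed-unit variance on the support, unobserved-unit variance on the
  candidates), per-unit CDs for the CD criteria. The candidate set is always
  scanned in its criterion-specific informative order (decreasing prediction
  variance for D; increasing CD for CDMin). For the support set the helpful
  direction is genuinely unclear in this model — removing a unit deletes its
  whole individual-specific effect, which inverts the classical-linear-model
  intuition — so all three orderings (increasing, decreasing, random) are
  first-class options and none is blessed as a default beyond the function's
  argument order. Scores are recomputed after every accepted swap because
  they are design-dependent; within a scan they are frozen. Whether to
  re-sort per acceptance or per pass is underdetermined in the protocol the
  package follows; per-acceptance was chosen as the more faithful reading of
  "greedy", and the choice is isolated in one place should a sensitivity
  analysis want the alternative.
* **Random-swap hill climbing** is the naive baseline from the earlier
  genomics literature: propose a uniformly random exchange, keep it if it
  improves. It terminates on a proposal budget or a configurable rejection
  streak, so its endpoint carries no local-optimality certificate.
* **Multi-restart driver**: a master seed spawns per-restart child seeds;
  each restart draws a uniform random start of size `n` and runs the
  configured algorithm. The best final value wins, ties to the lowest restart
  index. Identical `(config, seed)` reproduces bit-identical results, traces
  included.
* **Exhaustive enumeration** is the oracle for small instances, capped at
  `1e6` subsets by default.

A criterion evaluation that fails numerically mid-scan (a singular restricted
GRM can arise with duplicated individuals or user-supplied matrices) is
treated as non-improving with a warning rather than aborting the search;
robustness was preferred over a hard stop. Failed attempts still count as
evaluations.

## Synthetic data: what it emulates and what it does not

The generator exists so every experiment runs without external data.
`simulate_markers()` draws biallelic dosages binomial(2, p_j), `p_j` uniform
on (0.05, 0.95) by default; with `n_families > 1` each family gets two
simulated parents and offspring receive one transmitted gamete per parent, so
full sibs share alleles and within-family relationship exceeds
between-family relationship. `vanraden_grm()` builds the field-default
VanRaden method-1 GRM from observed frequencies and blends it with the
identity (`eps = 0.01` for fixtures) to guarantee nonsingularity without
distorting structure.

The named fixtures fix the study conditions: `tiny6` (N = 6) for
hand-checkable oracles, `small12` (N = 12; `choose(12, 4) = 495` designs,
where exhaustive search is the oracle), `medium50`, and `wheatlike200`
(N = 200, 4670 markers, 20 families) matching the scale of a typical wheat
training-population problem with `lambda = 1` and an intercept-only `X`.
Only scale and qualitative relatedness structure are emulated: there is no
linkage disequilibrium, no selection history, no attempt to match any real
population's eigen-spectrum (the real wheat data of the motivating problem
ships inside a licensed third-party package). Passing tests therefore
demonstrate correctness of the machinery and the algorithms' relative
behavior, not performance guarantees on any particular real population.

## Benchmark protocol and problem sizes

The shipped comparisons use: the `small12` fixture at `n = 4` with 10
restarts for exhaustive-versus-heuristic checks (all heuristics are verified
swap-local optimal; best-of-10 classical Fedorov attains the enumerated
global optimum for both criteria); and `wheatlike200` at
`n in {10, 20, 40}` with 2 restarts per algorithm for the evaluation-cost
comparison, where modified Fedorov needs a fraction of classical Fedorov's
evaluations and the gap widens with `n` (ratios of roughly 4, 7 and 13 at
the three sizes, seed 1). These sizes keep the full suite comfortably
reproducible on a laptop while preserving the qualitative findings; the
protocol scales to the full `n = 10..80` grid with 10 restarts via
`run_optimize()` unchanged.

One clarification the package makes explicitly: convergence traces index
*accepted exchanges* (iteration 0 is the start value), while evaluation
counts are reported separately — "iteration" is otherwise ambiguous across
algorithms with such different per-step costs.

## Known limitations

* No approximate-design theory, by necessity (non-additive information
  matrix), and no genetic-algorithm / simulated-annealing optimizer; the
  baseline for comparison is the random-swap hill climber.
* Criteria beyond D, CDMin, CDMean (A-, E-, G-optimality,
  accuracy-of-selection criteria) are not implemented.
* `lambda` is a single known scalar; no uncertainty in `G` or `lambda` is
  propagated.
* The CSV GRM dialect (ids in first row and column, dense double precision)
  is the only ingestion path; marker files (VCF/PLINK) are out of scope.
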