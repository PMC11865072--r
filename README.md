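# gblupdesign

Optimal training-set design for genomic prediction under the gBLUP model.

## The problem

Breeding programs predict genomic breeding values with the gBLUP linear mixed
model

    y = X beta + Z gamma + e,    gamma ~ N(0, sigma_g^2 G),   e ~ N(0, sigma_e^2 I),

where `G` is the genomic relationship matrix (GRM) over all `N` selection
candidates and `Z = I` on the phenotyped units. Phenotyping is expensive, so
only `n < N` individuals can be put in the training set. Which `n`? That is an
exact optimal-design problem: choose the support set `xi` maximizing a scalar
criterion on the information matrix

    M(xi) = D'D + lambda * B,    D = [X_xi  I_n],   B = blockdiag(0, G(xi)^-1),

with `lambda = sigma_e^2 / sigma_g^2` assumed known. Because `G(xi)` changes
with every candidate swap, `M` is not additive in the units and classical
convex design theory does not apply — search has to work on exact designs,
re-evaluating the criterion for every exchange.

The package implements, for this model:

* **Model machinery** — the mixed-model-equation covariance blocks (`build_mme`,
  with an independent Schur-complement route `h22_via_schur`), prediction error
  variances of observed and unobserved units, the fixed-effect-annihilating
  projection `P = V^-1 - V^-1 X (X'V^-1X)^-1 X'V^-1`, and generalized
  coefficients of determination (CD) for individuals (`cd_matrix`) and
  zero-sum contrasts (`cd_contrasts`).
* **Criteria** — the D-criterion `-ln|H22(xi)|` on the random-effect (PEV)
  block, and the CDMin / CDMean criteria `min / mean CD(target | xi)` over a
  target set (default: all `N` candidates). All maximized.
* **Search** — classical Fedorov exchange (best improving swap per full
  neighborhood scan), modified Fedorov exchange (first improving swap under
  increasing / decreasing / random support-set orderings, scores recomputed
  after every acceptance), a naive random-swap hill-climbing baseline, a
  seeded multi-restart driver, and an exhaustive enumeration oracle for small
  instances. Cost is tracked in criterion evaluations, a hardware-independent
  metric.
* **Synthetic data** — a seeded biallelic-marker simulator with optional
  family structure and a VanRaden (method 1) GRM builder, plus frozen named
  fixtures up to a wheat-scale population (`N = 200`, 4670 markers).
* **A command-line interface** (`inst/cli/gblupdesign.R`) with `simulate`,
  `optimize`, `exhaustive`, `evaluate` and `report` subcommands.

## Worked example

```r
library(gblupdesign)

fx <- make_fixture("small12")        # N = 12, 3 families, lambda = 1, intercept
cs <- criterion_spec("D")

ex <- exhaustive_search(fx$grm, fx$spec, cs, n = 4)
ex$best_value
#> [1] 3.403324

mr <- multi_restart(fx$grm, fx$spec, cs, n = 4,
                    algorithm = "modified_fedorov", ordering = "decreasing",
                    restarts = 10, seed = 1)
mr$best
#> modified_fedorov (decreasing): value 3.40332 after 7 accepted swaps, 88 criterion evaluations (converged)

sort(mr$best$design$support)
#> [1]  3  5 10 12
```

The exhaustive oracle scores all `choose(12, 4) = 495` designs; the winning
restart of the greedy heuristic reaches the same global optimum
(`-ln|H22| = 3.403324`, larger is better) with 88 criterion evaluations.
Per-unit prediction quality for that design:

```r
round(cd_matrix(fx$grm, fx$spec, mr$best$design), 3)
#> [1] 0.123 0.058 0.448 0.065 0.496 0.127 0.151 0.114 0.210 0.461 0.172 0.434
```

These are coefficients of determination in [0, 1]: the fraction of each
individual's genetic variance the trained model would capture (trained units
included).

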