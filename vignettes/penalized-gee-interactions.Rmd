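---
title: "Selecting feature-environment interactions in longitudinal data with penalized GEE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting feature-environment interactions in longitudinal data with penalized GEE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Longitudinal omics studies measure a continuous phenotype (here: body
weight of experimental animals, weekly over a study period) together with a
high-dimensional profile of molecular features (lipid species
concentrations) and a low-dimensional, pre-assigned environment or
treatment factor (e.g. four arms: control, exercise + ad libitum feeding,
exercise + pair feeding, dietary calorie restriction).  Two questions are
asked jointly:

* which features have main effects on the phenotype, and
* which features *interact* with the treatment factor — i.e. change the
  phenotype differently across arms.

Because the treatment factor enters as a group of `q` dummy variables, a
feature's interaction with it is a *group* of `q` product terms.  A feature
either interacts with the factor or it does not; selecting individual
dummy-by-feature products would be incoherent with the ANOVA coding.  The
repeated measures are correlated within subject, and the number of
candidate effects (`1 + q + p + pq`, e.g. 304 at `p = 75, q = 3`) typically
exceeds the number of subjects, so the model must be both *marginal*
(working-correlation based) and *penalized*.

## Model and estimating equations

For subject `i` at time `j` the marginal linear model is

$$Y_{ij} = \beta_0 + E_{ij}^\top\beta_1 + X_{ij}^\top\beta_2 +
  (X_{ij}\otimes E_{ij})^\top\beta_3 + \varepsilon_{ij}
  = Z_{ij}^\top\beta + \varepsilon_{ij},$$

with `X` the `p` features, `E` the `q` treatment dummies, and the Kronecker
block ordered feature-major (`x1:e1, x1:e2, ..., x1:eq, x2:e1, ...`).
Estimation uses generalized estimating equations: with identity link and
constant variance the score is

$$U(\beta)=\sum_{i=1}^n Z_i^\top V_i^{-1}(Y_i - Z_i\beta), \qquad
V_i = \phi\, R(\eta),$$

where `R(η)` is a working correlation matrix — independence, exchangeable,
or AR(1) — and `(φ, η)` are nuisance parameters.  GEE estimates remain
consistent when `R` is misspecified, which the simulation study below
exercises deliberately (the generated errors are AR(1); the flagship method
uses an exchangeable working structure).

Selection is obtained by penalizing the score: the penalized estimating
function subtracts minimax-concave-penalty (MCP) derivative terms

$$Q(\beta) = U(\beta)
  - \sum_{g=1}^p \rho'(|\beta_{2g}|;\lambda_1,\gamma)\,\mathrm{sign}(\beta_{2g})
  - \sum_{h=1}^p \rho'(\|\beta_{3h}\|_{\Sigma_h};\, q\lambda_2,\gamma),$$

where `ρ'(t; λ, γ) = (λ − t/γ)_+` for `t ≤ γλ` and 0 beyond.  Main feature
effects are penalized individually; each feature's interaction block
`β_{3h}` is penalized as a unit through the empirical group norm
`‖β‖_Σ = (βᵀΣβ)^{1/2}` with `Σ_h = B_h^\top B_h / n`, `B_h` the feature's
`q` interaction columns.  The intercept and the environment dummies are
never penalized: the treatment factor is experimentally assigned and known
to belong in the model.  MCP applies LASSO-like shrinkage near zero and
none beyond `t = γλ`, so large effects are estimated nearly without bias.

### Benchmark roster

Six methods share this machinery (`method_spec()`): A1/A2/A3 use the group
penalty for interactions under exchangeable / AR(1) / independence working
correlations; A4/A5/A6 penalize every interaction coefficient individually
(`ρ'(|β|; λ₂, γ)`), serving as the no-group-structure benchmark.

## Algorithm

`pgee()` solves the penalized equations by Newton–Raphson with a local
quadratic approximation of the penalty:

$$\hat\beta^{(d+1)} = \hat\beta^{(d)} +
  \left[T^{(d)} + n W^{(d)}\right]^{-1}
  \left[U^{(d)} - n W^{(d)}\hat\beta^{(d)}\right],$$

with `T = Σᵢ Zᵢᵀ Vᵢ⁻¹ Zᵢ` and `W` diagonal: zero on the `1 + q`
unpenalized columns, `ρ'(|β_g|; λ₁, γ)/(ε + |β_g|)` on main columns, and
the group weight `ρ'(‖β_h‖_Σ; qλ₂, γ)/(ε + ‖β_h‖_Σ)` shared by all `q`
columns of an interaction group (A1–A3) or the individual analogue
(A4–A6).  Design choices that matter:

* **Initialization.**  `β⁽⁰⁾` is a LASSO fit on the pooled `n·k`
  observations (within-subject correlation ignored at this stage), with its
  own penalty chosen by 5-fold cross-validation (`glmnet`); the intercept
  and environment columns are unpenalized.  Fold ids are derived from the
  subject labels, so the initializer — and hence the whole fit — is
  invariant to subject reordering.
* **Nuisance refresh.**  `φ` (mean squared residual) and `η`
  (Liang–Zeger moment estimators: all within-subject pairs for
  exchangeable, adjacent pairs for AR(1); denominators are raw counts with
  no degrees-of-freedom correction, since the coefficient dimension can
  exceed `n·k`) are re-estimated from the current residuals at every
  iteration.  `η` is clipped to the region where `R(η)` stays positive
  definite (`[-0.99, 0.99]` for AR(1), `[-1/(k-1) + 0.01, 0.99]` for
  exchangeable); `φ` is floored at `1e-8`.
* **Stabilizer.**  `ε = 1e-6` keeps the `W` denominators finite at zero;
  consequently exact zeros are never produced by the update itself.
* **Convergence.**  Stop when the L1 norm of the coefficient change drops
  below `tol = 1e-3` (default), or after `max_iter = 50` iterations with a
  non-convergence flag.  Typical runs at `n = 250, p = 75` converge in
  10–25 iterations.
* **Linear algebra.**  `T + nW` is solved by Cholesky factorization with
  an escalating diagonal jitter fallback (`1e-10` up to `1e-4` of the mean
  diagonal).  The escalation matters: with time-invariant covariates the
  stacked design has at most `n` distinct rows, so whenever the
  unpenalized-plus-saturated coordinates outnumber the subjects (routine
  at `n = 60, d = 124` with strong effects) `T + nW` is genuinely rank
  deficient and a fixed tiny jitter cannot rescue the solve.  `T` itself
  is assembled in `O(d²)` per iteration from precomputed cross-product
  blocks (exchangeable `V⁻¹` is `aI + bJ`; AR(1) `V⁻¹` is tridiagonal),
  which a unit test checks against the direct `Σᵢ Zᵢᵀ V⁻¹ Zᵢ`.
* **Thresholding.**  After convergence, penalized coefficients with
  `|β| < τ = 1e-3` are declared zero (`sparsify()`); `τ` matches the
  convergence tolerance scale.  Intercept and environment columns are never
  thresholded.
* **γ.**  Fixed at 3 by default.  Results are insensitive across the probe
  set {1.8, 3, 4.5, 6, 10}; the argument is exposed for sensitivity runs.
* **`Σ_h` divisor.**  The group Gram uses the subject count `n` even though
  `B_h` has `n·k` rows, which inflates the empirical norm by roughly
  `√k` relative to a per-row normalization; `interaction_gram()` exposes an
  `"observations"` divisor for sensitivity checks.  The default follows the
  definition as printed; the practical effect is a rescaling of `λ₂`.

## Tuning

`cv_pgee()` runs subject-level 5-fold cross-validation over a joint
`(λ₁, λ₂)` grid: folds partition *subjects* (never rows), each pair is
fitted on 4/5 of the subjects and scored by mean squared prediction error
on the held-out fifth.  The default grid is 8 log-spaced values per
dimension on `[0.01, 1]·sd(y)`, deliberately coarse for desk-scale
studies.

The **selection rule** deserves comment, because it is the one place where
this family of estimators is genuinely fragile.  On data with correlated
features the held-out error surface is nearly flat across a wide range of
small penalties: spurious coefficients on neighbours of true features
carry proxy predictive signal, so the strict error minimizer often sits in
an overfitting regime with many extra selected coefficients whose CV error
is "better" by far less than fold noise.  The default `rule = "min"` takes
the strict minimizer (exact ties broken toward the larger `λ₁ + λ₂`, the
sparser model), because it is the transparent, assumption-free choice; the
one-standard-error convention (`rule = "1se"`) is available as the
standard guard against overselection, with the caveat that the SE estimate
from five folds is itself noisy — in our experiments it sometimes failed
to leave the overfitting regime and sometimes overshot to effect-killing
sparsity.  A cell whose fit fails outright in a fold is scored on the
remaining folds and flagged.  Selected counts respond sharply to the
tuning — a 40% move in `λ₁` can swing false positives from ~12 to ~2 on
the study scale below — so reported TP/FP values should always be read
jointly with the tuning actually chosen, which `replicate_study()`
records.

For replicate studies, `tuning = "pilot"` (default) runs CV once on the
first replicate and fixes the chosen pair for all replicates — the usual
fixed-tuning benchmarking mode; `"per_replicate"` reruns CV each time, and
`"fixed"` takes a user pair.

## The synthetic-data generator

`simulate_longitudinal()` emulates the motivating study design:

* **Features** `X`: one `p`-vector per subject, multivariate normal, unit
  marginal variance, AR(1) cross-feature correlation `ρ_X = 0.5`, held
  constant over the `k = 5` time points (a single profile per animal).
* **Environment**: a time-invariant assignment from a latent standard
  normal.  Default `E_mode = "quartile4"` cuts at the empirical quartiles
  into a 4-level factor, lowest level baseline, `q = 3` one-hot dummies —
  mirroring a 4-arm study and keeping the design full rank.  The
  alternative `"tertile"` (cuts at the 30th/70th percentiles, all three
  categories one-hot) is provided for completeness but warned against:
  with an intercept those columns are exactly collinear, and the feature
  block becomes a linear combination of its own interaction block, so
  "truth recovery" is not identifiable under it.
* **Errors**: per subject `k`-variate normal, AR(1) with `ρ_error ∈
  {0.5, 0.8}`, unit marginal variance.
* **Truth** (`simulation_truth()`): in `"interactions"` mode the intercept,
  the `q` dummies, 4 feature mains and 3 complete interaction groups are
  nonzero — 17 effects at `q = 3` — with magnitudes `U[0.4, 0.8]` (the
  case-study scale uses `U[1.4, 1.8]` with `n = 60, p = 30`);
  `"main_only"` has 8 feature mains and no interactions; `"null"` is all
  zero.  Nonzero positions sit at the first eligible features so truth
  indices are stable; seeded-random placement is available.
* **Fixed truth across replicates**: `replicate_study()` draws the
  coefficient vector once per study and re-draws only data, so the
  estimation metrics (below) compare every replicate against a single `β`.

What the generator does *not* emulate: real lipid concentration scales and
detection limits, unbalanced cluster sizes, time-varying exposures, or the
full 176-species panel.  Passing tests on this generator demonstrate the
selection machinery under the stated correlation structure, not
performance on any particular real dataset.

A note on identifiability that affects interpretation: because `X` and `E`
are time-invariant, a feature's main column equals the sum of its
interaction columns plus its values on baseline subjects, so main and
interaction coefficients for the same feature are separated only by the
baseline arm (~25% of subjects).  Interaction estimates therefore carry
intrinsically higher variance than main-effect estimates at equal `n`, and
the per-coordinate squared error of true interaction coefficients
dominates the nonzero-coordinate MSE.

## Metrics and harnesses

`identification_metrics()` counts selected coefficients against the truth,
per individual coefficient (a partially selected group contributes
fractionally), split by main/interaction, under two conventions: exclusive
(penalized columns only) and inclusive (`TP_incl`; adds the truly nonzero,
always-present intercept and dummy terms, so the 17-effect truth maxes the
inclusive overall TP at 17 and the inclusive main TP at 8).  Unpenalized
columns never count as false positives.  `estimation_metrics()` reports
MSE (truly nonzero coordinates), NMSE (truly zero) and TMSE
(`mean ‖β̂−β‖²/d`), averaged over replicates.  `replicate_study()` runs
simulate → tune → fit → score over `R` replicates and prints a mean (sd)
table; `stability_selection()` refits on `B` subject subsamples drawn
without replacement and reports per-coefficient selection proportions.

## Problem sizes used in the shipped checks

The package's own test-suite studies run at `R = 30` replicates with the
coarse 8×8 grid and pilot tuning for the `n = 250, p = 75` scale, `R = 30`
for the null, misspecification and case-study (`n = 60, p = 30`) scales,
and an `R = 3` fixed-tuning smoke run at `n = 500, p = 300`; these sizes
make a desk-scale reproduction while keeping Monte-Carlo error within the
tolerances stated alongside each check.

## Known limitations

* Balanced designs only (`k` equal across subjects); missingness is
  rejected at load, not modelled.
* Gaussian identity-link marginal model only; no non-continuous phenotypes.
* The MCP estimating equations are nonconvex: the iterate depends on the
  initializer, monotonicity of selection in `λ` can be violated locally,
  and CV-selected tuning — not the fitter — dominates the variance of
  selected-set sizes between runs.
* Selected coefficient counts change sharply near critical `λ` values
  (see the tuning section); comparisons between methods are meaningful at
  matched or CV-selected tuning, with the tuning reported.
* No post-selection inference: selection proportions from
  `stability_selection()` are a robustness description, not p-values.
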