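---
title: "Feature decomposition and kernel discriminant analysis: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature decomposition and kernel discriminant analysis: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braindecomp)
```

## The model

A subject's feature vector is the vectorized gray-matter density map of a
spatially normalized brain volume. The working assumption is additive: each
training vector is a class-specific part (what a diagnostic label explains),
a non-class-specific part (low-rank variation shared across subjects —
scanner, processing, demographic drift), and a sparse error (registration
failures, segmentation spikes). Stacking N training subjects as columns of
`X` (M × N), the training decomposition solves

$$\min_{A,B,\beta,E} \|A\|_* + \mu\|B\|_* + \gamma\|\beta\|_F^2 +
\tau\|E\|_1 \quad \text{s.t.}\quad X = A + B\beta + E,$$

with the training codes over `A` fixed to the identity, so `A` has one
column per training subject and each column inherits that subject's label.
The labels never enter the optimization: "class-specific" is realized
structurally — the nuclear norm on `A` concentrates the low-rank structure
that the subject-aligned dictionary can carry, while `B\beta` (d atoms, code
matrix `β`) absorbs subject-generic variation and `E` the gross outliers.
An alternative reading solves the program once per class block; we solve it
globally, since the identity-code convention already ties `A`'s columns to
labeled subjects and a per-class solve would forfeit the shared confound
estimate. A test vector `y` is coded by
$\min \|\alpha\|_1 + \gamma\|\beta\|_2^2 + \tau\|\varepsilon\|_1$ s.t.
$y = A\alpha + B\beta + \varepsilon$, and only the class-specific
reconstruction `Aα` is classified.

The second stage is Gaussian-kernel discriminant analysis. With kernel
matrix `K` on the training class-specific components and the class-graph
matrix `W` (`W_ij = 1/N_l` iff i, j share class l), discriminant directions
maximize the regularized Rayleigh quotient
$(\alpha^\top KWK\alpha)/(\alpha^\top(KK+\delta K)\alpha)$. Embedded
samples are classified by 1-nearest-neighbor.

## How the SRKDA solve works, exactly

Spectral regression replaces the N×N generalized eigenproblem by graph
responses plus ridge regressions. For this pencil the reduction is exact:
when `K` is nonsingular the pencil `(KWK, KK + δK)` is equivalent to
$WK(K+\delta I)^{-1}c = \lambda c$ with $\alpha = (K+\delta I)^{-1}c$, and
since `W` projects onto the span of the class indicators, every eigenvector
response `c` lies in that C-dimensional span. `srkda_fit()` therefore solves
a C × C reduced eigenproblem (`T[j, l]` = class-j mean of
`K (K+δI)^{-1} 1_l`), maps each of the C eigenvectors back through one ridge
solve, and reports their quotients; the model's `quotient_max` equals the
dense eigensolver optimum to machine precision, which the test suite and
acceptance script verify on random instances. One of the C directions is
the near-constant solution (the analogue of the all-ones graph eigenvector);
it maximizes nothing useful for classification, so the direction whose
response is most aligned with the ones vector is dropped and the remaining
C − 1 serve as discriminant directions. The commonly used shortcut — fix
the response to the ones-orthogonalized indicator and ridge-solve — is only
O(δ)-accurate for the regularized pencil; we preferred the exact reduced
solve because it costs the same and makes the eigensolver equivalence a
testable identity rather than an approximation.

Two numerical facts worth knowing. First, as δ → 0 the reduced matrix tends
to the identity, its eigenvectors degenerate, and direction identification
becomes ill-conditioned; δ well below 1e-6 is not useful. Second,
duplicating every training point halves the effective ridge, so the
embedding is invariant under duplication only up to O(δ·cond(K)) — about
1e-6..1e-5 at δ = 1e-6 on toy instances.

## Tunable parameters

| parameter | default | rationale |
|---|---|---|
| `mu` (nuclear weight on B) | 1 | equal footing with `‖A‖*`; the split is then governed by structure, not scale |
| `gamma` (ridge on β) | 1 | scale-equivariance: solving `cX` with `cγ` scales the solution by `c` (a tested identity) |
| `tau` (L1 weight on E) | `1/sqrt(max(M, N))` | the standard L1 weight in nuclear + L1 programs; balances sparse against low-rank terms across problem sizes |
| `n_atoms` (d) | `min(M, N)` | richest confound dictionary that cannot exceed feasible rank |
| `rho_init`, `rho_scale`, `rho_max` | `1/‖X‖₂`, 1.2, 1e7 | the usual inexact-ALM schedule; `1/‖X‖₂` makes the first SVT threshold O(‖X‖₂) |
| `tol` (training) | 1e-7 | relative constraint residual at which the decomposition is considered exact for downstream use |
| test solver `rho_scale`, `inner` | 1.05, 10 | slower penalty growth plus several proximal sweeps per outer iteration keep the test code within ~1e-4 of the convex optimum (measured against a QP solver), versus ~1e-3 misses with an aggressive schedule |
| kernel `sigma` | median pairwise distance | the standard scale-free bandwidth heuristic; the bandwidth is otherwise unspecified in this family of methods |
| `delta` (KDA ridge) | `0.01·trace(K)/N` | scale-aware; with unit-diagonal Gaussian kernels this is 0.01 |
| `screen_threshold` | 0.05, uncorrected | conventional screening level; multiple-testing correction is deliberately left to the user since screening is a prefilter, not an inference |
| `n_folds` | 10 | the canonical evaluation protocol for cohorts of hundreds |

The t-test screening uses the pooled-variance Student statistic (Welch
behind a flag). Zero-variance rows follow the limits of the statistic:
equal means give p = 1 (dropped), unequal means with zero variance give
p = 0 (retained).

## The synthetic generator

`generate_cohort()` plants exactly the structure the decomposition assumes:
shared within-class loadings of rank `rank_class` (subject scores i.i.d.
normal), class-mean offsets confined to the first `signal_frac` of the
features and scaled so adjacent classes differ by `effect` within-class
standard deviations (so the class component has rank at most
`rank_class + C − 1`), a rank-`rank_confound` confound loading on all
features, sparse corruption with uniform support and amplitude
±U(1,2)·`sparse_scale` times the feature scale, and optional dense noise.
Default group sizes are 198/167/236/229 (an AD/pMCI/sMCI/NC cohort of 830);
the default demo dimension is 1000 features — the generator scales to the
canonical 262144 but nothing in the package requires it.

What the generator does **not** emulate: spatial correlation of voxels,
registration error fields, nonlinear atrophy patterns, class-conditional
confounds, or heavy-tailed within-class variation. Passing tests on this
generator therefore show that the implementation is faithful to the model
and recovers planted structure under the model's own assumptions — not that
the method succeeds on real MR data, where the additive low-rank+sparse
assumption is an approximation.

## Study conditions used by the tests and acceptance script

Problem sizes were chosen so the full suite runs in minutes on one CPU:
training-solver checks use 20 noiseless cohorts of 80 features × 24
subjects, where the planted triple is exactly feasible and the solver's
objective must not exceed the planted objective; test-decomposition
optimality uses instances with at most 15 features against a quadratic-
programming oracle; SRKDA equivalence uses cohorts of at most 12 subjects
against a dense eigensolver; the end-to-end reference cohort is 30+30
subjects × 200 features with `effect = 4` and 2% corruption, where pooled
10-fold accuracy is required to reach 0.95.

The decomposition-versus-ablation comparison (full pipeline against KDA on
screened raw features) runs on confound-dominated cohorts: 20+20 × 120,
`effect = 1.5`, `confound_sd = 2` (confound variance 4 ≥ class-effect
variance), 10% sparse corruption at 3× amplitude, `noise_sd = 0.5`. This
regime was chosen because it is where the decomposition's premise operates:
the E term absorbs gross spikes and `Bβ` the shared confound before the
kernel sees the data. Design pilots showed the contrast honestly: with weak
effects and only mild corruption the decomposition can *hurt* — the
subject-aligned dictionary then absorbs idiosyncratic noise into the
class-specific component — so a practitioner should not expect the
decomposition to help when gross corruption is rare and confounds are weak.

## Numerical choices and degenerate inputs

- Training ALM: one proximal pass per variable per outer iteration, in the
  order A (SVT), E (soft threshold), β (ridge), B (linearized SVT step with
  step `1/‖ββᵀ‖₂`); multiplier update, then penalty growth. Initialization
  is deterministic (SVD warm start for B, least-squares β, zero A/E/Y).
- `X = 0` and `y = 0` short-circuit to the exact trivial minimum.
- Nearest-neighbor ties break toward the lowest training index; the AUC
  score is the nearest-negative minus nearest-positive embedded distance,
  oriented by the configured positive class (the disease/progressor group),
  since 1-NN alone yields no continuous output.
- Non-convergence of either ALM solver flags the result (`converged =
  FALSE`) rather than raising, so cross-validation can report partial runs.
- Vectorization order is R column-major (first axis fastest) everywhere.
- Smoothing renormalizes the truncated Gaussian kernel mass at boundaries,
  which makes constants exact eigenfunctions of the filter; downsampling is
  a strict block mean and refuses non-divisible extents rather than crop.
- `sparse_kda()` skips supports whose denominator submatrix is
  computationally singular (counted in `skipped_supports`); exhaustive mode
  is gated to N ≤ 20.

## Known limitations

- The nuclear-norm split of `X` into `A` versus `Bβ` is scale-sensitive:
  nothing but the norms' economics decides which term takes shared
  structure, and with the default weights the class-mean directions are
  retained in `A` rather than guaranteed to be. Recovery guarantees are
  deliberately out of scope; the package asserts empirical properties
  (feasibility, objective dominance, support recovery) instead.
- Per-class dictionary learning (one decomposition per class block) is not
  implemented.
- SRKDA stores the full training kernel; cohorts beyond a few thousand
  subjects would need low-rank kernel approximations the package does not
  provide.
- Preprocessing upstream of the density maps — bias correction, skull
  stripping, segmentation, deformable registration — is external; the
  package consumes registered nonnegative density volumes or ready-made
  feature matrices.
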