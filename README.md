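# braindecomp

Classification of structural MR brain images — typically for distinguishing
Alzheimer's disease (AD), progressive/stable mild cognitive impairment
(pMCI/sMCI) and normal controls (NC) — from voxel-wise gray-matter (GM)
density features. The package is aimed at neuroimaging researchers who have
already registered and segmented their scans (so each subject is a
nonnegative GM density volume in a common space) and want a transparent,
fully testable implementation of a decomposition-then-discriminate pipeline.

## The method

Voxel-wise GM densities mix disease-related signal with subject-generic
variation from acquisition and processing, plus occasional gross corruption.
The pipeline separates these explicitly, in two stages:

**1. Feature decomposition.** Stack the N training feature vectors as the
columns of `X` (M voxels × N subjects) and decompose

```
min  ‖A‖* + μ‖B‖* + γ‖β‖²_F + τ‖E‖₁    s.t.  X = A + Bβ + E
```

where `‖·‖*` is the nuclear norm. `A` is the **class-specific dictionary**
(one column per training subject, inheriting its label — the training codes
over A are fixed to the identity), `Bβ` is the **non-class-specific** term
absorbing shared low-rank confounds, and `E` collects sparse errors. The
program is solved by inexact augmented Lagrange multipliers (ALM) with
singular-value thresholding for the nuclear terms, soft thresholding for
`E`, and a closed-form ridge step for `β`. A test sample `y` is then coded
against the learned dictionaries,

```
min  ‖α‖₁ + γ‖β‖²₂ + τ‖ε‖₁    s.t.  y = Aα + Bβ + ε
```

and only its class-specific reconstruction `Aα` goes forward.

**2. Kernel discriminant analysis.** The class-specific components are mapped
to a linearly separable space by Gaussian-kernel discriminant analysis in
spectral-regression form (SRKDA): with training kernel matrix `K` and
class-graph matrix `W` (`W_ij = 1/N_l` iff subjects i, j share class l), the
discriminant directions maximize `(αᵀKWKα) / (αᵀ(KK + δK)α)`; the solver
obtains them exactly from a C×C reduced eigenproblem in the class-indicator
span followed by one ridge solve per direction. A cardinality-constrained
sparse variant (greedy forward selection with a backward sweep, or
exhaustive search on small problems) is available. Embedded samples are
classified by 1-nearest-neighbor; a margin-based score supplies the
continuous output for the AUC.

Around the core: Gaussian smoothing and factor-k block-mean downsampling of
density volumes (the canonical setting reduces 256³ maps to 64³ = 262144
features), training-only two-sample t-test feature screening, biomarker
mapping of `-log10(p)` back into the volume, a synthetic cohort generator
that plants the exact structure the model assumes (low-rank class signal,
low-rank shared confound, sparse corruption), and a stratified 10-fold
cross-validation harness reporting ACC/SEN/SPE/AUC.

## Worked example

```r
library(braindecomp)

coh <- generate_cohort(synth_spec(n_per_class = c(30, 30), dim = 200,
                                  rank_class = 2, rank_confound = 3,
                                  sparsity = 0.02, effect = 4, seed = 11))
report <- run_cv(coh$features, pipeline_config(n_folds = 10, cv_seed = 11))
print(report)
```

```
10-fold stratified cross-validation (60 subjects)
  pooled: ACC 100.0%  SEN 100.0%  SPE 100.0%  AUC 100.0%
```

The cohort plants a rank-2 class-specific component whose class means differ
by 4 within-class standard deviations on a quarter of the features, a rank-3
shared confound and 2% sparse corruption; at that separation every held-out
subject is classified correctly, and `report$per_fold` shows the four
metrics per fold. Inspecting the fitted stages:

```r
fit <- pipeline_fit(coh$features, pipeline_config())
print(fit$dmodel)
#> decomp_model: 50 features, 60 training subjects, 50 confound atoms
#>   relative residual 9.05e-08 after 71 iterations (converged)
print(fit$kda)
#> kda_model: 60 training subjects, 2 classes; sigma = 37.27 , delta = 0.01
#>   discriminant Rayleigh quotient(s): 0.99874
```

The decomposition satisfies its constraint to ~1e-7 relative residual, and
the kept SRKDA direction attains a Rayleigh quotient near its upper bound
of 1. A thin command-line interface (`inst/cli/braindecomp`) exposes
`cohort`, `volume` and `cv` subcommands over the same functions.

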