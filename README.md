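# tensorsynth

Synthetic longitudinal health data via generalized CP tensor
decomposition.

Longitudinal health records — repeated lab measurements or visit
attributes for a patient cohort — form a three-way tensor
**X** (patients × variables × visits). Sharing such records requires
de-identification, and a generative model is one way to get there: fit
the model, release draws from it. But a tensor factorization's
reconstruction approximates the original cell by cell, so releasing it
would keep a one-to-one link to real patients. `tensorsynth` instead
fits a **generalized canonical polyadic (GCP) decomposition**

```
x[i,j,k] ≈ m[i,j,k] = Σ_r λ_r · A[i,r] · B[j,r] · C[k,r]
```

by minimizing a mask-weighted elementwise loss `Σ w·ℓ(x, m)` (Gaussian,
gamma, β-divergence, or Poisson log-link; `w ∈ {0,1}` marks observed
cells), and then synthesizes the **latent patient factor matrix A** —
a small, non-longitudinal table — rather than the records. New factor
rows Â are drawn by one of three samplers:

* **Gaussian copula** — correlated normals pushed through Φ and inverse
  marginal CDFs (empirical, kernel-smoothed, or parametric), with a
  Frobenius-norm acceptance loop on the synthetic correlation matrix;
* **sequential decision trees** — R−1 CART models, each column sampled
  from the terminal node reached by the previously synthesized columns;
* **Hamiltonian Monte Carlo** — posterior draws of the latent
  covariance under a known-mean multivariate Gaussian model with
  half-Cauchy scale priors, then rows drawn per posterior draw.

Synthetic records are reconstructed from Â with the fitted **B** and
**C**, including a synthetic missingness pattern (the binary mask
tensor is itself decomposed and resynthesized) and synthetic visit
counts for irregular panels. Utility is scored with per-variable
Hellinger distances, absolute pairwise correlation differences, RMSDC
(root mean square difference of correlations), and descriptive
summaries. A fully specified simulator of EHR-like panels provides
ground truth for every test; no clinical data ships with or is needed
by the package.

Intended users: biostatisticians and data custodians prototyping
latent-space synthesis for longitudinal panels, and methodologists who
want a reproducible, dependency-light reference implementation.

## Worked example

```r
library(tensorsynth)

# a dense 226-patient, 4-lab, 5-visit panel with known generative truth
long <- sim_ehr_like(sim_profile("labs_dense", seed = 5))

cfg <- synthesis_config(rank = 12, sampler = "seqtree", seed = 11)
out <- synthesize(long, cfg)
out
#> GCP synthesis: 226 -> 226 patients (seqtree sampler, rank 12)
#>   fit score 0.7225   RMSDC 0.0798   median Hellinger 0.0892

out$report
#> Utility report: real vs synthetic
#>   patients: 226 real / 226 synthetic   correlations: pearson
#>   RMSDC: 0.0798   median |corr diff|: 0.0659 (n = 190)
#>   Hellinger distances:
#>     creatinine       0.0622
#>     hematocrit       0.1096
#>     potassium        0.1003
#>     sodium           0.0782
#>   missing fraction: 0.000 real / 0.000 synthetic
```

Reading: the rank-12 Gaussian-loss fit explains ~72% of the
(standardized) panel; the synthetic cohort reproduces the real
dependency structure to RMSDC 0.08 over the 190 variable-visit
correlation pairs, and every lab's marginal distribution sits within
Hellinger distance ≈ 0.06–0.11 of the real one (0 = identical,
1 = disjoint). Swap `sampler = "copula"` or `"hmc"` to compare
samplers; `n_out = 250` synthesizes a cohort of a different size than
the original.

Lower-level pieces are exposed in the classic modelling idiom:

```r
fit <- gcp(long, rank = 12, standardize = TRUE, seed = 11)
fit
#> Generalized CP decomposition (rank 12, gaussian loss)
#>   tensor: 226 patients x 4 variables x 5 visits (4520 observed cells)
#>   objective: 347.758   fit score: 0.7225
#>   fitted on standardized variables

coef(fit, "patients")      # the latent patient factor matrix A
fitted(fit, "original")    # dense reconstruction on the data scale
syn <- simulate(fit, nsim = 250, method = "copula", seed = 1)
sel <- select_rank(as_tensor3(long), 1:8)   # elbow-rule rank choice
```

There is also a small CLI (`inst/exec/tensorsynth`) with
`simulate`, `fit`, `synthesize` (YAML config mirroring
`synthesis_config()`), and `evaluate` subcommands; see `?run_cli`.

## Documentation

The methods vignette (`vignettes/tensorsynth-methods.Rmd`) documents
the model and its assumptions, every tunable parameter and its default,
the samplers' design decisions, what the simulator does and does not
emulate, and known limitations.
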