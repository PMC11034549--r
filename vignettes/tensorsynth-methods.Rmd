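---
title: "Generating synthetic longitudinal health data with tensorsynth"
author: "tensorsynth authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating synthetic longitudinal health data with tensorsynth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tensorsynth)
```

## The problem and the model

Longitudinal health records — repeated laboratory measurements or visit
attributes for a cohort of patients — form a three-way array
$\mathcal{X} \in \mathbb{R}^{I \times J \times K}$ of $I$ patients, $J$
variables and $K$ visits. Sharing such records requires de-identification,
and synthetic data generation is an attractive route: fit a generative
model, then release draws from it instead of the records themselves.

`tensorsynth` builds that generative model around the **generalized
canonical polyadic (GCP) decomposition**. The rank-$R$ model tensor is

$$ m_{ijk} = \sum_{r=1}^{R} \lambda_r\, a_{ir}\, b_{jr}\, c_{kr}, $$

with a patient factor matrix $A$ ($I \times R$), variable factors $B$
($J \times R$), visit factors $C$ ($K \times R$) and positive weights
$\lambda$ (fixed to $\mathbf{1}$ during fitting; scale is absorbed into
the factors, and `gcp_normalize()` can repopulate $\lambda$ afterwards).
The factors minimize a mask-weighted elementwise loss

$$ F(A, B, C) = \sum_{ijk} w_{ijk}\, \ell(x_{ijk}, m_{ijk}), \qquad
   w_{ijk} \in \{0, 1\}, $$

where $w_{ijk} = 0$ marks a missing cell that must never influence the
fit. The loss catalog (`loss_spec()`) covers Gaussian, gamma,
$\beta$-divergence and Poisson log-link losses, chosen by how the data
are believed to be generated; in practice, standardizing each variable
and using the Gaussian loss is the recommended default for continuous
laboratory panels, and the Poisson log-link or Gaussian loss for
integer-coded categorical panels.

A reconstruction of the model tensor approximates the original records
cell by cell, so releasing it (or draws with its cells perturbed) would
retain a one-to-one correspondence with real patients. The package
therefore never synthesizes the tensor directly. Instead it synthesizes
the rows of the **latent patient factor matrix** $A$ — a small,
non-longitudinal table — and reconstructs synthetic records from sampled
factor rows $\hat A$ together with the *fitted* $B$ and $C$. A synthetic
patient is a new point in phenotype space, not a perturbed copy of a real
one.

## Fitting

`gcp()` minimizes $F$ jointly over all three factor matrices with a
bound-constrained quasi-Newton method (L-BFGS-B), using the analytic
gradient assembled from mode-$n$ unfoldings and Khatri–Rao products:
with $y_{ijk} = w_{ijk}\,\partial\ell/\partial m_{ijk}$,

$$ \partial F / \partial A = Y_{(1)}\, (C \odot B)\,\mathrm{diag}(\lambda), $$

and cyclically for $B$ and $C$. Design choices worth knowing:

* **Optimizer.** A deterministic full-gradient method rather than the
  stochastic gradient variants used for massive tensors: at the cohort
  sizes this package targets (hundreds of patients), full gradients are
  cheap and make every fit exactly reproducible from its seed. A
  projected first-order optimizer (`optimizer = "adam"`) is provided as
  an alternative.
* **Nonnegativity.** When requested (or required by the gamma and
  $\beta$-divergence domains), every factor entry is constrained to the
  nonnegative orthant. With L-BFGS-B this is a box constraint — the same
  feasible set as clipping after each step, handled inside the line
  search; the Adam path clips explicitly after each update.
* **Initialization.** I.i.d. uniform$(0, s)$ for nonnegative fits,
  $N(0, s^2)$ otherwise, with $s$ defaulting to
  $(\mathrm{rms}(x)/R)^{1/3}$ so initial reconstructions have roughly the
  data's magnitude. `restarts` reruns from seeded initializations and
  keeps the best objective; seeds are `seed`, `seed + 1`, ….
* **$\beta$-divergence.** $\beta = 1.5$ by default (between the gamma
  and Gaussian limits), with a small `offset` stabilizing logs and
  divisions near zero; both are configurable in `loss_spec()`.
* **Fit score.** Reported as the standard CP fit
  $1 - \|W \circ (X - M)\|_F / \|W \circ X\|_F$ over observed cells.

**Rank selection.** `select_rank()` implements an elbow rule: fit each
candidate rank (warm-starting from the previous fit, padded with a small
random column, which makes the objective non-increasing in rank), then
choose the smallest rank whose improvement to the next candidate falls
below 1% (configurable) of the improvement accumulated since the first
candidate. Relative-to-total is used rather than relative-to-current so
that a near-zero objective (an exact fit) cannot masquerade as further
meaningful improvement. The admissible range is
$R \le \min\{IJ, IK, JK\}$.

## Missingness, irregular visits, and baselines

Real panels are incomplete in two ways, and `synthesize()` handles both:

* **Missing measurements.** The binary mask tensor $\mathcal{W}$ is
  itself decomposed (Gaussian loss, rank $R'$, `mask_rank`), giving mask
  patient factors $A_w$. Synthetic mask factors are sampled jointly with
  the value factors, reconstructed through $B_w, C_w$, and binarized at
  0.5 (`binarize_threshold`) to yield a synthetic missingness pattern.
  Binarization is a hard threshold because the reconstruction
  approximates cell-wise observation propensities; under purely
  unstructured (MCAR) missingness the low-rank model reconstructs the
  roughly constant observation rate, so a panel observed at, say, 79%
  yields reconstructions almost everywhere above 0.5 and very few
  synthetic missing cells. Structured missingness (patients or visits
  with systematically sparser coverage) is what the mask model can
  actually reproduce; the utility report always states both real and
  synthetic missing fractions so the discrepancy is visible rather than
  silently corrected.
* **Irregular visit counts.** Patients with $v_i < K$ visits are padded
  with missing cells (`regularize_visits()`), and $v_i$ — a
  non-longitudinal patient attribute — is appended to the latent table as
  one more column. After sampling, each synthetic patient's records are
  truncated to its synthetic visit count, rounded half-up and clipped to
  $[1, K]$.
* **Baseline attributes.** Per-patient covariates join the latent table
  the same way (standardized alongside the tensor when standardization
  is on, and restored afterwards).

All blocks are concatenated column-wise into one augmented latent table
(`augment_latent()`/`split_latent()`), so a single sampler draws values,
missingness and visit counts **jointly** and cross-dependence between
them survives synthesis.

## The three latent samplers

All samplers consume and produce `latent_table`s, return exactly `n_out`
rows with the input's column order, and are deterministic given a seed.

**Gaussian copula** (`copula_sample()`). Draw
$t \sim N(0, \Sigma)$ with $\Sigma$ the latent columns' correlation
matrix, set $u_r = \Phi(t_r)$, and invert each column's marginal
$\hat a_r = F_r^{-1}(u_r)$. Marginals are, by default, midpoint-rank
empirical CDFs ($p_i = (i - \tfrac12)/n$) with linear interpolation
between order statistics — synthetic values therefore never leave the
observed range — with kernel-smoothed and parametric (gamma, beta,
truncated-Gaussian, fitted by maximum likelihood) alternatives. Because
a finite draw never reproduces the correlation matrix exactly, draws are
retried (up to `max_tries`) until
$\|\mathrm{corr}(\hat A) - \mathrm{corr}(A)\|_F < \varepsilon$; if the
cap is exhausted the best draw is returned flagged
(`attr(, "accepted") = FALSE`) instead of raising an error, since a
near-miss is still usable. The default
$\varepsilon = 0.05 R$ scales with the matrix dimension so the
per-entry tolerance is roughly constant in $R$. A non-positive-definite
correlation estimate is repaired by eigenvalue clipping with a warning.

**Sequential decision trees** (`seqtree_fit()`/`seqtree_sample()`).
$R - 1$ CART regression trees are fitted, tree $M_j$ predicting column
$a_j$ from $a_1, \dots, a_{j-1}$ in table order. Sampling bootstraps
$\hat a_1$ from the observed first column, then walks each tree and
draws uniformly from the *training values in the terminal node reached*
— so every synthetic value is a value observed in that column, and a
constant column is reproduced exactly. Trees use a minimum leaf size of
5, no effective depth cap, a small complexity penalty ($10^{-4}$), and
have cross-validation disabled (it would consume randomness without
affecting the fitted tree). No kernel noise is added in the leaves by
default.

**Hamiltonian Monte Carlo** (`hmc_fit()`/`hmc_sample()`). The latent
rows are modelled as $x_i \sim N(\mu, \Sigma)$ with known mean and
unknown covariance $\Sigma = \mathrm{diag}(\sigma)\,\Omega\,
\mathrm{diag}(\sigma)$, half-Cauchy(2.5) priors on the scales and an
LKJ-type prior on $\Omega$ (concentration 1.5), parameterized through
canonical partial correlations ($\tanh$-transformed to unconstrained
space). The posterior is explored by HMC with analytic gradients,
dual-averaging step-size adaptation (target acceptance 0.8) and
leapfrog paths jittered over 15–30 steps, initialized near the sample
moments. Split $\hat R$ and effective sample sizes are reported for
every parameter, with a warning attached when any scale parameter has
$\hat R > 1.1$. Sampling draws, per synthetic row, a retained posterior
$\Sigma$ and then $x \sim N(\mu, \Sigma)$ — so synthetic rows integrate
over posterior uncertainty rather than conditioning on a point estimate.
Two deliberate choices:

* The **known mean** defaults to the empirical column means
  (`mean = "empirical"`), restored when sampling. A zero mean
  (`mean = "zero"`) is simpler but biases every synthetic marginal when
  the latent factors are not centered, which GCP factors generally are
  not.
* The model is a Gaussian one, so it is only appropriate for latent
  spaces produced by a **Gaussian-loss** fit; the latent table carries
  its loss as provenance and other losses are refused unless explicitly
  overridden.

## The utility report

`utility_report()` compares real and synthetic long tables:

* **Hellinger distance** per variable, pooling values across visits:
  $H = \sqrt{1 - \sum_b \sqrt{p_b q_b}}$ over 30 shared equal-width bins
  spanning the pooled range (category frequencies for categorical
  variables). $H \in [0, 1]$, 0 for identical distributions. Pooling
  across visits (rather than per visit) is a fixed convention here; it
  matches how per-variable distances are summarized for longitudinal
  panels and keeps every variable's estimate well-populated.
* **Correlation structure** on the patients × (variable, visit) widened
  matrix, Pearson by default with Kendall available (preferable for
  coded categorical data and heavily tied panels), computed on
  pairwise-complete observations; columns with fewer than 3 observed
  values or zero variance are excluded with a warning. From the real
  and synthetic matrices come the vector of absolute upper-triangle
  differences (the box-plot source) and the scalar
  **RMSDC** $= \sqrt{\mathrm{mean}\,(C_\text{real} -
  C_\text{syn})^2_{\triangle}}$.
* **Descriptive summaries** per variable (min, quartiles, median, mean,
  sd, max, missing count against the full patient × visit grid), for
  both tables, plus overall missing fractions.

Reports serialize losslessly to JSON (`write_report()`/`read_report()`)
and have `print()` and `plot()` methods.

## The simulator, and what passing tests do and do not show

Because the clinical extracts such models are used on are access-
controlled, the package ships a fully specified simulator
(`sim_ehr_like()`) whose regimes mirror the shapes the method is meant
for: a dense 226 × 4 × 5 laboratory panel, the same four labs over 36
visits with 21% MCAR missingness, an irregular-visit variant (3–10
visits), and a dense 246 × 2 × 5 categorical panel — all with known
generative equations (see `?sim_spec`):
patient effect + AR(1) visit process for continuous variables
(defaults: same-visit cross-variable correlation 0.45, patient variance
share 0.65, AR coefficient 0.6, lab-like means/scales), and
persistent-preference categorical draws (persistence 0.8). These
defaults were fixed once as a realistic regime for repeated laboratory
panels and are not tuned per experiment.

The simulator emulates low-rank patient structure, temporal
autocorrelation, cross-variable dependence, MCAR missingness, irregular
visit counts and categorical marginals. It does **not** emulate
heavy-tailed or skewed laboratory distributions, informative (MNAR)
missingness, visit-time irregularity beyond truncation, or cohort
heterogeneity — so passing tests demonstrate that the machinery
preserves the structure it models, not that synthetic clinical data from
any particular hospital system would be fit for release.

Problem sizes used throughout the tests and the acceptance script are
the package's own choices for its simulated data: ranks 12 (dense
profile) and 8 with mask rank 4 (missing-data profile), rather than the
much larger ranks one would select on real 36-visit panels; recovery
checks use 20 × 6 × 10 tensors of rank ≤ 3; HMC recovery uses 500 rows
of a known 3 × 3 covariance with 4 chains of 400 + 400 iterations.

## Numerical details and degenerate inputs

* Masked cells carry `NA` sentinels in memory, are zeroed before any
  vectorized loss evaluation, and are provably inert: objectives,
  gradients, fit scores and standardization statistics are all invariant
  to their stored values (tested by perturbation).
* Standardization requires each variable to have ≥ 2 observed values and
  positive variance; constant variables raise an error naming the
  variable rather than producing infinities downstream.
* `fit_score` is undefined (error) when every observed entry is zero.
* Empirical-CDF inversion clamps at the extreme order statistics
  (`rule = 2`), kernel CDFs are deduplicated before inversion, and the
  gamma/beta marginals are fitted after an affine map onto their
  support.
* Ties in visit-count rounding go half-up (`floor(v + 0.5)`), then clip
  to $[1, K]$; categorical codes round half-up, clip to the admissible
  range and snap to the nearest admissible code.
* Seeds: every user-facing sampler and the pipeline take an integer
  seed; `synthesize()` derives per-stage seeds (`seed`, `seed + 1`, …)
  so stages stay reproducible independently. End-to-end runs are
  bitwise reproducible given (config, seed).

## Known limitations

* The mask model reproduces only structured missingness (see above);
  under pure MCAR the synthetic missing fraction can be far from the
  real one — it is reported, not corrected.
* Factors are identifiable only up to permutation and scaling; nothing
  should be read into the sign or order of individual components.
* The HMC model assumes a multivariate Gaussian latent space; latent
  spaces from non-Gaussian losses need the copula or tree samplers.
* Privacy is argued structurally (synthetic patients are sampled from
  the latent distribution, never copied or perturbed records); the
  package deliberately ships no formal privacy-attack evaluation, and
  none of its metrics should be read as a privacy guarantee.
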