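---
title: "Coping with family structure in marker-wise association: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coping with family structure in marker-wise association: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famlmm)
```

## The problem

Marker-wise association scans regress a quantitative trait (a methylation
beta value, an expression level, any continuous readout) on covariates, one
marker at a time, and rank markers by significance. When the cohort is made
of families, the observations are not independent: siblings share genetic
background, so residuals are correlated within families. Ignoring this
underestimates standard errors and inflates the type-I error; the scan's
"top hits" then contain an excess of false positives.

If the relatedness structure is known, the remedy is a linear mixed model.
`famlmm` implements that model from first principles and uses it to compare
three practical strategies side by side:

* **representative** — keep one randomly drawn member per family and run
  ordinary least squares on the retained, mutually independent subset. The
  model is valid but the effective sample size collapses to the number of
  families.
* **kinship** — keep everyone and model the family effect as a random
  effect whose covariance is proportional to the expected relationship
  matrix. The ideal option when kinship is available.
* **independence** — keep everyone and ignore the structure. The model is
  wrong, but all the data are used.

A fourth, derived strategy — the **hybrid** — takes the markers identified
by *both* the independence and the representative scans. It is motivated by
the empirical observation that the two wrong-in-opposite-ways strategies
rarely agree on a false positive.

## The model

For marker $j$ the trait vector $y_j \in \mathbb{R}^n$ follows

$$
y_j = X\beta_j + \mu_j + \epsilon_j, \qquad
\mu_j \sim N(0,\ \sigma^2_\mu K), \qquad
\epsilon_j \sim N(0,\ \sigma^2_\epsilon I_n),
$$

so that $\mathrm{Cov}(y_j) = \sigma^2_\mu K + \sigma^2_\epsilon I_n$. Here
$K$ is the expected relationship matrix. We store $K = 2\Phi$, where $\Phi$
is the kinship-coefficient matrix, so $K$ has unit diagonal for non-inbred
individuals and $K_{ij} = 0.5$ for full siblings (the GRM convention). Any
overall rescaling of $K$ is absorbed by $\sigma^2_\mu$, so the convention is
free; what matters is using it consistently, which every function in the
package does.

Founders are assumed non-inbred and unrelated across families, so $K$ from
a pedigree is block-diagonal by family. Simulated families are pure
sibships (siblings only, parents latent), giving exchangeable blocks with
unit diagonal and off-diagonal `within_value` (0.5 for full siblings).

### Variance components

The default estimator is REML on the spectral rotation. With
$K = U D U^\top$ computed once, rotating $y$ and $X$ by $U^\top$ makes the
covariance diagonal, $\sigma^2_\epsilon(\lambda D + I)$ with
$\lambda = \sigma^2_\mu/\sigma^2_\epsilon$, and every likelihood evaluation
costs $O(np)$ instead of $O(n^3)$. The restricted likelihood is profiled
over $\lambda$ by a coarse grid of 100 points on
$\log\lambda \in [-10, 10]$ followed by bounded golden-section refinement
(tolerance $10^{-8}$). Numerical choices worth knowing:

* If the profile maximum sits at an endpoint, $\lambda$ is clamped there
  and the fit is flagged `boundary = TRUE`; at the lower endpoint the
  family component is set to exactly zero.
* Ties (a flat profile) resolve to the smallest $\lambda$. With $K = I$ the
  ratio is unidentifiable and this tie-break yields the documented collapse
  $\sigma^2_\mu = 0$, $\sigma^2_\epsilon$ = residual mean square, which
  makes the kinship option reproduce ordinary least squares exactly.
* A constant trait returns $(0, 0)$.

An analysis-of-variance-style moment estimator (`anova_variance_components`,
Haseman–Elston regression of residual cross-products on kinship entries) is
provided for comparison; it is cheaper, unbiased before clamping, and less
efficient than REML when family sizes vary. Negative moment estimates are
clamped to zero with the `boundary` flag set; the pre-clamp value is kept
in `sigma2_mu_raw`.

### Fixed effects and tests

Given plugged-in components, coefficients are estimated by generalized
least squares through the same rotation (never an explicit inverse of
$V$), and the tested coefficient gets a Wald statistic. All options use
the standard-normal reference by default: the smallest analysis unit in
the package's study is 200 representatives, where normal and $t$ are
practically identical; a $t$ reference (df $= n - p$) can be switched on
for the representative option, which is the one with the smallest sample.
Two-sided p-values are floored at the smallest positive double so that
$p \in (0, 1]$ always holds. Each marker's variance components are
re-estimated independently — nothing is shared across markers except the
eigendecomposition of $K$.

## What the simulator emulates

`simulate_dataset()` draws each marker's trait independently from the
generating model above, with a mean shift `effect_delta` for `m_causal`
randomly chosen causal markers. The default configuration is the package's
study condition:

| parameter | default | why |
|---|---|---|
| `n_families` | 200 | the study's family count |
| `family_size` | `c(2, 3, 5, 7, 8)` recycled | mixed sibship sizes, mean 5, $n = 1000$ |
| `m_markers` / `m_causal` | 1000 / 10 | 1000 markers, 10 under the alternative |
| `within_value` | 0.5 | full siblings |
| `sigma2_mu`, `sigma2_eps` | 1, 1 | equal family and residual variance |
| `effect_delta` | 0.2 | intermediate power (see below) |
| `mode` | `"mean_shift"` | the alternative is a nonzero trait mean |

Two defaults deserve their rationale:

* **Mixed family sizes.** With *equal-size* exchangeable blocks and an
  intercept-only design, the rows of $V^{-1}$ sum to a constant, so the GLS
  estimate equals the OLS estimate for every marker: the kinship and
  independence options then differ only in their standard errors and
  produce near-identical rankings. Real sibship cohorts have variable
  sibship sizes, and it is exactly that imbalance that gives the mixed
  model its efficiency advantage (it downweights large families properly).
  The default `c(2, 3, 5, 7, 8)` keeps 200 families and $n = 1000$ while
  making the three options genuinely distinguishable.
* **`effect_delta = 0.2`.** Under the defaults the GLS standard error of
  the mean is about 0.063, so a shift of 0.2 puts the kinship option at
  roughly 70% power against the top-20 inclusion threshold, and the
  representative option (SE $\approx 0.1$) near 30%. Much larger shifts
  saturate every option at 100% recovery and erase the comparison; much
  smaller ones drown it in noise.

In `mode = "covariate"` the alternative is instead a nonzero coefficient on
a simulated continuous exposure, and the design gains the covariate
structure of a family methylation cohort: intercept, exposure, integer age
20–80, binary sex, binary site, and four orthonormal mean-zero
principal-component-like columns (nuisance coefficients fixed at 0.01 for
age, 0.25 for sex and site, 0.5 for each PC column). This mode exists to
mirror the shape of a real cohort analysis and is an extension, not the
study default.

What the simulator does **not** emulate: genotypes, allele frequencies,
linkage disequilibrium between markers (markers are independent given the
family structure), assay chemistry, missingness, or non-Gaussian traits.
Passing tests therefore demonstrate correctness of the machinery and of
the qualitative comparison under the stated model — not robustness of any
strategy to, say, heavy-tailed residuals or population stratification.

## The comparison harness

Significance is defined by ranking: the top-$k$ markers by p-value, ties
broken by marker index (a p-threshold mode with optional Bonferroni
correction exists but is not the default, since the study protocol is set
up around top-100 sets for cohort-scale scans and top-20 sets for the
simulation). `run_study()` simulates `n_replicates` datasets; per dataset
it fits kinship and independence once, redraws representatives
`n_representative_draws` times, and records for every (replicate, draw)
run the seven exclusive Venn regions of the three top-$k$ sets
(A = representative, B = kinship, C = independence), truth recovery and
FDR per option, and the hybrid intersection. FDR here is the fraction of a
reported set that is not a true signal; an empty hybrid set has undefined
FDR and is excluded from the FDR average (its size still counts in the
size average).

Aggregation uses the sample mean and sample SD (denominator $n - 1$)
across runs, pooling replicates and draws; the per-run tables keep both
indices so either axis can be re-aggregated separately. Kinship and
independence values are constant across draws within a replicate and are
repeated per run so that pooled averages weight runs equally.

The idealized expectation — representative hits nested inside kinship hits
nested inside independence hits — is only a diagnostic
(`nestedness_report` counts the escapes); it is violated routinely, which
is the phenomenon that motivates the hybrid strategy in the first place.

All seeds derive from the study seed through a fixed integer-mixing scheme
(`derive_seed`), so a report is reproducible bit for bit and every
randomized step (dataset, representative draw) has an independent stream;
the manifests written by the analysis scripts record them.

## Problem sizes used in the checks

The test suite validates the kinship recursion against a gene-dropping
Monte-Carlo oracle (20 random pedigrees of up to 10 members, $10^5$
dropped loci each), the spectral REML against a dense-matrix restricted
likelihood (machine agreement at $n = 20$; estimator agreement against an
independent dense optimizer at $n = 200$), variance-component recovery at
$n = 1000$ over 200 replicates, test calibration on 5000 null markers,
and the three-option comparison on 30 replicate studies of the default
configuration (150 runs). These sizes keep every check comfortably inside
a desktop run while leaving the Monte-Carlo bands tight enough to be
informative.

## Known limitations

* Inbreeding loops, X-linked kinship and genotype-based empirical
  relationship matrices are out of scope; pedigrees are assumed non-inbred
  and the validator enforces entries in $[0, 2]$ with unit-or-larger
  diagonal.
* The Wald/normal reference is mildly liberal for very few families; use
  the $t$ toggle for the representative option if the family count is
  small.
* Score and likelihood-ratio tests, multiple variance components, and
  binary traits are not implemented.
* The qualitative ordering of the options (kinship best; independence
  close behind with inflated type-I error; representative noisy) is a
  statement about averages across replicate studies at the default
  conditions; any single dataset can and does deviate.
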