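---
title: "Covariate-adjusted differential connectivity for microbiome networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate-adjusted differential connectivity for microbiome networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudonet)
```

## The problem

Microbial co-abundance networks summarize which taxa rise and fall together
across samples. Differential network analysis asks whether a taxon's
*connectivity* — how strongly it is tied into the rest of the community —
differs between two biological conditions (say, cases and controls). Classical
two-group network comparisons cannot adjust for the clinical covariates (age,
sex, BMI, diet) that routinely confound microbiome studies. `pseudonet`
addresses this with a regression formulation: instead of comparing two network
summaries directly, it converts each subject's contribution to the group
network into a *jackknife pseudo-value* of taxon degree centrality and
regresses those pseudo-values on the group indicator plus covariates.

## The model

**Network estimation.** Microbiome counts are compositional, so Pearson
correlations of relative abundances are biased. We use the SparCC
basis-variance decomposition: for fractions $u_j$, the log-ratio variance

$$t_{jk} = \mathrm{Var}\!\left(\log \frac{u_j}{u_k}\right)
         = \sigma_j^2 + \sigma_k^2 - 2\rho_{jk}\sigma_j\sigma_k$$

links the observable $t_{jk}$ to the latent basis variances $\sigma_j^2$ and
correlations $\rho_{jk}$. Under the sparsity approximation, the row totals
$t_j = \sum_{k \ne j} t_{jk}$ satisfy a linear system
$t_j \approx (p_j - 1)\,\sigma_j^2 + \sum_k \sigma_k^2$ over the retained
pairs, which `solve_basis_variances()` inverts; `estimate_correlations()`
then recovers $\hat\rho_{jk} = (\hat\sigma_j^2 + \hat\sigma_k^2 -
\hat t_{jk}) / (2\hat\sigma_j\hat\sigma_k)$. The classic estimator iterates,
excluding the strongest remaining pair above a threshold (default 0.1, at
most 10 exclusions) so that a few true strong correlations do not contaminate
the basis solution. Estimation is a deterministic single pass on
pseudocount-smoothed fractions (pseudocount 1); we deliberately do not use
Dirichlet resampling, so that every leave-one-out re-estimate is exactly
reproducible.

**Degree centrality and pseudo-values.** For taxon $k$ the connectivity
summary is the signed marginal sum $\hat\theta_k = \sum_j \hat\rho_{jk}$,
including the unit diagonal (the constant is absorbed by the regression
intercept; an absolute-value variant is available via `absolute = TRUE`, and
the convention used is recorded in the output metadata). Within each group
$z$ of size $n_z$, the jackknife pseudo-value for subject $i$ and taxon $k$
is

$$\tilde\theta_{ik} = n_z\,\hat\theta_k^z - (n_z - 1)\,\hat\theta_{k(i)}^z,$$

where $\hat\theta_{k(i)}^z$ is re-estimated with subject $i$ removed.
Pseudo-values behave approximately like independent subject-level responses,
which is what licenses the regression step. They are computed
group-specifically; a pooled variant (all samples in one network with the
group as covariate only) is not offered, as pooling discards the
between-group network difference the test targets.

**Regression and testing.** For each taxon, the pseudo-values are regressed
on an intercept, the 0/1 group indicator, and the covariates:

$$E[\tilde\theta_{ik} \mid Z_i, X_i] = \alpha_k + \beta_k Z_i +
  \sum_m \gamma_{km} X_{im}.$$

The fit is least trimmed squares (LTS) to guard against wild pseudo-values,
$U_k = \hat\beta_k / \mathrm{SE}(\hat\beta_k)$ is referred to a
t-distribution with the retained-observation degrees of freedom, and Storey
q-values control the FDR across taxa ($q_k < \alpha$, default
$\alpha = 0.05$, flags taxon $k$ as differentially connected).

For paired two-timepoint designs, `dc_test_paired()` computes centralities
on the *difference* of the two timepoints' association matrices per group
(each leave-one-out removes the subject from both timepoints), so $\beta_k$
measures group differences in the temporal change of connectivity.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `pseudocount` | 1 count | zero smoothing before fractions |
| `exclusion_threshold` | 0.1 (correlation) | strong-pair exclusion cutoff |
| `max_exclusion_iters` | 10 | exclusion loop length; 0 = smooth variant |
| `coverage_fraction` | maximal breakdown, $h = \lfloor (n+d+1)/2 \rfloor$ | LTS trimmed-objective coverage |
| `n_initial_subsets` | 500 | FAST-LTS elemental starts |
| `reweight_cutoff` | 2.5 (sd units) | post-trimming outlier rejection |
| `alpha` | 0.05 | q-value call threshold |
| `qvalue_method` | `"storey"` | `"bh"` as conservative fallback |

## The smoothness trade-off of the exclusion loop

The jackknife's validity rests on the functional being smooth in the sample.
The exclusion loop is a *discrete model-selection step*: removing one subject
can flip which pair is excluded, changing $\hat\theta_{k(i)}$ by a jump, and
the pseudo-value multiplies that jump by $n_z - 1$. The consequence, measured
by this package's test suite, is a two-regime behavior:

* with the classic iterative estimator (the default, matching how the method
  is defined), pseudo-values are heavy-tailed, per-taxon tests become
  strongly anticonservative under global network perturbations, and the
  pipeline operates as a highly sensitive screen — under simulation it calls
  most taxa once any part of the network differs, so recall is high while
  precision approaches the prevalence of truly differential taxa;
* with `sparcc_config(max_exclusion_iters = 0)` the centrality is a smooth
  functional, the complete-null type-I error is near the nominal 5% level
  (a property test verifies this), and power against localized single-edge
  differences is correspondingly modest.

Both configurations are first-class; the default follows the method's
definition, and the screening interpretation should be kept in mind when
reading its output. Any positive finding warrants experimental follow-up.

## Least trimmed squares: numerical choices

`fit_lts()` implements FAST-LTS: 500 random elemental starts, two
concentration steps each, full refinement of the ten best candidates. The
raw scale $\sqrt{\mathrm{obj}/h}$ is multiplied by the Gaussian consistency
factor for the trimmed variance and by a finite-sample correction calibrated
once by simulation under the Gaussian model over $n \in [30, 400]$,
$d \in [2, 5]$ (best-of-many subset search overfits noise, biasing the raw
scale low — the same reason the reference LTS implementations carry
published small-sample correction factors). Observations with standardized
residuals within 2.5 are retained; coefficients, scale and standard errors
come from least squares on the retained set, with two further calibrated
corrections so that the reported scale is unbiased and the reported standard
errors match the estimator's true finite-sample sampling variability under
the Gaussian reference model. A dedicated test verifies near-nominal
rejection rates on clean Gaussian data. At full coverage ($h = n$) the fit
reduces exactly to ordinary least squares. Degenerate cases: an exact fit
(zero raw scale) retains all points; rank deficiency on every subset is an
error; a per-taxon failure inside `taxon_tests()` yields an NA row with a
warning instead of aborting the analysis.

The coverage default is the maximal-breakdown count
$h = \lfloor (n + d + 1)/2 \rfloor$. A literal reading of a trimming
proportion $c \in [0.5, 1]$ with $h = [n(1 - c)] + 1$ would allow coverage
as low as one observation, which contradicts LTS breakdown theory, so the
conventional coverage-count parameterization is used and exposed as
`coverage_fraction`.

## q-values

Storey's estimator computes $\hat\pi_0(\lambda)$ on the grid
$\lambda = 0, 0.05, \dots, 0.95$ and evaluates a cubic smoothing spline at
$\lambda = 0.95$. With strongly signal-dominated p-value sets the smoothed
estimate can reach zero; it is then stabilized to $1/m$ (one null
hypothesis' worth of mass) rather than erroring. Forcing `pi0 = 1`
reproduces Benjamini-Hochberg exactly, and `method = "bh"` is offered as the
conservative fallback. Because the per-taxon tests share one estimated
network, they are not independent; q-values here — as in any differential
network analysis — inherit that caveat.

## The synthetic-data generator

`simulate_dataset()` emulates a two-group microbiome study in which the
truth is known by construction:

* groups $Z_i \sim \mathrm{Bernoulli}(0.5)$; covariate
  $X_i \sim N(55, 10^2)$ (an age-like variable), with the group-2 mean
  shifted by 5 years in the multivariable design;
* a fresh Barabasi-Albert scale-free network per replicate (igraph, $m = 1$);
  each group's spiked taxon set $S_z$ (a fraction $\delta_z$, drawn uniformly
  among non-isolated nodes) has all incident edges removed from that group's
  truth adjacency $\Omega^z$; the truth label is
  $\eta_k = I\big(\sum_j |\Omega^1_{jk} - \Omega^2_{jk}| > 0\big)$;
* latent Gaussian vectors per group with correlation 0.6 on that group's
  truth edges (projected to the nearest positive-definite correlation by
  eigenvalue clipping at $10^{-8}$ and rescaling);
* zero-inflated truncated log-normal marginals through the copula quantile
  transform: a taxon's abundance is zero when its latent Gaussian falls in
  the lower `zero_inflation` (default 0.3) tail — so zeros are coupled
  across taxa, as a Gaussian copula with zero-inflated marginals implies —
  and otherwise is log-normal with taxon-level location ($N(0,1)$) and scale
  ($U(0.5, 1.5)$), upper tail winsorized at 3 sd;
* spiked taxa receive `effect_coefficient` (default 1) times standardized
  $X_i$ on the latent log scale within their group (multivariable), or a
  constant unit shift in group 2 (univariable, where $S_1 = \emptyset$);
* integer counts by multinomial sampling at a log-normal library size
  (median 10,000).

The explicit copula is what makes the benchmark meaningful: the
differential edges asserted by the truth labels are actually present in the
data's co-abundance structure, and the spiked taxa additionally carry a
covariate-associated abundance signal. What the generator does *not*
emulate: marginals calibrated to a real template dataset, taxon-specific
prevalence/abundance relationships beyond the shared copula threshold,
overdispersion beyond the log-normal, or batch structure. Passing the
simulation benchmarks therefore demonstrates correct behavior under this
generative model, not performance guarantees on real data.

Replicate seeds are `seed + s`, so a configuration is byte-reproducible;
drawing a new network per replicate reflects between-study biological
variability of network structure.

## Problem sizes used by the test suite

The packaged checks run at desk scale on one CPU: algebraic properties on
$p \le 10$, $n \le 40$; oracle comparisons (exhaustive LTS enumeration at
$n \le 12$, rebuild-from-scratch jackknife at $p = 10$, $n = 40$); a
200-replicate complete-null calibration at $p = 20$, $n = 100$; and
benchmark cells at $p = 20$ and $p = 40$, $n = 200$ with 50 and 30 Monte
Carlo replicates respectively. The corresponding study-scale analyses use
1,000 replicates; the replicate means reported here carry Monte Carlo
standard errors so the two scales can be compared honestly.

## Known limitations

* Pseudo-value inference assumes approximate subject-level independence of
  pseudo-values; with the iterative (default) network estimator this fails
  under perturbation, and the test behaves as a sensitive screen rather than
  a calibrated test (see the trade-off section above).
* The paired two-timepoint variant does not model within-subject correlation
  across more than two timepoints; repeated-measures extensions would need a
  GEE-style covariance treatment.
* Groups must be binary; multi-level groups are out of scope.
* q-value guarantees are approximate under cross-taxon dependence.
* LTS standard errors are calibrated under a Gaussian reference model;
  strongly non-Gaussian pseudo-value noise retains some residual
  anticonservatism.
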