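---
title: "Low-rank linear mixed models for GWAS confounding correction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-rank linear mixed models for GWAS confounding correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrlmm)
```

## The problem

Population structure and kinship make individuals' phenotypes covary through
their genomes, which biases naive per-marker tests of association. Two
standard corrections exist: include leading principal components (PCs) of a
genetic relationship matrix (GRM) as fixed effects, or fit a linear mixed
model (LMM) with the GRM as the covariance of a random effect. Both act on
the same regression space — the LMM is exactly a regression on *all* PCs,
weighted by their singular values, with a Gaussian prior on the
coefficients — but they differ in how many dimensions they use and how
strongly each is shrunk. This package implements:

1. spectral (eigendecomposition-based) exact ML/REML fitting of the LMM;
2. the **effective degrees of freedom** (EDF) of the correction — the trace
   of the random-effect hat matrix — as a measure of model complexity;
3. a **low-rank LMM (LRLMM)** that orders PCs by relevance, scans ranks
   0…r, and selects the dimensionality of the correction with an
   information criterion;
4. Balding–Nichols simulators and an FDR/power evaluation harness that
   reproduce the statistical structure of the evaluation studies.

## Model and fitting

With standardized genotypes $X$ ($n \times m$, columns centered at $2\hat p$
and scaled by $\sqrt{\hat p(1-\hat p)}$), the GRM is $K = XX^\top/m$ and
$K = U \Lambda U^\top$. The LMM is

$$ y \sim \mathcal N\!\left(W b,\; \sigma_g^2 K_S + \sigma_e^2 I\right),
\qquad K_S = U_S \Lambda_S U_S^\top, $$

where $S$ indexes the PCs carrying the random effect (all of them for the
full-rank LMM). Rotating by $U^\top$ diagonalizes the covariance:
coordinate $j$ has variance $\sigma_g^2\lambda_j + \sigma_e^2$ for
$j \in S$ and $\sigma_e^2$ otherwise. Writing
$\delta = \sigma_e^2/\sigma_g^2$, the fixed effects and $\sigma_g^2$ are
profiled out in closed form (generalized least squares on the rotated
coordinates), leaving a one-dimensional problem in $\delta$.

**Optimization.** $\delta$ is maximized over a log-spaced grid of 100
points on $10^{-5}\dots 10^{5}$, then refined by golden-section search
between the best grid point's neighbors. The OLS limit
($\delta \to \infty$, no genetic variance) is always evaluated and wins
ties, so the fit degrades gracefully to the linear model. The procedure is
deterministic given the inputs. The grid range and resolution are package
choices (the optimizer behind the original analyses is not specified
anywhere we could follow); the profile is smooth in $\log\delta$ and the
refinement step makes the result insensitive to the grid resolution.

**REML** uses the Harville restricted likelihood including the
$\tfrac12\log|W^\top W|$ term, so its value is invariant to the basis of
the fixed effects. ML is the default throughout (REML-vs-ML differences are
small for these applications), with one caveat below.

**Numerical choices.** Eigenvalues below $10^{-10}\lambda_1$ are clipped to
zero; eigenvalue ties in orderings break by original index. $K$ is
trace-normalized to $n$ before fitting so that variance components are
interpretable (see pseudo-heritability below). A rank-deficient rotated
design raises an error rather than silently pseudo-inverting.

**A boundary caveat for full-rank ML.** A column-centered GRM has a zero
eigenvalue whose eigenvector is the constant vector — exactly the
intercept. In the full-rank ML profile that coordinate is fit perfectly at
every $\delta$, which adds a $-\tfrac12\log\delta$ term to the profile and
creates a weak pull toward $\delta = 0$ (heritability 1) whenever the
likelihood is otherwise flat, e.g. at modest $n$ with a bulk-dominated
spectrum. The grid's lower bound keeps the fit finite, and REML cancels the
term exactly; for full-rank heritability estimation at modest sample sizes
REML is therefore the better choice, and the EDF confidence-interval tests
use it. Low-rank fits are unaffected (their off-$S$ coordinates carry real
residuals that anchor $\delta$).

## Effective degrees of freedom

For any fit that is linear in the response, $\hat y = Hy$, the complexity
of the fit is $\mathrm{tr}(H)$, which equals the parameter count for
ordinary least squares. For the LMM's random effect,
$H = K_S(K_S + \delta I)^{-1}$ and

$$ \mathrm{EDF} = \sum_{j \in S} \frac{\lambda_j}{\lambda_j + \delta}, $$

a sum of per-PC contributions in $[0,1]$: a PC contributes more when its
eigenvalue is large and less when the phenotype-adaptive $\delta$ is large.
Fixed effects are excluded from this EDF (the criteria add them back as an
explicit $c$). Confidence intervals for the EDF come from the profile
likelihood in $\delta$: a fine grid (400 log-spaced points spanning
$\delta_{\mathrm{MLE}} \times 10^{\mp 4}$), a $\chi^2_1$ likelihood-ratio
cut at level $1-\alpha$, and the monotone map from the $\delta$ interval to
EDF. These intervals are illustrative rather than optimal; when the
accepted region touches the grid boundary the grid is widened once and the
affected bound is flagged as censored. Where EDF is reported relative to
sample size we normalize by $n$ (not $n-c$).

## The low-rank LMM

Ranks $r = 0 \dots r_{\max}$ are scanned by adding PCs in one of four
orders:

* **eigenvalue** — marker-informed only;
* **corSq** — squared correlation between each PC and the phenotype
  (residualized on the covariates);
* **corSq_x_eigenvalue** — the product of the two;
* **DF** — the EDF of a rank-1 LRLMM fit to each PC individually, each
  with its own optimized $\delta$.

Each rank records the maximized log-likelihood, EDF, and

$$ \mathrm{AIC} = -2\ell + 2(\mathrm{EDF} + c + 2), \quad
   \mathrm{BIC} = -2\ell + \log(n)(\mathrm{EDF} + c + 2), \quad
   \mathrm{GCV} = \frac{n\,\mathrm{RSS}}{(n - \mathrm{EDF} - c)^2}. $$

The constant "+2" counts the two variance components; it is shared across
ranks, so it shifts but never reorders the criteria. GCV's RSS is the
unweighted residual sum of squares at the plug-in BLUP fit (computed in the
rotated basis, where the coordinate residuals shrink by
$\delta/(\lambda_j+\delta)$ on included PCs). Rank selection is the argmin;
ties resolve to the smaller rank; $-2\ell$ is provided but degenerate for
the eigenvalue ordering (monotone in rank). `r_max` defaults to
`min(n, n - c - 2)` and can be capped; when the confounding is known to
live in the leading PCs (as in the simulation studies, where it is drawn
from the first 30), capping at 50 changes nothing but runtime.

**Selection bias of phenotype-aware orderings.** Under a null phenotype,
BIC on the *eigenvalue* ordering selects rank 0 essentially always. The
corSq and DF orderings, however, sort by statistics maximized over $n$
PCs; the best spurious PC carries a likelihood gain of roughly
$2\log n$, which exceeds the $\log n$ BIC penalty, so one to three
spurious PCs are typically admitted. This is an inherent property of
ordering PCs on the phenotype, not a defect of the criterion; it leaves
null-scan calibration intact (the spurious PCs absorb a vanishing share of
variance) and inflates the selected rank by a couple of units in
rank-recovery experiments.

## Association scans and calibration

Mixed-model scans rotate phenotype, covariates and all markers into the
eigenbasis once. By default $\delta$ is estimated once under the null model
and reused for every marker (the standard approximation that makes
genome-wide scans linear-time); `delta_policy = "exact"` re-optimizes per
marker for verification, and the two agree closely away from extreme
p-values. Statistics are Wald: $t$ with $n - c - 1$ degrees of freedom for
the linear model, standard normal for mixed models. Monomorphic markers are
reported with $p = 1$ and a flag. The genomic-control $\lambda$ is the
median association $\chi^2_1$ over its null median (0.4549); markers
included in $K$ are also tested (no leave-one-chromosome-out), which is a
documented limitation shared with the classic LMM tools this follows.

## What the simulators emulate — and what they do not

`simulate_structured_genotypes()` draws Balding–Nichols genotypes:
ancestral frequencies uniform on (0.05, 0.95) (avoiding near-monomorphic
markers), per-population frequencies Beta-distributed with dispersion set
by $F_{st}$, binomial dosages, equal population sizes. Markers are
independent given ancestry — there is no linkage disequilibrium beyond
what shared ancestry induces — and are laid out at 20 kb spacing across 22
chromosomes purely so positional clustering rules are exercised.
`simulate_phenotype()` builds confounding from sampled PCs (or from the
markers most correlated with leading PCs, in the stratified mode), adds
causal-marker effects and noise, and rescales the components *exactly*
(after in-sample orthogonalization) so the stated variance fractions hold
in every replicate, not just in expectation. Coefficients are standard
normal before rescaling; the exact coefficient-variance constants of the
original studies are not recoverable from the text, and exact rescaling
reproduces every stated variance target while fixing the unknown scale.

Passing tests on these generators show that the estimator and its
selection rules behave as claimed when the generating process matches the
model family. They do not speak to LD-induced false-positive structure, to
rare variants, or to phenotypes whose confounding is not spanned by
leading PCs.

**Study conditions.** The heritability-recovery and null-calibration
studies use a homogeneous population (`n_pops = 1`, n = 1000, m = 5000):
the reference analyses drew both from a single-ancestry cohort, whose
leading 30 eigenvalues are comparable in size. That matters because with
equal-amplitude PC coefficients a strongly differentiated 3-population GRM
(two dominant ancestry eigenvalues) makes the phenotype inconsistent with
the LMM's eigenvalue-weighted prior, biasing $\hat h^2$ upward, and makes
markers mutually correlated through ancestry, widening the null
distribution of genome-wide calibration statistics beyond what independent
tests would give. The power study keeps 3 populations at $F_{st} = 0.05$
(its confounding is meant to be ancestry-like), at n = 500, m = 2000 with
15–25 replicates for the directional comparisons. The heritability study
runs 100 replicates with the rank scan capped at 50.

## Pseudo-heritability

With $K$ trace-normalized to $n$, the full-rank pseudo-heritability is
$\sigma_g^2/(\sigma_g^2+\sigma_e^2) = 1/(1+\delta)$. For a low-rank fit the
genetic variance actually injected into the phenotype is
$\sigma_g^2 \, \mathrm{tr}(K_S)/n$, so the package reports

$$ h^2 = \frac{1}{1 + \delta \, n / \sum_{j\in S}\lambda_j}, $$

which reduces to the full-rank formula when $S$ is everything and equals
the fraction of phenotypic variance the fitted genetic term explains. Under
the definition without the trace adjustment, a rank-10 model of a phenotype
whose PCs explain half the variance would report $h^2$ near 1.

## Evaluation rules

A significant marker is a true positive if its squared genotype correlation
with some causal marker is at least `r2_cutoff` (default 0.1 — the
reference analyses' exact cutoff is not recoverable from the text, so it is
exposed and reported); otherwise it is a false positive. Hits of either
kind merge into clusters when within 100 kb on a chromosome; the FDR at a
p-value threshold is `false_clusters / (false_clusters + true_clusters)`,
and power is the number of *causal markers* tagged by at least one true
positive at the most permissive threshold with FDR at or below the target.
Thresholds sweep the observed p-values exactly (no interpolation), so
operating points are reproducible.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
g <- simulate_structured_genotypes(500, 2000, n_pops = 3, seed = 1)
sp <- eigendecompose(compute_similarity(standardize_genotypes(g)))
sim <- simulate_phenotype(
  g, sp, confounding = list(type = "pc_based", k_relevant = 10,
                            pool_size = 30, var_frac = 0.15),
  n_causal = 10, h2_total = 0.4, seed = 2)

scan <- rank_scan(unname(sim$y), spectrum = sp, ordering = "corSq", r_max = 40)
sel <- select_rank(scan, "BIC")
res <- assoc_scan(g, unname(sim$y), model = "lrlmm", spectrum = sp,
                  fit = sel$fit)
power_at_fdr(res, sim$truth, g, fdr = 0.05)
```

## Known limitations

* One genetic variance component plus residual; no multiple random
  effects, no sparse kinship.
* No leave-one-chromosome-out; tested markers participate in $K$.
* Gaussian phenotypes only; no binary-trait or interaction models.
* The EDF confidence intervals inherit the asymptotic fragility of
  boundary likelihood-ratio intervals when $\hat\delta$ sits at the edge of
  its range.
* Mean imputation is the only missing-genotype policy; heavy missingness
  deserves proper imputation upstream.
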