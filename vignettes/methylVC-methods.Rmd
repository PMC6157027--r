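---
title: "Methylation kernels as genetic variance components: models and methods"
author: "methylVC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation kernels as genetic variance components: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylVC)
```

## The model

methylVC asks whether the DNA-methylation state of CpG sites flanking one
gene explains part of a quantitative trait's variance, over and above the
polygenic background carried by family structure. For a trait vector $y$
measured on $n$ related individuals it fits, by maximum likelihood under a
multivariate normal, the mixed model

$$
y \sim \mathcal{N}\!\left(X\beta,\; \Omega\right), \qquad
\Omega \;=\; \sigma^2_{Total}\left(2\Phi\, h_r^2 \;+\; E\, h_{meth}^2
\;+\; I\, e^2\right),
$$

where $\Phi$ is the expected kinship matrix from the pedigree (so $2\Phi$ is
the additive relationship matrix), $E$ is a gene-specific methylation
relationship kernel with unit diagonal, $I$ is the identity, and
$h_r^2 + h_{meth}^2 + e^2 = 1$. The fixed effects $X$ default to intercept,
sex and age. Because every structuring kernel has unit diagonal, the
diagonal of $\Omega$ is $\sigma^2_{Total}$ for outbred individuals and the
three fractions are interpretable as proportions of phenotypic variance.

A variant of the model with the methylation kernel entering as $2E$ is
sometimes written down by analogy with $2\Phi$. With a unit-diagonal $E$
that coefficient would make the diagonal of $\Omega$ equal to
$\sigma^2(h_r^2 + 2h_{meth}^2 + e^2)$ and destroy the
proportion-of-variance reading of $h_{meth}^2$, so methylVC uses
coefficient 1 by default; `fitVarComp()` accepts any kernel list, so a
caller who wants the $2E$ parameterization can simply pass `2 * E`
(the fitted fraction then halves, the likelihood-ratio statistic is
unchanged).

The association test for one gene compares the full model against the
polygenic null $\Omega = \sigma^2(2\Phi h_r^2 + Ie^2)$ with a likelihood
ratio. Since $h_{meth}^2$ is tested on the boundary of its parameter space,
the null distribution of the LRT is a 50:50 mixture of a point mass at zero
and a $\chi^2_1$; `mixturePvalue()` implements
$p = \tfrac12 P(\chi^2_1 \ge \mathrm{LRT})$ for positive statistics. This
reference is known to be slightly conservative in finite family samples,
which the acceptance checks confirm (empirical type-I error at
$\alpha = 0.05$ is at or below 0.06).

**Convention at LRT = 0.** Half of all null statistics are exactly zero.
Some implementations report $p = 0.5$ there; methylVC reports $p = 1$, so
that genes with no fitted methylation variance can never drift toward the
significant tail. The choice only affects genes with literally zero signal.

## Kernel construction

For each gene with at least `minSites` (default 5) annotated CpG sites, the
site rows are extracted from the (inverse-normalized, usually PC-corrected)
methylation matrix and standardized per site to mean 0, variance 1
(`standardizeSites()`; samples × sites orientation, missing entries imputed
to the post-standardization mean 0, constant sites dropped). From
$Z\ (n \times m)$ the kernel is

$$
R = ZZ^{\mathsf T}, \qquad K = D^{-1/2}\, R\, D^{-1/2},\quad D =
\mathrm{diag}(R),
$$

i.e. the pairwise sample correlation of standardized site vectors. The
$D^{-1/2}$ scaling is the only transformation that guarantees every
diagonal element equals 1 exactly, which is what makes $h^2_{meth}$ a
variance proportion; it also makes $K$ invariant to whether site
standardization divides by $n$ or $n-1$ (both conventions are offered,
sample sd is the default). The minimum-site filter exists because kernels
built from very few sites produce spuriously extreme pairwise correlations.
Genes reduced below the threshold by constant-site drops are skipped and
listed in the scan's skip report rather than silently absorbed.

## Kinship

`kinshipMatrix()` uses the standard recursive (tabular) method over a
topological order of the pedigree:
$\phi_{ii} = \tfrac12(1 + \phi_{f(i)m(i)})$ and
$\phi_{ij} = \tfrac12(\phi_{f(i)j} + \phi_{m(i)j})$, with missing parents
contributing zero. It is exact, $O(n^2)$ in memory, and entirely adequate at
the scale of family studies; founders-only pedigrees give $\Phi = 0.5I$
exactly and inbred pedigrees are handled (the diagonal exceeds 0.5). Row
and column order follows first appearance in the pedigree file, and all
downstream alignment is by sample id, never by position.

## Inverse-normal transformation

Methylation beta values are bounded, skewed and heteroscedastic, so each
site row is mapped to rank-based normal scores before any modelling:
$\Phi^{-1}\!\big((r_i - c)/(n - 2c + 1)\big)$ with the Blom offset
$c = 3/8$, the common default in genetic epidemiology; $c$ is exposed as an
argument. Ties take average ranks (deterministic and symmetric), missing
values are excluded from ranking and remain missing, and sites with fewer
than three observed values are dropped with a warning. Normalization is
always within the supplied matrix — if two timepoints are analysed, each
matrix is normalized separately.

## Principal-component batch correction

Array methylation data often carry a strong sample-level artifact
(plate/batch structure). methylVC estimates it by PCA with **samples as
observations** and a random 10% subset of sites as variables (defaults:
`subsetFraction = 0.10`, `nComponents = 20`, mandatory seed). That
orientation is the only one that yields one score per sample, usable as a
fixed-effect covariate in per-sample models. Subset membership is a
function of the site-id set and the seed alone, so the fit does not depend
on row order. Variables are centered but not rescaled (rows are already
near unit variance after inverse-normalization); centering/scaling of the
PCA input is handled internally by `prcomp`.

Two consumption routes are provided, because both are legitimate and they
serve different stages:

* `residualize()` replaces each site row by its least-squares residual on
  the PC scores — used before kernel construction (`runPipeline()` default
  `residualizeBeforeKernel = TRUE`), so kernels measure gene-local
  covariance rather than the global artifact;
* PC scores as fixed-effect covariates in the per-site heritability scan
  (`siteH2Scan(..., pcs = )`), the classical route for the per-site model.

The package's synthetic batch factor is drawn **per family**, not per
sample. An artifact independent across individuals only adds environmental
noise and would *deflate* per-site heritability; what inflates it — the
phenomenon this correction exists for — is batch structure confounded with
family (relatives processed on the same plate), which masquerades as
familial covariance. With `batchSd = 1` the naive mean per-site $\hat h^2$
roughly triples relative to `batchSd = 0` at a true value of 0.2, and
residualizing on 20 PCs from a 10% site subset brings the two arms back to
statistically indistinguishable distributions; this is exercised in the
acceptance tests.

## Maximum-likelihood fitting

All fits profile the fixed effects by GLS and $\sigma^2_{Total}$ in closed
form, leaving only the variance fractions free.

*One kernel.* With eigendecomposition $K = UDU^{\mathsf T}$, rotating the
data by $U^{\mathsf T}$ makes the covariance diagonal,
$w_i = s d_i + (1-s)$, so each evaluation of the profiled log-likelihood in
the genetic fraction $s$ is $O(nq^2)$. The maximizer is found by a
deterministic coarse grid ($s \in \{0, .1, .25, .5, .75, .9, 1{-}10^{-7}\}$)
followed by golden-section refinement (interval tolerance $10^{-8}$); the
boundary $s = 0$ is evaluated exactly and estimates below $10^{-6}$ are
snapped to 0.

*Two kernels.* The fraction pair is reparameterized as
$\theta = s\,(p,\, 1-p)$ with total genetic fraction $s$ and mixing ratio
$p$. For fixed $p$ the combined kernel $K_p = p\,2\Phi + (1-p)E$ is
eigendecomposed once and the inner problem in $s$ is solved exactly as
above; $p$ is searched on the grid $\{0, .25, .5, .75, 1\}$ and refined by
golden section (tolerance $10^{-3}$, which resolves fractions far below the
reporting scale). This profiled search is deterministic, needs only
15–20 eigendecompositions per gene, and — the property the likelihood-ratio
test depends on — evaluates $p = 1$ (the null model) *exactly*, so the
full-model likelihood can never fall below the null's and null-true genes
return LRT = 0 to machine precision rather than optimizer noise. Statistics
below $10^{-8}$ are reported as exact zeros. The eigendecomposition itself
is a small C++ routine (LAPACK divide-and-conquer via RcppArmadillo), the
single hot spot of a genome scan.

ML is the default (REML is available via `method = "REML"`); ML is what the
likelihood-ratio comparison of nested mean-identical models requires.
Degenerate inputs are handled explicitly: an aliased kernel ($E = 2\Phi$)
leaves the components unidentifiable but the fit still converges with the
null's likelihood; near-singular covariances get a logged $10^{-8}$ ridge
in the exact-likelihood evaluator `vcLogLik()`.

## Per-site heritability scan

`siteH2Scan()` treats each (inverse-normalized) site as the trait of a
polygenic model versus a sporadic (no-kernel) model. The kinship
eigendecomposition is shared across all sites, so a 1000-site scan on 200
samples takes seconds. The reported p-value uses the same boundary mixture.

## Multiple testing

The genome-wide threshold is Bonferroni, $\alpha / n_{tests}$, with
$n_{tests}$ the number of *converged* gene tests in the scan (configurable
$\alpha$, default 0.05). A Benjamini–Hochberg FDR column can be added
trivially by the caller from the returned p-values; the scan's Q-Q export
uses expected quantiles under the mixture null, because half the null
p-values equal 1 and a uniform reference would fake deflation.

## The synthetic-data generator

`simulateDataset()` exists so that every claim the package makes is
testable without access-restricted cohort data. It emulates:

* family-structured samples (nuclear or three-generation families,
  founders unrelated across families);
* per-site heritable methylation: latent value
  $g + \lambda_s b + \varepsilon$ with $g \sim \mathcal N(0, h^2_{site}
  \cdot 2\Phi)$, loadings $\lambda_s \sim U(0.5, 1)$, family-level batch
  factor $b$, mapped to the beta scale by the standard normal CDF — chosen
  so the rank-based inverse-normal transform is (approximately) its
  inverse and the simulated pipeline is self-consistent;
* a trait drawn from exactly the fitted covariance model, with sex/age
  effects fixed at $\beta = (0.5, 0.01)$ and configurable polygenic /
  methylation fractions.

The desk preset — 40 families of 5 (200 samples), 1000 sites, 50 genes of
5–30 sites, site $h^2 = 0.2$, polygenic trait fraction 0.3 — was chosen so
that full acceptance runs (500 null replicates, 50-replicate parameter
recovery at $n = 600$, 20-gene ranking scans at $n = 400$) complete in
minutes on one CPU. What the generator does **not** emulate: real CpG-island
coordinates and correlation structure along the chromosome, array-specific
noise (detection p-values, probe chemistry), cell-type composition, or
longitudinal drug response. Passing tests therefore demonstrate
correctness of the statistical machinery under its own assumptions, not
robustness to artifacts of any particular platform.

## Numerical choices, in one place

| choice | value | why |
|---|---|---|
| inverse-normal offset | Blom $c = 3/8$ | standard in genetic epidemiology; configurable |
| site sd convention | sample ($n-1$) | kernel is invariant to it after scaling |
| per-site missingness cap | 20% | kernels stay informative; configurable |
| min sites per gene | 5 (inclusive) | few-site kernels are noise-dominated |
| fraction snap tolerance | $10^{-6}$ | boundary point mass must be exact |
| LRT zero tolerance | $10^{-8}$ | below likelihood-evaluation noise |
| mixing-ratio tolerance | $10^{-3}$ | resolves fractions to $\sim10^{-3}$ |
| singular-covariance ridge | $10^{-8} I$ | applied once, with a warning |
| p at LRT = 0 | 1.0 | null genes never look significant |

## Known limitations

Two structured kernels at most (no multi-gene joint models, no dominance or
GxE components); no bivariate/longitudinal modelling across timepoints — a
two-timepoint study is analysed as two separate scans; dense $O(n^2)$
kernels and $O(n^3)$ decompositions limit the sample size to cohort scale
(thousands), which is where pedigree studies live anyway; p-values rest on
the asymptotic boundary mixture rather than permutation, and are slightly
conservative.
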