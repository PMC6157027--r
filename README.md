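# methylVC

Gene-level DNA-methylation variance components in pedigree-based linear
mixed models.

## The problem

Epigenome-wide studies in family cohorts measure hundreds of thousands of
CpG sites alongside quantitative traits. Testing each site individually
carries an astronomical multiple-testing burden and ignores that the sites
flanking one gene act together on its transcriptional control. methylVC
takes the variance-component route instead: the methylation state of all
CpG sites near a gene is summarized into one samples-by-samples
relationship kernel, and that kernel is tested as an **additional genetic
variance component** in the classical polygenic mixed model for related
individuals.

For a trait `y` on `n` family members the full model is

    y ~ N(Xb, Omega),    Omega = sigma2_Total * (2*Phi*h_r2 + E*h_meth2 + I*e2)

where `Phi` is the expected kinship matrix from the pedigree, `E` is the
gene-specific methylation kernel (unit diagonal, so `h_r2`, `h_meth2` and
`e2` are proportions of phenotypic variance summing to 1), and `X` holds
intercept, sex and age. Each gene is screened with a likelihood-ratio test
against the polygenic null `Omega = sigma2*(2*Phi*h_r2 + I*e2)`; because
`h_meth2` sits on its boundary under the null, p-values come from the 50:50
mixture of a point mass at zero and a 1-df chi-square.

The package covers the full workflow for whom this is the daily bread —
statistical geneticists working with family methylation cohorts:

* pedigree parsing and exact recursive kinship (`readPedigree`,
  `kinshipMatrix`, `additiveMatrix`);
* methylation I/O, per-site rank-based inverse-normal transform, CpG-to-gene
  indexing with the >= 5 sites validity filter (`readMethylation`,
  `inverseNormalize`, `buildGeneIndex`);
* batch correction by PCA on a random 10% site subset, 20 leading
  components, consumed either by residualization or as covariates
  (`fitPCs`, `residualize`);
* kernel construction `K = D^{-1/2} Z Z' D^{-1/2}` from standardized site
  vectors (`standardizeSites`, `buildKernel`, `kernelScan`);
* profiled maximum-likelihood fitting with exact boundary solutions
  (`fitVarComp`, `fitNullAndFull`, `vcLogLik`);
* genome-wide gene scan, mixture p-values, Bonferroni threshold, per-site
  heritability scan, Manhattan/Q-Q exports (`geneScan`, `mixturePvalue`,
  `siteH2Scan`, `exportPlotData`);
* a family-structured synthetic-data generator with known ground truth
  (`simulateDataset` and friends) and an end-to-end `runPipeline()` plus a
  thin CLI at `inst/scripts/methylvc`.

## Worked example

Simulate a desk-scale family cohort (40 nuclear families, 200 samples,
1000 CpG sites on 50 genes) in which gene `G010`'s methylation explains 25%
of the trait variance, then scan all genes:

```r
library(methylVC)

sim <- simulateDataset(seed = 42, traitHmeth2 = 0.25, causalGenes = "G010")
sim$ped
#> Pedigree with 200 individuals, 80 founders in 40 families

res <- geneScan(sim$trait, as.matrix(sim$covariates), sim$phi2, sim$kernels,
                annotation = sim$annotation)
res[order(res$p_value)[1:3],
    c("gene_id", "n_sites", "lrt", "p_value", "h_meth2", "h_r2_full")]
#>  gene_id n_sites   lrt  p_value h_meth2 h_r2_full
#>     G010      16 44.77 1.11e-11  0.3068     0.141
#>     G028      15  6.74 4.71e-03  0.1097     0.290
#>     G041       8  3.39 3.27e-02  0.0461     0.324

attr(res, "n_tests"); attr(res, "threshold")
#> 50          # converged gene tests
#> 0.001       # Bonferroni bar: 0.05 / 50
```

The causal gene tops the scan with LRT = 44.8 and p = 1.1e-11, far below
the Bonferroni threshold of `0.05 / 50 = 1e-3`; its fitted `h_meth2 = 0.31`
is the fraction of trait variance attributed to the kernel (true value
0.25), with the polygenic fraction dropping accordingly. The two runners-up
are null genes at p > 4e-3. A per-site heritability scan of the same data
(`siteH2Scan(sim$methNorm, sim$phi2)`) returns a mean h2 of 0.184 against a
simulated truth of 0.2 — the slight attenuation is the rank-normalization
cost.

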