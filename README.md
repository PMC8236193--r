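# mcpca

Nonlinear dimension reduction for inferring **population structure
from low-coverage sequencing data**.

Below roughly 5x coverage, hard genotype calls are unreliable and the
honest representation of a genotype is its **dosage** — the posterior
mean minor-allele count, `DS = Pr(1 | Data) + 2 Pr(2 | Data)`,
continuous on [0, 2].  Linear PCA on dosages leaves structure on the
table because the informative recoding of a dosage is not linear
(for a rare allele, almost all of the signal is heterozygote vs major
homozygote).  This package implements **maximally correlated PCA
(MCPCA)**: discretize each SNP's dosages into a few ordered
categories, then find per-SNP standardized transformations
φ<sub>j</sub> maximizing the **Ky Fan q-norm** of the transformed
covariance matrix,

> maximize  Σ<sub>r=1..q</sub> λ<sub>r</sub>(**K**<sub>φ</sub>),  
> where  **K**<sub>φ</sub>(j, j′) = E[φ<sub>j</sub>(x<sup>j</sup>) φ<sub>j′</sub>(x<sup>j′</sup>)],  E[φ<sub>j</sub>] = 0,  E[φ<sub>j</sub>²] = 1,

by block coordinate descent.  PCA is the affine special case, so the
MCPCA objective always dominates PCA's top-q eigenvalue sum on the
same data; `objective / p` is the explained-variance fraction for
both.  The optimized q-dimensional sample embeddings (MCPCs) are what
you cluster or plot.

For whom: population geneticists and methodologists working with
genotype likelihoods (ANGSD Beagle-GL output, VCF GP/PL/DS), dosage
matrices, or simulation studies of low-coverage designs.

## What's inside

| area | functions |
| --- | --- |
| I/O | `read_beagle_gl`, `read_vcf_genotype_probs`, `write_scores`, `phred_to_error` |
| dosage | `posteriors_from_likelihoods` (HWE/uniform prior), `dosage_from_posteriors`, `maf_filter` |
| discretization | `fd_bin_count` (Freedman–Diaconis), `equal_width`, `equal_frequency`, `jenks` (exact DP), `discretize_matrix` |
| core | `fit_mcpca`, `kyfan`, `transformed_covariance`, `standardize_transform`, `explained_fraction` |
| baselines | `pca`, `kpca` (polynomial kernel) |
| simulation | `sim_config`, `sim_low_coverage`, `sim_admixed_genotypes`, `sim_depths`, `sim_quality`, `perturb_genotypes`, `sim_reads`, `likelihoods_from_reads`, `sim_two_group_nonlinear`, `parse_ms_output` |
| CLI | `inst/exec/mcpca` with `simulate`, `fit`, `report` subcommands |

## Worked example

Simulate three admixed populations sequenced at mean depth 2x, carry
the genotype likelihoods through dosage, discretize with Jenks natural
breaks, and fit MCPCA with q = 2:

```r
library(mcpca)
cfg <- sim_config(n_per_pop = 30, p_sites = 800, mean_depth = 2, seed = 42)
sim <- sim_low_coverage(cfg, n_keep = 600)
mean(sim$error_mask)                    # 0.3203 — hard calls are 32% wrong
D   <- discretize_matrix(sim$DS, method = "jenks", m = "auto")
fit <- fit_mcpca(D, q = 2)
fit
#> mcpca_fit: p = 600 features, q = 2, objective = 117.0505 (explained fraction 0.1951)
#> 66 sweep(s), converged
pca(sim$DS, q = 2)
#> embedding (pca): 90 samples, q = 2, explained fraction 0.1034
km <- kmeans(fit$scores, 3, nstart = 10)
sum(apply(table(km$cluster, sim$pop), 2, max)) / 90   # 1 — populations recovered
```

At 2x coverage nearly a third of hard calls are wrong, yet the top two
MCPCs explain 19.5% of the variance — versus 10.3% for linear PCA on
the same dosages — and k-means on them recovers the three populations
perfectly.

The same pipeline from the shell:

```sh
inst/exec/mcpca simulate --out simdata --mean-depth 2 --seed 42
inst/exec/mcpca fit --input simdata/dosage.tsv --method mcpca \
    --discretize jenks --q 2 --out scores.tsv   # + scores.json report
```

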