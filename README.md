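# ialnet — SNP-gene regulatory network inference by iterative adaptive lasso

`ialnet` jointly infers a **directed gene regulatory network** and a
**per-gene eQTL assignment** from a gene expression matrix and a SNP
genotype matrix. It is aimed at systems-biology analyses where genetic
variants are used as perturbations to orient regulatory edges: SNPs may
regulate genes, genes may regulate genes, and SNPs are never regulated.
No eQTL mapping needs to be supplied — identifying each gene's eQTL is
part of the inference (each gene is assumed to be regulated by at most
one SNP).

## Model and method

Each gene's expression follows a sparse linear structural equation

```
y_i = b_i Y + f_i X + mu_i + eps_i ,      b_ii = 0
```

with `Y` (genes × samples) the expression matrix, `X` (SNPs × samples)
the genotype matrix coded `{1,2,3}` = minor-allele count + 1, `b_i` the
incoming gene-gene regulatory weights of gene *i*, and `f_i` its eQTL
weights. Rows are mean-centered, eliminating `mu_i`. Estimation runs in
three stages:

1. **Ridge + elastic-net screen** — per-gene closed-form ridge fits
   (penalties by 5-fold CV) initialize the coefficients; an elastic net
   with l2 on gene coefficients and l1 on SNP coefficients retains a
   small candidate eQTL set per gene.
2. **Lasso-path finalization** — a lasso on the combined gene/candidate
   regressors is traced along a decreasing penalty path; the candidate
   SNP whose coefficient becomes nonzero earliest is the gene's single
   eQTL.
3. **Iterative adaptive lasso** — the gene network is re-estimated by a
   weighted l1 fit whose penalty weights `|previous estimate|^(-alpha)`
   are recomputed from the latest coefficients before every pass;
   coefficients that hit zero are excluded permanently, and `alpha` is
   raised stepwise until the selected-edge count stops changing.

A known eQTL map can be supplied instead (mode `ial1`), in which case
only stage 3 runs on the given SNP support.

The package also ships the synthetic benchmark generator used to
characterize the method (random acyclic networks, coefficients uniform
on ±[0.5, 1], one eQTL per gene, genotypes 0.25/0.5/0.25, Gaussian noise
variance 0.01) and TPR/FDR structure-recovery scoring, so its operating
characteristics are fully reproducible. See the methods vignette
(`vignettes/ial-methods.Rmd`) for the algorithmic details and design
notes.

## Worked example

```r
library(ialnet)

sim <- sgrn_simulate(sgrn_sim_config(n_genes = 10, n_samples = 100,
                                     edges_per_gene = 2, seed = 7))
print(sim)
#> Simulated SGRN dataset: 10 genes/SNPs, 100 samples, 24 true gene edges, Eg = 2, seed = 7

fit <- ial(sim$Y, sim$X, ial_config(mode = "ial2", seed = 7))
print(fit)
#> SGRN fit (IAL2): 10 genes, 10 SNPs
#>   gene-gene edges: 24; eQTL assignments: 10 (of 10 genes)
#>   outer iterations: 5 (termination: no_change), inner passes: 16

m <- structure_metrics(support_indices(sim$model$B),
                       fit$stage_supports$final_b,
                       b_slot_universe(10))
print(c(TPR = m$tpr, FDR = m$fdr))
#> TPR FDR
#>   1   0
```

The fit recovered all 24 true regulatory edges with no false positives
(TPR 1, FDR 0) and assigned the correct eQTL to every gene, starting
from a first pass that selected ~80 edges and pruning them away over
five weight-exponent rounds. `fit$B` and `fit$F` hold the final
coefficient matrices, `fit$eqtl` the per-gene SNP assignments with path
diagnostics, and `fit$trace` the per-iteration edge counts.
`write_network()` exports edge lists or SIF; `read_expression()`,
`read_genotypes()` and `read_genotypes_vcf()` import TSV/VCF data. A
command-line interface with `simulate` / `infer` / `evaluate` /
`benchmark` subcommands is installed at
`system.file("cli", "ialnet.R", package = "ialnet")`.

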