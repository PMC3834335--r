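# fmcnet

Microbial co-occurrence networks and functional microbial communities
(FMCs) from genus-level 16S abundance tables.

Mucosal and faecal microbiome surveys report genus counts that are
*compositional*: each sample's reads sum to the sequencing depth, so naive
correlations between taxa are distorted by closure. `fmcnet` implements an
end-to-end workflow for finding reproducible, disease-associated community
structure in such data:

1. **SparCC-style correlation inference.** Pairwise basis correlations
   ρ<sub>ij</sub> between genus abundance profiles are estimated from the
   log-ratio variances t<sub>ij</sub> = var log(x<sub>i</sub>/x<sub>j</sub>)
   under a sparsity assumption, with Dirichlet (+1 pseudocount) resampling
   of the counts to handle zeros, iterative exclusion of strongly
   correlated pairs, and median aggregation across resamples.
2. **Signed weighted network.** The soft threshold
   a<sub>ij</sub> = (0.5 + 0.5 ρ<sub>ij</sub>)<sup>β</sup>, default β = 4
   (the scale-free topology criterion is available via
   `pick_soft_threshold()`), maps co-occurrence to 1 and co-exclusion to 0.
3. **Modules (FMCs).** Genera are clustered by average linkage on the
   topological overlap dissimilarity 1 − TOM and the dendrogram is cut
   with a dynamic branch decomposition; modules are colour-labelled
   (largest = turquoise), unassigned genera are grey.
4. **Module summaries.** Each module is summarised by its eigengenus
   (first principal component of the standardized member profiles),
   member kME values (intramodular connectivity), Pearson module–trait
   correlations, per-genus ANOVA differential abundance with BH-FDR, and
   a Welch t-test for hub enrichment of disease-associated members.
5. **Cross-dataset preservation.** The permutation Z-summary statistic
   (median of four density Zs and three connectivity Zs, averaged)
   quantifies whether a module found in one cohort reappears in another;
   Z < 2 none, Z > 5 moderate, Z > 10 strong preservation.
6. **Classification.** Nearest shrunken centroids on genus-region or
   FMC-region features with leave-one-out cross-validation (folds =
   subjects; a subject is correctly classified when the cross-validated
   probability of its true class exceeds 50%).
7. **Synthetic cohorts.** A compositional count generator with planted,
   hub-graded modules, diagnosis effects and paired reference/test
   datasets makes every stage testable without sequencing data.

## Worked example

```r
library(fmcnet)

scenario <- fmc_scenario(n_genera = 80, module_sizes = c(12, 25), r_in = 0.7,
                         n_subjects = c(control = 16, UC = 8, CD = 8),
                         seed = 7)
sim <- simulate_fmc(scenario)                    # counts + metadata + truth
fit <- fmc_network(sim$table, sim$metadata, seed = 11,
                   min_reads_per_sample = 0, drop_singletons = FALSE)
print(fit)
#> Co-occurrence network fit: 80 genera x 96 samples, beta = 4
#>   SparCC rho range: [-0.509, 0.761]
#> Module assignment: 2 module(s) over 80 genera (44 unassigned)
#> turquoise      blue
#>        24        12

round(fit$traits$correlation[, c("control", "UC", "CD", "IBD")], 2)
#>           control    UC    CD   IBD
#> turquoise    0.51 -0.10 -0.50 -0.51
#> blue        -0.18 -0.17  0.39  0.18
```

The two planted communities are recovered (24 and 12 genera; the rest
grey). The generator depressed the large module in IBD and elevated the
small one in Crohn's disease, and the eigengenus–trait correlations show
exactly that: the turquoise FMC tracks health (r = 0.51 with control,
−0.51 with IBD) while the blue FMC is CD-associated (r = 0.39,
p = 9×10⁻⁵). Downstream, `module_preservation()` checks whether the same
communities exist in a second cohort, and `nsc()`/`nsc_loocv()` turn
genus-region features into a disease classifier.

A shell front end covers the same stages:

```sh
Rscript inst/scripts/fmcnet discover --config config.yaml --seed 1 --out out/
Rscript inst/scripts/fmcnet preserve --seed 1 --out out/
```

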