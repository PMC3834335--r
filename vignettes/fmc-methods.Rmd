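---
title: "Functional microbial communities from compositional abundance data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional microbial communities from compositional abundance data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmcnet)
```

This vignette documents the statistical models behind `fmcnet`, the
parameters that matter, the numerical conventions, and the places where a
design was genuinely open and a choice had to be made. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The problem

16S surveys of the gut mucosa report genus read counts per sample. Reads
are a fixed-size multinomial draw, so the observed fractions live on a
simplex: if one taxon blooms, every other fraction falls. Correlations
computed directly on fractions therefore confound genuine ecological
co-occurrence with closure artefacts. `fmcnet` estimates *basis*
correlations (correlations of the unobserved absolute abundances),
assembles them into a signed weighted network, extracts modules of
co-occurring genera — functional microbial communities, FMCs — and asks
two downstream questions: are the modules associated with disease state,
and do they replicate in an independent cohort?

## Sparse compositional correlation

For fractions $f_i$ the statistic $t_{ij} = \mathrm{var}\,
\log(f_i/f_j)$ decomposes as $t_{ij} = \omega_i + \omega_j - 2\rho_{ij}
\sqrt{\omega_i \omega_j}$, where $\omega_i$ is the basis variance of
taxon $i$. Under sparsity (most pairs uncorrelated) the row sums of $t$
give a linear system for $\omega$,

$$\textstyle\sum_{j \ne i} t_{ij} \approx (D-2)\,\omega_i + \sum_j \omega_j,$$

solved directly; $\rho_{ij}$ follows from the decomposition. Strong pairs
violate sparsity, so the pair with the largest $|\rho|$ above
`exclusion_threshold` (default 0.1) is removed from the system and the
variances re-solved, up to `max_exclusion_rounds` (default 10) times; a
genus is never reduced below two partners, which would make the system
singular. Zeros are handled by drawing each sample's fractions from the
Dirichlet posterior with a unit pseudocount (concentration = count + 1);
the estimate is aggregated over `n_resamples` (default 20) resamples by
the element-wise median, which is robust to the occasional degenerate
re-solve (a mean is available by flag). Negative $\omega$ estimates are
floored at $10^{-10}$ with a warning and $\rho$ is clipped to $[-1, 1]$.
Defaults follow the conventional settings of the estimator; they are not
data-tuned.

The guard requiring at least 4 genera reflects the degeneracy of the
sparsity approximation at smaller dimension. Log-ratio variances
themselves only need two samples (a variance with $n-1 = 1$); estimates
at such sizes are of course noisy.

## Network, topological overlap, modules

The signed transform $a_{ij} = (0.5 + 0.5\rho_{ij})^\beta$ with default
$\beta = 4$ maps co-exclusion ($\rho \to -1$) to adjacency 0 — a signed
convention throughout. For other datasets `pick_soft_threshold()` scores
each candidate power by the scale-free fit: connectivities are binned
into ~10 equal-width bins and $\log_{10} p(k)$ regressed on $\log_{10}
k$; the signed index $-\mathrm{sign}(\text{slope}) \cdot R^2$ should
exceed `r2_cut` (default 0.8). Equal-width binning is deliberate:
equal-count bins would make $p(k)$ constant by construction and the fit
meaningless.

The topological overlap measure

$$\mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}}$$

counts shared weighted neighbours and is the clustering similarity;
genera are clustered by average linkage on $1 - \mathrm{TOM}$.

**Module detection.** A single global height cut cannot, in general,
separate a tight module that attaches to the tree *below* the
background's internal merge heights — on planted data the module branches
are exact subtrees yet join their parents within a few thousandths of the
background merges. `detect_modules()` therefore decomposes branches:

* every subtree with at least `min_module_size` genera below the height
  ceiling (default 0.995 × the maximum merge height) is scored by its
  *separation* — mean dissimilarity to the rest of the network minus mean
  within-branch dissimilarity. Separation peaks at coherent, distinct
  branches: sub-branches lose it (their complement contains the rest of
  their own module) and supersets dilute cohesion;
* branches whose separation reaches `deep_split`-controlled fraction
  (0.20/0.10/0.05/0.025 of the dissimilarity spread for `deep_split`
  0–3; default 2) are candidates, accepted greedily by size-weighted
  separation (exponent 0.75 — large enough to prefer whole branches over
  tight sub-cliques, small enough not to reward loose supersets);
* accepted modules that are not mutually separated are merged, and
  unassigned genera whose affinity to their closest module is within
  three separation thresholds of that module's internal cohesion are
  attached to it.

Everything else stays grey. Labels are deterministic (ties break on the
lowest genus index); module colours follow the canonical order with
turquoise the largest. A structureless network yields one
all-encompassing module or only grey genera, never a crowd of small
spurious ones. `min_module_size` defaults to 5, the smallest community
size the package is designed to resolve.

## Eigengenus, kME, trait associations

Genus profiles are transformed to $\log_{10}(\text{fraction} + 10^{-6})$
before summarisation (options: raw fractions or ranks); compositional
abundance distributions are skewed over orders of magnitude, and a
principal component of raw fractions would be dominated by the few most
abundant taxa. Per module, member profiles are standardized across
samples and the first right singular vector taken as the eigengenus,
oriented to correlate non-negatively with the module's mean standardized
profile (sign of the first non-zero entry decides exact ties, e.g. a
two-genus module with profiles $x$ and $-x$). Variance explained is
$d_1^2 / \sum d_k^2$. Zero-variance members are dropped from the
computation with a warning.

kME is the Pearson correlation of each genus with each eigengenus; a
module's hubs are its high-kME members, and `hub_enrichment_test()`
compares the kME of flagged (e.g. disease-enriched) members against the
rest by a Welch $t$-test — Welch everywhere a $t$-test is named, since
equal variances are never guaranteed. Diagnosis enters trait correlations
as three one-vs-rest indicators plus a combined IBD indicator; the five
colon regions are coded ordinally 0–4 from cecum to rectum (the package
codes five regions 0–4; descriptions that count "0 to 5" over five
regions are off by one); collection site is an indicator. Module–trait
associations are Pearson correlations with two-sided $p$ from the $t$
distribution on $n-2$ degrees of freedom; constant traits are flagged,
not errors. Differential abundance uses one-way equal-variance ANOVA per
taxon with Benjamini–Hochberg correction; a taxon with zero variance gets
$F = 0$, $p = 1$ by convention, logged rather than dropped.

## Module preservation

`module_preservation()` recomputes correlation, adjacency and profiles
independently in a reference and a test dataset restricted to their
shared genera, then scores each reference module with four density
statistics (mean intramodular adjacency, mean intramodular correlation,
mean |kME|, proportion of variance explained — all in the test data) and
three connectivity statistics (cross-dataset correlations of intramodular
connectivity, of kME, and of the intramodular correlation entries). Each
statistic is standardized against `n_permutations` (default 100, minimum
20) random genus sets of the same size drawn uniformly from the shared
universe (grey genera included — the random-assignment null);
$Z_\text{density}$ and $Z_\text{connectivity}$ are medians of their
groups and $Z_\text{summary}$ their average. Thresholds: below 2 no
evidence, 2–5 labelled "weak" (the band is otherwise unnamed in common
usage), above 5 moderate, above 10 strong. Statistics with degenerate
null standard deviation are dropped from the median with a warning. The
full published statistic family is larger; this seven-statistic subset is
the part that drives the summary in the tens-to-hundreds-of-genera
regime, and the deviation is deliberate and documented.

One property worth knowing: when a single module contains most of the
genus universe, permutation-null sets consist mostly of that module's
members and the *connectivity* null becomes structured itself, deflating
$Z_\text{connectivity}$. The statistic is designed for universes with a
substantial unassigned background, which is how the package's tests
exercise it.

## Nearest shrunken centroids

Features are subject × "unit@region" matrices — relative abundances of
genera or eigengenus scores of modules, one sample per requested colon
region per subject; subjects lacking a region are excluded (matched
design, logged). With overall centroid $\bar x_i$, class centroids
$\bar x_{ik}$, pooled within-class standard deviations $s_i$, fudge
$s_0 = \mathrm{median}(s_i)$ and $m_k = \sqrt{1/n_k - 1/n}$, the
standardized differences $d_{ik} = (\bar x_{ik} - \bar x_i) / (m_k (s_i +
s_0))$ are soft-thresholded by $\Delta$; features with all-zero shrunken
differences are dropped. Prediction minimises $\delta_k(x) = \sum_i (x_i
- \bar x'_{ik})^2 / (s_i + s_0)^2 - 2 \log \pi_k$ with empirical class
priors by default (uniform available); posteriors are the softmin
$\exp(-\delta_k/2)$, and with every feature shrunk away prediction falls
back to the prior. Leave-one-out cross-validation refits per left-out
subject; a subject counts as correctly classified when the
cross-validated probability of its true class exceeds 50%, and the
reported $\Delta$ is the largest grid value achieving the minimum error
count (the most parsimonious optimum). Folds that lose a class in
training are excluded from the denominator with a warning. The shrinkage
presets 1.459 and 1.030 appear in the default pipeline grid alongside a
coarse sweep.

## The synthetic cohort generator

`fmc_scenario()`/`simulate_fmc()` emulate a colonoscopic lavage cohort:
64 subjects (32 control, 16 UC, 16 CD), three of five colon regions
sampled per subject (~192 samples), 263 genera in five communities of
sizes 5, 20, 40, 80 and 118, sequencing depth negative-binomial with mean
6909 truncated at a 3000-read floor. Latent log-abundances follow a
factor model: member $i$ of module $m$ has squared loading $r_i$ drawn
uniformly in `r_in` ± `hub_spread` (default 0.6 ± 0.2), so every module
carries an intramodular hub gradient, as real co-occurrence modules do —
without it, cross-dataset connectivity preservation would have no signal
to detect. Baseline log-abundances (SD `base_mean_sd` = 1.5, producing
realistic dominance skew) and the loadings are *law parameters* drawn
from the scenario seed; the call seed drives cohort sampling, factors,
noise, depths and counts. Two draws from one scenario are therefore
replicates of a single generative law — exactly what module preservation
probes. Disease effects shift module-member means in log units; the
default elevates the first module by +1 in CD and depresses the second by
1 in UC and CD, mirroring the signs typically reported for CD-associated
and health-associated communities. `simulate_fmc_pair()` produces
reference/test pairs as replicates, with permuted genus labels (structure
destroyed), or with one module's correlation zeroed (selective loss).

What the generator does *not* emulate: phylogenetic correlation between
related genera, overdispersion beyond the multinomial, region- or
subject-level random effects, and taxonomic misassignment between
cohorts. Passing tests therefore demonstrate the pipeline's correctness
and calibration under a clean compositional law, not performance on any
particular real cohort; with real data the taxonomies of the two cohorts
must be harmonized upstream, since genus identity for alignment is the
trimmed, case-folded label.

A note on closure: even with all correlations zero, log-fractions of
distinct genera are weakly negatively correlated (they share the
denominator), and a strong disease effect on one module induces a
genuine secondary co-variation block among the remaining genera. Both
phenomena are visible to the estimator because they are real features of
compositional data, and the test suite checks their expected magnitude
rather than pretending they do not exist.

## Numerical conventions and problem sizes

Degenerate inputs are handled explicitly: zero-total samples are errors
for normalisation; zero-variance genera are dropped (eigengenus), NA
(kME) or $p = 1$ (ANOVA); constant traits are flagged; all-zero
adjacency is an error; exact ties in module labelling break on the
lowest genus index. Every stochastic stage takes a seed and records it,
and the test suite asserts byte-identical reproduction. The simulation
scales used by the tests and the acceptance script — 150–300 genera,
84–180 samples, 100 permutations, 20-replicate power loops — were chosen
so the full suite completes in well under a minute per file while keeping
every planted-recovery margin wide; they are stated in the tests
themselves.

## Known limitations

* The sparsity assumption of the correlation estimator degrades when a
  large fraction of pairs is truly correlated; the exclusion heuristic
  mitigates but does not remove this.
* Module detection's separation threshold is relative to the spread of
  the TOM dissimilarities; datasets whose true modules are weaker than
  `deep_split` level 3 resolution will be left grey rather than guessed.
* The preservation null treats genera as exchangeable; strong
  phylogenetic structure in real data makes it anti-conservative.
* NSC assumes feature-wise class-conditional normality after
  standardization; relative abundances are heavy-tailed, and the
  classifier is used as a transparent baseline, not a performance
  ceiling.
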