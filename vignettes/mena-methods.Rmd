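---
title: "Random-matrix-theory molecular ecological networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-matrix-theory molecular ecological networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(menet)
```

## The problem

Amplicon surveys of soil bacterial communities produce OTU-by-sample
abundance tables. Beyond composition, ecologists want the *interaction
structure*: which taxa co-vary, how tightly the community is wired, which
taxa occupy topological key positions, and how the wiring relates to soil
physicochemistry (moisture, temperature, pH, conductivity, organic matter,
available P/K, nitrate and ammonium nitrogen). `menet` implements the
molecular ecological network analysis (MENA) approach: co-occurrence
networks whose similarity cutoff is chosen by random matrix theory (RMT)
rather than by an arbitrary correlation or p-value cutoff, followed by the
standard topology panel, Zi–Pi node-role classification, module eigengenes,
and community–environment linkage statistics.

The central entry point is the fitting function `mena()`, which takes an
`otu_table` (plus optional `sample_metadata`) and returns a classed fit
holding every stage; `run_pipeline()` applies it per sample group and
writes a report bundle.

## Preprocessing model

Per group the pipeline:

1. **Prevalence filter.** Keeps OTUs detected in at least `min_present`
   samples. Default is the absolute majority, `floor(n/2) + 1` (8 of 15
   for the motivating design). A fractional rule (e.g. 0.75) is available
   because both conventions circulate in the MENA literature; which to use
   is a study-level choice.
2. **Blank fill.** Remaining zeros are replaced by 0.01 so every cell is
   positive. Zeros at this stage are structural non-detections of otherwise
   prevalent taxa; the small constant keeps them ordered below every real
   detection on the log scale.
3. **log10 transform**, then **Pearson correlation** across samples. The
   similarity is |r|, with the sign kept separately so edges remember
   whether an association is positive or negative. Spearman is available
   but non-default: the method's convention is Pearson on log abundances.

Missing metadata values are never imputed; they are excluded pairwise in
downstream correlations.

## RMT threshold selection

The similarity matrix is truncated at a candidate cutoff (entries below it
zeroed, OTUs without any qualifying partner dropped). The nearest-neighbour
spacing distribution (NNSD) of the truncated matrix's eigenvalues
discriminates two universal regimes:

* **Poisson law** \(P(s) = e^{-s}\): uncorrelated eigenvalues, the
  signature of a system of independent (modular) blocks;
* **Wigner–GOE surmise** \(P(s) = \frac{\pi}{2} s\, e^{-\pi s^2/4}\):
  level repulsion, the signature of a strongly coupled random system.

Scanning the cutoff downward from 0.99, the selected threshold is the
smallest cutoff whose NNSD still fits Poisson at `alpha = 0.05` — below
it, noise couples the spectrum. For two-group comparisons a fixed common
threshold (0.81 by convention, the package default) keeps the groups
comparable, and `mena()` defaults to fixed mode for that reason; scan mode
is `threshold_mode = "scan"`.

### Numerical choices

* **Unfolding.** Spacings are comparable across matrices only after
  unfolding: eigenvalues are mapped through a smoothed cumulative spectral
  function so the mean spacing is 1. We fit a degree-5 polynomial
  (configurable) to the empirical CDF, reducing the degree automatically if
  the fit is non-monotone over the data range, and normalise the resulting
  spacings to exactly unit mean (polynomial CDF fits can over- or
  undershoot on heavy-tailed spectra, which would shift the whole spacing
  distribution).
* **Edge trim.** Polynomial unfolding is least reliable at the spectral
  edges, where CDF tail misfit can fabricate extreme spacings; 2% of
  spacings at each edge are discarded by default. The spacing laws are bulk
  properties, so this costs nothing statistically and makes the chi-square
  tests behave at their nominal levels (the package's calibration tests
  check exactly this).
* **Degeneracies.** Exact eigenvalue ties are split by deterministic
  increments below 1e-10 before unfolding; the unfolding model assumes a
  simple spectrum, and a deterministic split keeps runs bit-reproducible.
* **Binning.** The chi-square goodness of fit uses 20 equal-probability
  bins under the Poisson null, expected masses from the analytic CDFs, and
  automatic merging of bins with expected count below 1 (degrees of freedom
  adjusted).
* A spacing analysis needs at least 20 distinct eigenvalues; cutoffs whose
  truncated matrix is smaller are recorded as `NA` in the scan.

## Network topology

Metrics are computed on the unweighted skeleton — the reported panel
(degree, density, clustering, path lengths, transitivity, connectedness)
is count-based; weights are kept for export. Average path distance
averages over *reachable* pairs; geodesic efficiency averages \(1/d\) over
all pairs with \(1/\infty = 0\); connectedness is Krackhardt's fraction of
reachable pairs. The scale-free credibility figure is the R² of the
log–log OLS fit of the degree histogram; it needs at least 3 distinct
degrees. Modules come from greedy (CNM-style) modularity maximisation,
which is deterministic for a given graph; Newman's
\(Q = \sum_c (e_c/m - (d_c/2m)^2)\) scores the partition. Two module
counts are reported: all modules, and modules with more than five nodes
(the reporting rule used for module-level analyses such as eigengenes).
Leading-eigenvector detection is available as an alternative.

## Node roles

Within-module connectivity \(Z_i\) is the z-score of a node's link count
into its own module, using the *population* standard deviation (the
convention of the Guimerà–Amaral role taxonomy from which the thresholds
derive). Modules whose members all have equal within-degree (sd = 0,
including singletons) give \(Z_i = 0\): topologically equivalent members
are not hubs. Among-module connectivity
\(P_i = 1 - \sum_t (k_{it}/k_i)^2\). The role rule cuts at
\(Z_i = 2.5\) and \(P_i = 0.62\), with boundary values falling in the
\(\le\) branches: network hubs (> , >), module hubs (> , \(\le\)),
connectors (\(\le\) , >), peripherals otherwise.

## Module eigengenes and environment linkage

A module's eigengene is the leading left singular vector of the
samples-by-members matrix of standardized member profiles, computed on the
same filled, log10 table the network used, restricted to members. Its sign
is fixed against the module's mean profile, and the explained-variance
fraction is \(d_1^2 / \sum d_k^2\). Eigengene–environment association uses
Pearson correlation with t-distribution p-values; eigengene–eigengene
structure is summarised by average-linkage clustering on \(1 - r\),
exported as Newick.

The community-level link to each environmental variable is a Mantel test:
Bray–Curtis distance on relative abundances at the OTU level versus
Euclidean distance on the standardized variable, Pearson correlation of
the lower triangles, one-tailed permutation p with 999 seeded permutations
(\(p = (\#\{r_{perm} \ge r_{obs}\} + 1)/(B + 1)\)). One test per variable;
no partial Mantel. Group comparisons of soil properties use Student's
pooled t-test (Welch optional), and `ttest_from_summary()` reconstructs
the test from printed mean ± sd summaries when raw values are unavailable.

## Alpha diversity

Computed on raw counts, before the network's prevalence filter (the two
analyses answer different questions and the estimators need unfiltered
count data): Chao1 (classical form; bias-corrected variant when no
doubletons exist), ACE (classical formula, rare cutoff 10, Chao1 fallback
at zero coverage), Shannon in natural log (base toggle available), and
Simpson reported as dominance \(D = \sum p_i^2\) — smaller D means a more
even community — with \(1 - D\) also emitted. Rarefaction subsamples
without replacement at seeded depths; the hypergeometric closed form
`rarefaction_expected()` provides the analytic mean it estimates. NMDS
ordination of the Bray–Curtis matrix is delegated to vegan's engine
(classical-scaling start, isotonic refinement, seeded restarts) and
returns Kruskal stress-1.

## The synthetic-data generator

`generate_community()` emulates the study conditions every test runs
under: two groups of 15 samples, a few hundred OTUs, planted correlation
blocks, and environment variables wired to specific blocks.

* **Latent model.** log10 abundances are correlated Gaussians: mean 2, sd
  1 (`dispersion`), block-structured correlation with
  `within_module_correlation = 0.9` by default and 0 between blocks.
  Planting correlation on the log scale makes the planted structure the
  estimand of the Pearson-on-log10 pipeline; compositional effects are
  deliberately not modelled, as the analysed method ignores them too.
* **Zeros.** Cells whose latent values fall below the global
  `zero_inflation` quantile (default 0.2) become zeros — so zeros hit the
  low-abundance tail, the way non-detections do, and the 0.01 fill
  downstream confronts realistic structural zeros.
* **Environment.** A driven variable equals the driving module's mean
  latent profile times its strength (default 0.7) plus matched noise;
  defaults wire module 1 to temperature and module 2 to pH, and add
  group shifts (in sd units) to T, pH and ammonium so the group
  comparison has signal. The nine variable names follow the soil panel.
* Everything is reproducible from `seed`.

What passing tests on this generator do **not** show: robustness to
compositionality, sequencing-depth variation, overdispersion beyond
log-normal, or taxonomy-dependent structure. The generator validates the
pipeline's logic, not the biology of any particular soil.

A null generator (`generate_null_community()`) provides fully independent
OTUs. Under independence with 15 samples the exact two-sided tail
\(P(|r| \ge 0.80) \approx 3.4\times10^{-4}\) implies that a 200-OTU null
table still retains about 6% of OTUs as connected nodes at a 0.80 cutoff
— an honest false-positive floor of correlation thresholding at this
sample size; at 0.85 the retention drops below 5%. The package's null
tests check retention against this exact tail rather than against a round
number.

## Problem sizes and determinism

The validation suite uses synthetic communities of 40–120 OTUs and
spectral ensembles of dimension 400–625 (100 replicates for the
discrimination rates), 10 seeds for planted-module recovery, and 500
replicates of 999 permutations for Mantel calibration — sizes at which
every quantity of interest is stable yet the whole suite runs in minutes.
Every stochastic step (generation, permutations, jitter-free degeneracy
handling, NMDS restarts) is driven by explicit seeds; identical seeds give
byte-identical pipeline bundles.

## Known limitations

* Pearson-on-log10 inherits sensitivity to the fill constant for OTUs
  with many zeros; the prevalence filter bounds this but does not remove it.
* Polynomial unfolding can misbehave on strongly multimodal spectra
  (e.g. a few dense cliques): the CDF fit degrades and the scan records
  non-fits. Sparse modular matrices — the regime the method targets —
  behave well.
* Greedy modularity has a known resolution limit; small genuine modules
  may be merged. The leading-eigenvector alternative is provided.
* The Mantel test uses Pearson body correlation; rank-based variants are
  out of scope.
* Networks are built per group; no differential-network statistic is
  provided beyond side-by-side panels.
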