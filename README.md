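# menet — molecular ecological network analysis for microbial communities

`menet` builds and analyses microbial co-occurrence networks from OTU
abundance tables, for ecologists who want to compare the *interaction
structure* of communities (e.g. soils under two treatments) rather than
just their composition.

The core method is random-matrix-theory (RMT) threshold selection. From an
OTU table the pipeline computes, per sample group:

1. prevalence filtering, 0.01 blank filling, log10 transform, and the
   absolute Pearson correlation matrix |r| between OTU profiles;
2. a similarity cutoff, either fixed (0.81 by default, for cross-group
   comparability) or chosen by scanning cutoffs from the top and testing
   the nearest-neighbour spacing distribution (NNSD) of the truncated
   matrix's eigenvalues: the spectrum of a modular (noise-free) system has
   uncorrelated levels, P(s) = e^-s (Poisson), while noise couples it into
   the Wigner–GOE regime, P(s) = (π/2) s e^(-π s²/4); the selected cutoff
   is the smallest whose NNSD still fits Poisson at α = 0.05;
3. the network topology panel (total nodes/links, power-law R², average
   degree 2L/N, clustering, average path distance, geodesic efficiency,
   density, transitivity, Krackhardt connectedness, maximal degree),
   greedy-modularity modules and Newman's Q;
4. node roles from within-module connectivity Zi and among-module
   connectivity Pi = 1 − Σ(k_it/k_i)², cut at Zi = 2.5 and Pi = 0.62 into
   peripherals, connectors, module hubs and network hubs;
5. module eigengenes (leading singular vector of each module's
   standardized abundance submatrix), their correlation with environmental
   variables, and their hierarchy;
6. community–environment Mantel tests (Bray–Curtis vs. standardized
   variable distance, seeded permutations), group t-tests on soil
   properties, and alpha diversity (Chao1, ACE, Shannon, Simpson,
   rarefaction, NMDS).

A synthetic-data generator with planted correlation modules
(`generate_community()`) makes every stage testable against a known
ground truth.

## Worked example

```r
library(menet)

sim <- generate_community(synth_spec(n_otus = 100,
                                     module_sizes = rep(25, 4),
                                     seed = 1))
lc  <- names(sim$otu$group)[sim$otu$group == "LC"]
fit <- mena(otu_table(sim$otu$abundance[, lc]), threshold = 0.81)
fit
#> Molecular ecological network fit
#>   threshold: 0.81 (fixed)
#>   96 nodes, 619 links, 4 modules (Q = 0.686)
#>   roles: peripheral=96, connector=0, module_hub=0, network_hub=0
```

The fit recovers the four planted modules exactly (96 of the 100 OTUs
survive thresholding on this draw; adjusted Rand index vs. the planted
partition = 1), the modularity Q ≈ 0.69 reflects the strong block
structure, and no node exceeds the hub thresholds because within a planted
block all members are statistically exchangeable. `summary(fit)` prints
the full topology panel; `plot(fit, "zp")` draws the Zi–Pi role scatter.

Two direct checks of the panel metric definitions:

```r
average_degree(158, 273)   # 3.456
network_density(260, 388)  # 0.012
```

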