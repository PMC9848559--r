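# reswebr

Empirical food-web construction for freshwater communities, combining
gut-content analysis (GCA) with Bayesian stable-isotope mixing models
(SIA). The package targets ecologists who have per-taxon bulk δ13C/δ15N
tissue samples and fish gut-content compositions and want a reproducible
pipeline from raw samples to a quantitative predation matrix and its
network indices.

## The method

1. **Gut contents restrict the prey pool.** For each diet item *i*,
   frequency of occurrence FO_i and mean volumetric contribution VO_i are
   combined into the feeding index

   FI_i = (FO_i × VO_i) / Σ_j (FO_j × VO_j),

   and diet categories with positive FI map to candidate prey taxa.
   Consumers with fewer than four examined guts fall back to a
   literature-based pool.

2. **Isotope preparation.** Whole-body samples with C:N > 3.5 are
   lipid-normalised (δ13C′ = δ13C − 3.32 + 0.99·C:N); trophic enrichment
   factors are attached (generic 0.4 ± 1.3 ‰ for δ13C, taxon-group values
   for δ15N); isotopically indistinct taxa are pooled after per-isotope
   t-tests/ANOVA; an "unknown producer" basal node can be imputed from
   zooplankton signatures stepped down one trophic level.

3. **Bayesian mixing model.** Consumer signatures are modelled as a
   concentration-weighted mixture of TEF-adjusted sources with propagated
   source/TEF variance plus a residual SD per isotope, a flat Dirichlet
   prior on diet proportions, and half-Normal priors on residual SDs.
   Inference is adaptive random-walk Metropolis on ALR-transformed
   proportions: by default 30,000 iterations, 10,000 burn-in, four chains,
   thinning 10, with Gelman–Rubin convergence checks.

4. **Feasibility and pruning.** Consumers must sit inside Monte-Carlo
   simulated mixing polygons; sources whose posterior median falls below
   0.25/N are removed one at a time (lowest first, refitting after each
   removal, never violating the polygon constraint), with a replayable
   audit trail.

5. **Predation matrix and indices.** Renormalised posterior medians form
   the prey × predator matrix; `web_indices()` reports S, L, link density
   L/S, directed connectance L/S², basal/intermediate/top fractions, mean
   Pianka overlap and Levins niche breadth.

A synthetic-community generator (`simulate_community()`) with known true
diets provides the test surface for every stage and writes fixtures in the
same CSV dialects the deposited field data use.

## Worked example

```r
library(reswebr)
sim <- simulate_community(sim_config(seed = 1, diet_concentration = 2))
d <- file.path(tempdir(), "demo_in")
write_fixture(sim$truth, sim$isotopes, sim$guts, d)
res <- run_pipeline(pipeline_config(
  d, file.path(tempdir(), "demo_out"),
  settings = mcmc_settings(iterations = 6000, burn_in = 2000,
                           chains = 2, thin = 5),
  plot = FALSE, seed = 1))
round(unclass(res$matrix), 3)
#>         Consumer1 Consumer2 Consumer3
#> Source1     0.689     0.429     0.315
#> Source2     0.213     0.439     0.335
#> Source3     0.098     0.132     0.350
res$indices
#> Food web: S = 6, L = 9, link density 1.500, connectance 0.250
#> fractions basal/intermediate/top: 0.500 / 0.000 / 0.500
#> mean Pianka overlap 0.851, mean Levins B 2.473
```

Each matrix column is one consumer's estimated diet (posterior medians,
summing to 1); the true simulated diets for this seed are (0.61, 0.29,
0.10), (0.25, 0.50, 0.25) and (0.25, 0.31, 0.43), so entries are recovered
to within about a tenth — the mixing model's resolution at ten samples per
taxon. The index block reads: 6 taxa, 9 realised links, 1.5 links per
taxon, a quarter of all possible directed links realised, half the taxa
basal, half top, and substantially overlapping consumer diets.

The output directory additionally holds `predation_matrix.csv`,
`web_indices.csv`, per-consumer posterior summaries, the pruning audit
trail and a `manifest.json` sufficient to replay the run.

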