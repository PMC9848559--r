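---
title: "Methods: from gut contents and stable isotopes to an empirical food web"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from gut contents and stable isotopes to an empirical food web}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reswebr)
```

## What the package does

`reswebr` reconstructs quantitative freshwater food webs from two
complementary lines of evidence: what a fish *ingested* (gut contents) and
what it *assimilated* (bulk delta13C and delta15N tissue signatures). Gut
contents decide which prey are plausible; a Bayesian stable-isotope mixing
model decides how much each plausible prey contributes; feasibility and
pruning rules discipline each model; and the per-consumer posterior medians
are assembled into a prey-by-predator predation matrix summarised with
standard network indices. A synthetic-community generator with known true
diets makes every stage testable without any field data.

## Gut-content analysis

For each diet item $i$ of a species, `occurrence_and_volume()` computes the
frequency of occurrence $FO_i$ (fraction of guts containing the item; any
strictly positive volume counts, with no trace-amount cut-off) and the mean
volumetric contribution $VO_i$ (averaged over *all* guts, guts lacking the
item contributing zero — matching the deposited data's "mean proportion of
the total gut content volume" semantics, rather than a mean over occurring
guts only). The feeding index is their normalised product:

$$FI_i = \frac{FO_i \times VO_i}{\sum_j FO_j \times VO_j}.$$

`candidate_sources()` converts positive-$FI$ diet categories into a source
pool through a category-to-taxon map. The original analysis never published
its mapping, so the map is a required input here and results are sensitive
to it. Consumers with fewer than four examined guts (the conventional
minimum) are flagged and given a literature-based pool instead.

The category vocabulary is the twelve-column deposited layout (the ten
microscopy categories plus detritus and hirudinea), since that is the format
the data actually ship in.

## Isotope preparation

**Lipid normalisation.** Whole-body samples with C:N > 3.5 get the
arithmetic aquatic-animal correction
$\delta^{13}C' = \delta^{13}C - 3.32 + 0.99\,(C\!:\!N)$; the correction is
idempotent and never touches delta15N. The 3.5 gate means a small
discontinuity at the threshold (the formula's root sits near C:N 3.35),
which is the standard, accepted behaviour of this normalisation.

**Trophic enrichment factors.** delta13C uses the generic
$0.4 \pm 1.3$ permil; delta15N is taxon-group specific. The cited
taxon-specific values are not printed in the source publication, so the
package ships documented defaults (fish $3.4 \pm 1.0$, invertebrates
$2.5 \pm 1.0$, algal primary consumers $2.2 \pm 1.0$ permil) and accepts any
CSV/YAML lookup table; provenance is the user's responsibility.

**Pooling.** Phenotypically similar taxa are pooled to a higher taxonomic
level when they cannot be statistically separated: per isotope, a Welch
t-test (pairs) or one-way ANOVA (larger sets), pooling when $p \ge \alpha$
on *both* isotopes. The source description ("significant isotopic overlap
... p < 0.05") is ambiguous about the direction of the test; the
conventional reading (cannot separate, therefore pool) is the default, and
the literal reading is available as `rule = "pool_if_overlap"`. Pooling
relabels samples and never drops them.

**Source summaries and the unknown producer.** Sources are summarised as
arithmetic mean and $n-1$ SD; single-sample taxa are errors unless
whitelisted (the field exception for abundant but hard-to-isolate taxa such
as Copepoda), in which case the SD is floored at 0.5 permil — a zero SD
would make the mixing likelihood degenerate. Where a primary producer could
not be sampled, `make_unknown_producer()` imputes a basal node by stepping
the zooplankton signature down one trophic level (subtracting the TEF mean
per isotope); the cited practice implies the one-step subtraction rather
than a verbatim copy, and a zero TEF recovers the copy behaviour.

## The mixing model

For consumer sample $y_{jk}$ on isotope $k$, diet proportions $p$ and
concentrations $q_{ik}$:

$$\mu_k(p) = \frac{\sum_i p_i q_{ik} (\mu_{ik} + \Delta_{ik})}
                  {\sum_i p_i q_{ik}}, \qquad
  V_k(p) = \frac{\sum_i p_i^2 q_{ik}^2 (\omega_{ik}^2 + \tau_{ik}^2)}
                {(\sum_i p_i q_{ik})^2} + \sigma_k^2,$$

with $y_{jk} \sim N(\mu_k, V_k)$ — the process-error formulation in which
source and TEF variance propagate into the likelihood. Priors are flat
Dirichlet$(1,\dots,1)$ on $p$ (gut-content information enters only through
the source-pool restriction, never as an informative prior) and
half-Normal$(0, 10\,\text{permil})$ on each residual SD. Concentration
dependence is off by default ($q \equiv 1$); the deposited inputs carry
concentration columns, so the toggle exists.

**Sampler.** Adaptive random-walk Metropolis on the additive log-ratio
transform of $p$ and the log residual SDs, with the transform Jacobians in
the target density. A single block proposal per iteration is adequate in
the at-most-a-dozen-source problems this pipeline sees. The proposal scale
adapts in batches of 50 during burn-in toward an acceptance rate of about
0.2–0.4 and is frozen afterwards, so retained draws satisfy detailed
balance. Protocol defaults are 30,000 iterations, 10,000 burn-in, four
chains, thinning 10; each chain runs on its own stream derived from the
seed, so results are exactly reproducible. Convergence is checked with the
classic Gelman–Rubin potential scale reduction factor, flagging parameters
above 1.1.

**Initialisation and numerics.** Chains start at the uniform diet and at
the consumer data's per-isotope SD; a degenerate SD initialisation falls
back to 1 permil. The ALR transform keeps every stored draw exactly on the
simplex; summaries renormalise the per-source medians (raw medians are also
reported, and the two differ only at the third decimal in practice).

**Test oracle.** `grid_posterior_oracle()` integrates the exact
unnormalised posterior on a simplex lattice crossed with a residual-SD
grid. Because the likelihood factorises over isotopes and each residual SD
touches one isotope only, the SD grid is marginalised per isotope before
combining, which keeps a 3-source lattice cheap. Halving the default grid
step moves posterior means by well under 0.005; the sampler and the oracle
agree to better than 0.02 on two-source problems.

## Feasibility, pruning, assembly

**Mixing polygons.** Per Monte-Carlo iterate, each source's TEF-adjusted
mean is resampled from $N(\mu + \Delta, \sqrt{\omega^2 + \tau^2})$, a
convex hull is formed, and each consumer point is tested for containment
(boundary inside). A consumer passes when the mean per-sample
inside-probability reaches 5% — the simulated-polygon convention, exposed
as a parameter, with a per-mean mode available. Two-source and collinear
geometries degrade to a distance-to-segment test (default tolerance 0.5
permil).

**Pruning.** The threshold is $0.25/N$ for the current source count $N$.
After each fit, below-threshold sources are candidates; the single lowest
is removed — provided the reduced pool still passes the polygon check,
otherwise it is restored and protected — and the model is refitted before
the next decision, because the threshold itself depends on $N$. The loop
refuses to go below two sources, and every decision lands in an audit trail
that can be replayed (`replay_audit()`) to reproduce the final summary
exactly.

A caution worth stating: with two isotopes and four or more sources the
diet simplex has a null-space direction, so a source that contributes
nothing can still retain a posterior median near 0.1 when its signature can
be traded off against the others. Pruning identifies truly unimportant
sources only when the geometry makes them identifiable; the package's
planted-zero demonstrations are constructed that way deliberately.

**Predation matrix.** One column per consumer holding renormalised
posterior medians over its surviving sources; absent links are exact
zeros; consumers eaten by other consumers appear as rows as well, so
fish-to-fish links are representable. Columns with any positive entry must
sum to 1 within 1e-6.

## Network indices

With $S$ nodes (union of rows and columns) and $L$ links (entries above the
threshold, default any positive entry): link density $L/S$; directed
connectance $L/S^2$ (the dominant convention for such matrices;
$L/[S(S-1)]$ is available). Nodes with no prey are basal — isolated nodes,
which pruning can create, count as basal — nodes with prey and no predators
are top, the rest intermediate. Pianka's overlap is the cosine-like
similarity of diet columns; niche breadth is Levins'
$B = 1/\sum_i p_i^2$ with the standardised $B_A = (B-1)/(N_j-1)$ reported
alongside, the natural choices when only diet proportions are available.

## The synthetic generator

`simulate_community()` emulates the study conditions end to end: source
signatures drawn uniformly on delta13C $[-34, -18]$ and delta15N
$[0, 12]$ permil (the spread of basal resources and prey in tropical
lentic systems), within-source SD 1 permil, TEFs $0.4 \pm 1.3$ (delta13C,
the generic literature value) and $3.4 \pm 1.0$ permil (delta15N, fish),
residual SD 0.5 permil, Dirichlet true diets, and ten tissue samples and
ten guts per taxon. Within-taxon isotope SDs are not published for the
original systems; 0.5–1.5 permil is the realistic range and 1 permil the
default, exposed in the configuration. All draws come from one seeded
stream in documented order (source means, then diets, then source samples,
then consumer samples, then guts), so fixtures are byte-identical across
runs.

Per-gut compositions are Dirichlet draws centred on the true diet with
precision `diet_concentration * n_items`; items are then dropped from a
gut with probability 0.3 and the rest renormalised, so frequency of
occurrence genuinely differs from volumetric contribution. Note the drop
step biases the *expected* composition slightly toward the items that
remain; the mean-composition-equals-diet property holds exactly only with
the drop probability at zero, which is how it is verified.

The reference recovery problem (`reference_community()`) uses three
well-separated, non-collinear sources and a true diet of
$(0.7, 0.2, 0.1)$ with 30 consumer samples — the situation the original
workflow engineers by pooling taxa into isotopically distinct units. What
passing recovery tests on this generator shows is that the inference
machinery is correct under its own forward model; it does not certify
performance on real communities with unmodelled tissue-turnover dynamics,
non-Normal source distributions, or misspecified TEFs.

## Problem sizes used in the test-suite and acceptance runs

The acceptance checks run the reference recovery at the full protocol
settings (30,000/10,000/4 chains). Elsewhere the suite scales simulations
to the smallest sizes that still exercise the property: 2,000–12,000
iterations and 2–3 chains for sampler properties, 50 replicate problems
for interval coverage, 500–4,000 Monte-Carlo iterates for polygon
probabilities, 1,000 replicates for the pooling null rate, and a
three-consumer community for the end-to-end pipeline. These sizes are the
package's own choices for a fast, deterministic suite.

## Known limitations

* Two isotopes only; no hierarchical or covariate mixing models, and no
  informative priors.
* The category-to-taxon map and the delta15N TEF table are inputs, not
  facts the package can supply; results are sensitive to both.
* Pruning inherits the identifiability caveat above.
* Excel inputs are not read directly; the pipeline dialect is CSV.
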