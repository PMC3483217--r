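---
title: "Predicting longevity genes from interaction networks and analyzing the screen that tests them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting longevity genes from interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longnet)
```

## The scientific problem

Genetic screens for lifespan regulators in *C. elegans* have never been
saturating: genome-wide RNAi screens verify long-lived phenotypes for well
under 1% of the genes they test, and they systematically miss genes that are
required for development, because inactivating those genes from hatching
arrests or kills the animal before adult lifespan can be measured.

`longnet` implements a network-based shortcut. Proteins work in complexes
and pathways, so the first-order protein–protein interaction (PPI) partners
of known longevity-associated genes (LAGs) are far more likely to modulate
lifespan than randomly chosen genes. The package builds *longevity
networks* from a PPI edge list and a core LAG list, quantifies whether the
core set is more interconnected than chance, selects untested essential
partner genes as candidates (including candidates transferred from a second
species through orthology), and then analyzes the post-developmental RNAi
screen that tests them.

## The longevity-network construction

Given an interactome graph $G$ (simple, undirected; self-loops and
duplicate edges removed at assembly) and a core gene set $C$:

1. keep the core genes with reported interactions, $C' = C \cap V(G)$;
2. add all first-order partners, $U = C' \cup N(C')$;
3. take the largest interconnected subgraph: the largest connected
   component, by node count, of the subgraph of $G$ induced on $U$.

Nodes of the result carry a role, `core` or `partner`. Two details of step
3 are genuinely open choices and are fixed as follows:

* **Induced semantics.** Partner–partner edges inside $U$ are retained. A
  "subgraph" over a chosen node set naturally means the induced subgraph,
  and partner interconnections are themselves informative.
* **Tie-breaking.** Equal-sized components are ranked by core-gene count,
  then by the lexicographically smallest sorted node list. Ties are
  essentially impossible in real interactomes but the rule makes the
  output a pure function of its inputs, which the regression tests rely
  on.

`coverage_fraction()` reports $|{\rm core\ retained}|/|C'|$ — the share of
interactome-present core genes that end up in one continuous network
(about 94% in the worm network this construction is modelled on).

## The interconnectivity statistic and its null

A member of a gene set is *interconnected* when it has at least one PPI
with a different member. `interconnectivity()` reports the fraction of
interactome-present members that are interconnected. Significance comes
from `permutation_null()`: draw random gene sets of the same size, where
"size" means the number of interactome-present members, because only those
can contribute edges, and compute

$$p = \frac{1 + \#\{\hat f_{\rm null} \ge f_{\rm obs}\}}{1 + n_{\rm perm}},$$

the add-one empirical p-value, which can never be zero and makes
"p < 0.001" exactly attainable at 1000 permutations.

The default null samples nodes uniformly. Uniform sampling is
anti-conservative for high-degree gene sets (hubs are interconnected more
often by chance alone), so a `degree_matched` mode is provided that samples
within ten degree-quantile bins; analyses should state which mode they
used. The package deliberately stops at degree and interconnectivity — no
diffusion scores or centrality beyond degree.

## Cross-species transfer and candidate selection

`map_gene_set()` pushes a gene set through a many-to-many orthology map
(InParanoid-style clusters). "Non-redundant" union is a plain set union by
canonical id: no best-hit collapsing, every cluster member kept, because a
collapse rule would add an arbitrary parameter with no biological
justification here. Unmapped genes are dropped from the result but always
enumerated in the mapping report, so transfer losses are auditable.
`build_cross_species_core()` applies the same logic to assemble a
native-plus-foreign core set with per-gene species provenance.

`select_candidates()` applies three criteria: membership in the worm
network's partner set or the worm-mapped partners of the human network;
absence from every supplied list of already-known LAGs; and essentiality
for development and growth (the antagonistic-pleiotropy filter — genes
essential early in life are enriched for late-life effects).
All three filters are set intersections/differences, so their order cannot
change the result; a filter trail records why each pool gene was excluded.
RNAi clone availability (`apply_clone_availability()`) is applied last as a
practical constraint, not a biological criterion. Candidates carry a
WLN-only / HLN-only / shared provenance partition whose counts always obey
inclusion–exclusion.

## Screen analytics

**Primary thrashing classifier.** Survival fractions are scored on days
15, 17, 19 and 21 of adulthood (at least 30 animals per condition). The
relative change versus control at each day is $(t - c)/c$; a record is
called `long` when at least 3 of 4 days change by at least +10% *and* no
day changes by −10% or worse, `short` symmetrically, otherwise `none`. The
opposite-direction veto is what "consistent" has to mean: plain 3-of-4
counting would call +25, +25, +25, −25 a long-lived phenotype. A day with
control fraction 0 has no defined relative change and is excluded from the
count; a record with all days indeterminate is an error, not a `none`.

**Longitudinal confirmation.** Kaplan–Meier product-limit curves
(`km_estimate()`, backed by the survival package) with the mean taken as
the area under the curve up to the largest event time — with no censoring
this is exactly the arithmetic mean of death ages. The two-group log-rank
test (`logrank_test()`) confirms a hit at p < 0.05; no multiple-testing
correction is applied across genes, matching the screen design this
replicates. Animals lost to bagging, rupture or wall deaths are treated as
right-censored at last observation.

**Effect measures.** `percent_changes()` reports the percent change of the
KM mean versus control, and of "maximum lifespan", defined as the mean age
at death of the longest-lived $\lceil n/4\rceil$ deaths per group — the
standard last-quartile reading, since no formula is otherwise canonical.
Both use uncensored deaths for the quartile and need at least 4 deaths per
group.

**Screen arithmetic.** Verification frequency is verified genes as a
percentage of *all genes screened* (not of retested genes).
`extrapolate_verified()` projects the confirmation rate onto untested
preliminary hits with a floor: $\lfloor\,{\rm preliminary}\times{\rm
verified}/{\rm retested}\,\rfloor$ — truncation, not rounding, is what
reproduces the published projections (e.g. $\lfloor 101 \cdot 19/45\rfloor
= 42$) and is the conservative choice for a count. All displayed
percentages use half-up rounding (5.0802 → 5.1), one decimal by default,
two on request, integers for detection rates; `round_half_up()` exists
because R's `round()` is half-to-even.

## The synthetic-data generator

`gen_world()` produces every pipeline input with known ground truth. What
it emulates, and what it does not:

* **Interactome**: scale-free preferential-attachment graph (heavy-tailed
  degrees like real PPI networks); Erdős–Rényi and configuration models
  are available for null comparisons. It does not emulate BioGRID's
  experimental-system metadata or study-specific ascertainment bias.
* **Planted core**: `plant_core_module()` raises the internal pair-density
  of a random $k$-set to a chosen multiple of the background density,
  emulating the elevated interconnectivity of real LAG sets. A boost of 1
  means "unchanged".
* **Orthology**: per-gene coverage with a tunable extra-paralog rate;
  real many-to-many cluster structure is richer.
* **Lifespans**: Gompertz mortality, shape 0.25/day and baseline hazard
  0.00095/day, giving a control mean lifespan of ~20 days and survival
  0.85/0.77/0.65/0.49 at the four scoring days — a realistic 20 °C assay
  window. Gompertz (rather than exponential) matters for the last-quartile
  statistic, which is sensitive to the right tail. A gene effect is an
  accelerated-failure-time factor: death times are multiplied, which stays
  within the Gompertz family and makes the expected percent change of mean
  lifespan equal to $100(f-1)$.
* **Thrashing**: binomial draws of 30 scored animals against the group's
  *true* model survival at each day, for both arms.

Defaults are fixed study conditions: 1000 genes, a 70-gene planted core at
4× density (which realizes roughly 100 screened candidates), 35%
background essentiality with 2-fold core enrichment, 70% orthology
coverage, 10% paralogy, 80% clone availability, 20 planted effect genes
alternating factors 1.3 and 0.7 (the clearly detectable end of verified
screen effects — a 5% effect is genuinely undetectable by a 10% threshold
assay, and planting undetectable effects would only measure the assay, not
the pipeline), 90 animals per longitudinal group, 5% censoring. A single
master seed spawns per-component child seeds through a fixed scheme
(`child_seed()`), so regenerating one input never perturbs the others.

Passing tests on this world show that the pipeline recovers planted
structure under its own model assumptions. They do not show robustness to
what real data add: false-positive/negative PPIs, correlated study bias,
id-mapping noise, non-Gompertz mortality, or batch effects between assay
replicates.

## Problem sizes and numerical choices

The shipped tests run the brute-force oracles on 200 random graphs of ≤10
nodes, calibrate the permutation p-value with 200 replicate draws at 199
permutations, test power on 50 replicates of a 20-gene module planted at
4× density in 200-node graphs at 999 permutations, and run the end-to-end
regression world at 1000 genes — sizes chosen so the whole suite completes
in well under a minute on one CPU while keeping every Monte-Carlo check at
a scale where its expected error is far from the asserted bound.

Degenerate inputs are errors, not warnings: empty edge files, cores with
no interactions, all-censored survival groups, all-indeterminate thrashing
records, and screen summaries violating verified ≤ retested ≤ preliminary
≤ screened all fail loudly at construction.

## Worked example

```{r example, eval = FALSE}
w <- gen_world(seed = 42, dir = "world")
cfg <- pipeline_config(
  edges = w$files$edges, core = w$files$core,
  orthology = w$files$orthology, hln_partners = w$files$hln_partners,
  essential = w$files$essential, known_lags = w$files$known_lags,
  clones = w$files$clones, lifespans = w$files$lifespans,
  thrashing = w$files$thrashing, out_dir = "out",
  n_permutations = 999, seed = 7)
pred <- run_predict(cfg)      # network + candidates + permutation p
scr  <- run_screen_stats(cfg) # phenotype calls + survival confirmation
mean(w$effect_genes %in% c(scr$verified_genes$long,
                           scr$verified_genes$short))
```

## Known limitations

* Interconnectivity is the only set statistic; no propagation or
  centrality scoring.
* The orthology generator mirrors ids one-to-one (plus paralogy); it does
  not simulate cluster-level ambiguity.
* The screen replicates a per-gene p < 0.05 rule with no multiplicity
  correction, by design; users wanting FDR control must apply it
  downstream.
* Real network node counts depend on the specific interactome and LAG
  releases used; the package checks the construction's properties, not any
  particular release's totals.
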