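---
title: "Co-occurrence network analysis of microbiome abundance tables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence network analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coocnet)
```

## The problem

Dietary interventions (prebiotics such as alginate oligosaccharides) alter
not only which gut taxa are present but how they co-vary. A standard way to
study this is to infer a **co-occurrence network** per treatment group from
a taxon-by-sample relative-abundance table — in practice, metagenome-assembled
genomes (MAGs) profiled across cecal samples — and compare the groups'
network topology: clustering, path lengths, modular structure, and the
topological roles of individual taxa. `coocnet` implements this arm as a
reusable, seeded, fully tested pipeline, plus a synthetic community
generator that plants known structure so every stage can be validated
against ground truth.

## Network inference

For each group separately, every taxon pair gets a **tie-aware Spearman
correlation**: the Pearson correlation of midranks (ties receive the mean of
the ranks they span). Two-sided P-values use the t approximation with
n − 2 degrees of freedom; with n = 16 samples per group, exact permutation
over all pair assignments is infeasible and the t approximation is the
standard choice. All C(p, 2) raw P-values of a group form one family and are
Benjamini–Hochberg adjusted together (the groups are built independently, so
each group is its own family).

An edge requires **both** criteria strictly:

* |rho| > 0.7 (a value of exactly 0.7 is excluded), and
* the selected P-value < 0.05.

The P-value used is the BH-adjusted one by default. The method literature
this rule comes from is ambiguous about whether the significance filter acts
on raw or adjusted P, so `network_config(use_adjusted_p = FALSE)` switches
to raw P; neither is asserted as "the" published choice. Edge sign is the
sign of rho. Taxa with no surviving edge are dropped from the node set by
default, which is why node counts in published networks fall below the taxon
count of the input table.

Constant taxa (common in sparse MAG tables) are retained with rho = 0 and
P = 1 rather than raising an error; they are reported in
`correlation_set$constant_taxa`.

## Topology and null models

Topology is computed on the **unweighted, sign-collapsed** graph; signs
survive only as edge attributes and in the positive-edge fraction. Reported
metrics:

* node clustering 2·triangles/(k(k−1)) for degree k ≥ 2, else 0; ACC is the
  mean over all nodes;
* APL as the mean shortest-path length over reachable ordered pairs
  (self-pairs excluded). Unreachable pairs are *excluded* rather than
  restricting to the giant component, so the metric stays defined on the
  fragmented, high-module-count networks this analysis produces; a graph
  with no edges reports APL as missing, never 0;
* diameter as the largest finite eccentricity;
* both E/N and 2E/N for "edges per node", because the two conventions
  differ by a factor of 2 and published figures do not always say which was
  used — the contrast table reports both and asserts neither;
* Newman modularity Q = Σ_c [e_c/m − (d_c/2m)²], with the partition found
  by seeded Louvain (`detect_modules`; greedy agglomeration available as an
  alternative). A network is called *modular* when Q > 0.4, the conventional
  criterion. Singleton components count as modules.

Observed metrics are compared against a **null ensemble** (default 1,000
replicates; tests and examples use 15–50 to keep runtimes in seconds). Two
null models are provided: degree-preserving Maslov–Sneppen rewiring (the
default — the stricter, standard ecological-network null; the degree
multiset is preserved exactly) and Erdős–Rényi G(n, m) with matching node
and edge counts. Per metric the ensemble mean, sd and
z = (observed − mean)/sd are reported; a degenerate null sd flags z as
undefined. The network is labeled "modular/small-world-like" when observed
ACC and Q both exceed their null means.

## Node roles (Zi–Pi)

With a partition fixed, each node gets:

* **Zi**, the within-module degree z-score: links into the node's own
  module, standardized by that module's mean and **population** standard
  deviation (the Guimerà–Amaral convention; with that convention a node of
  within-degree 5 in a module of mean 3 and sd 1 has Zi exactly 2). Modules
  with zero spread give Zi = 0.
* **Pi**, the participation coefficient 1 − Σ_s (k_is/k_i)²; 0 when all
  links are internal, and bounded by 1 − 1/K for a node touching K modules
  (so a connector cut of 0.62 is only reachable by nodes spreading links
  over at least three modules).

Classification uses zi_cut = 2.5 and pi_cut = 0.62. The network-role
methodology that microbial ecology cites uses these values; they are
exposed as parameters because published role assignments cannot be
reproduced without knowing the original cuts. Boundary ties go to the
hub/connector side (≥ on both cuts): module hub (Zi ≥ cut, Pi < cut),
network hub (both ≥), connector (Zi < cut, Pi ≥ cut), peripheral otherwise.
Module hubs and connectors are the candidate keystone taxa; the package
reports categories and leaves ecological interpretation to the analyst.

## Community metrics and associations

* Alpha diversity: Shannon in **nats** (the vegan convention), Simpson
  1 − Σp², inverse Simpson 1/Σp², richness. Rows not summing to 1 are
  auto-normalized with a notice.
* Bray–Curtis dissimilarity via `vegan::vegdist`; the matrix is exported
  for external ordination (PCoA/NMDS themselves are out of scope).
* Family-level indicator ratios (e.g. Lactobacillaceae to
  Enterobacteriaceae) after aggregating lineages at the family rank; a zero
  denominator is flagged infinite by default, with an optional pseudocount.
* Differential abundance: per-taxon two-sided Wilcoxon rank-sum tests
  (exact by enumeration when the combined sample is ≤ 20 and tie-free,
  tie-corrected normal approximation with continuity correction otherwise),
  BH-corrected over all taxa. Sidedness is not stated in the motivating
  analyses; two-sided is the conservative default. LDA-based effect-size
  scoring (LEfSe) is a separate published tool and is deliberately not
  reimplemented.
* Taxon–trait screening: Spearman with pairwise-complete handling of
  missing trait values (serum panels have sporadic missingness; per-pair n
  is reported), BH within each panel family — the taxon×trait rectangle and
  the trait×trait triangle are corrected separately, mirroring the two
  panels such screens are drawn as. A pair passes iff |rho| > 0.35
  (strict) and the selected P < 0.05 (strict).

## The synthetic generator

`generate_community()` draws a latent-Gaussian copula with log-normal
marginals: each planted block has one standard-normal factor per sample,
and a block member's log-abundance deviation is
√latent_corr · factor + √(1 − latent_corr) · noise. Per-taxon base
log-abundances are N(mu, sigma) with sigma = 2 by default, spreading taxa
over orders of magnitude as real relative-abundance data are. Everything is
exponentiated and **closed** (divided by the row sum). Defaults emulate the
motivating study design: 2 groups × 16 samples; 200 taxa is the desk-scale
default (the real catalogue had ~986 MAGs — scale is a parameter, and 200
keeps the full test suite under a minute).

Chosen over a Dirichlet construction because the within-block correlation
strength is then a single interpretable dial, which is what planted-recovery
testing needs.

What the generator does and does not emulate:

* Closure introduces the mild negative-correlation artifact real
  compositional data carry; it is accepted and visible in tests (mean
  off-diagonal rho is slightly negative under independence).
* Keystone taxa load √(latent_corr/K) on each of the K blocks they bridge
  (unit total variance). Their bridging signal — the sum of block
  factors — resembles the log-total that closure subtracts, so keystone
  correlations attenuate when block taxa dominate the composition; with
  ≥ 100 taxa the artifact is small. This is a real property of
  compositional data, not a generator bug, and it is why the package's
  validation of keystone behavior uses communities of at least 100 taxa.
* Traits are linear in the linked taxon's *relative abundance* plus
  Gaussian noise. Because log-normal abundances are heavy-tailed, a fixed
  absolute noise sd can represent anything from no noise to pure noise
  depending on the taxon's scale; meaningful noisy-coupling fixtures set
  the noise sd relative to the linked taxon's abundance sd.
* Not simulated: sequencing reads, MAG quality or completeness, phylogeny,
  dose–response kinetics, or group-dependent network rewiring. Passing the
  planted-recovery tests therefore demonstrates the *inference machinery*
  is correct, not that real cecal networks are recovered at n = 16 — at
  that sample size only correlations above roughly 0.7–0.8 survive the
  combined threshold, which is precisely the regime the method targets.

`generate_benchmark_graph()` supplies analytic oracles: two disjoint
cliques (clique partition has Q = 0.5), a ring of cliques whose dedicated
bridge nodes each link one member of three consecutive cliques (Pi = 2/3,
hence connectors at the default cut, while clique members stay below it),
and stochastic block models for partition-recovery checks.

## Determinism

Every stochastic operation draws from a seed passed explicitly or derived
deterministically from the pipeline's master seed (multiplicative-hash
sub-seeds kept below 2³¹). RNG state is restored after each seeded
operation, so package calls do not perturb a user's session RNG. Two
`run_pipeline()` invocations with the same config and seed produce
byte-identical JSON reports; the report validates against a versioned
schema shipped in `inst/extdata/`.

## Problem sizes in the shipped validation

Unit and acceptance tests run at deliberately small scale, chosen as the
smallest sizes at which each property is sharply testable: 10×10 random
tables for the Spearman oracle (1,000 replicates), 1,000 random p-vectors
for BH, 100 graphs for degree-preservation, 200 G(60, 300) replicates for
the ACC expectation, a 200-taxon/100-sample community for planted-block
recovery, a 200-taxon/16-sample independent community for the
false-positive control (the study's per-group n), and 15–50-replicate null
ensembles. The full suite runs in well under a minute on one CPU.

## Known limitations

* Correlation-based inference on compositions is biased toward negative
  associations; compositionality-corrected methods (SparCC, SPIEC-EASI)
  are explicitly out of scope. The strict |rho| > 0.7 threshold makes the
  surviving edges robust but conservative.
* P-values are t-approximations; for very small panels a seeded permutation
  test is the better tool and the approximation is the documented default.
* Louvain is stochastic across implementations; the same seed and igraph
  version reproduce partitions exactly, but different igraph versions may
  find different optima of equal or near-equal Q.
* Weighted or signed modularity is not implemented; topology deliberately
  collapses signs, matching how the motivating topological figures are
  defined.
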