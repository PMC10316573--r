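# coocnet

Seeded, tested co-occurrence network analysis for microbiome
relative-abundance tables: signed Spearman networks with
Benjamini–Hochberg control, topology against degree-preserving null
models, Louvain modularity, Zi–Pi keystone-role classification,
community-level diversity and differential-abundance statistics,
taxon–trait association screening, and a synthetic community generator
that plants known structure so every stage can be validated against
ground truth.

## The scientific problem

Feeding-trial microbiome studies (e.g. prebiotic supplementation in
broiler chickens) profile hundreds of taxa — typically
metagenome-assembled genomes — across a handful of samples per treatment
group, and ask not only *which* taxa shift but how the community's
co-variation structure changes. The standard analysis arm builds one
co-occurrence network per group and compares topology:

* edge rule: Spearman |ρ| > 0.7 **and** BH-adjusted P < 0.05 (both
  strict), edge sign = sign(ρ);
* topology: average clustering coefficient (ACC), average path length
  (APL) over reachable pairs, diameter, positive-edge fraction, compared
  with z-scores against a null ensemble (degree-preserving rewiring by
  default, Erdős–Rényi G(n, m) optionally);
* modularity: seeded Louvain; Newman Q = Σ_c [e_c/m − (d_c/2m)²];
  a network is called modular when Q > 0.4;
* roles: within-module degree z-score Zi (population-sd,
  Guimerà–Amaral convention) and participation coefficient
  Pi = 1 − Σ_s (k_is/k_i)²; quadrant cuts Zi = 2.5, Pi = 0.62 classify
  module hubs, connectors, network hubs, and peripherals — the first
  three are candidate keystones;
* community metrics: Shannon/Simpson/inverse-Simpson/richness,
  Bray–Curtis dissimilarity, family-level indicator ratios, per-taxon
  two-sided Wilcoxon rank-sum tests with BH correction;
* associations: taxon–trait Spearman screen passing at |ρ| > 0.35 and
  P < 0.05, with pairwise-complete handling of missing trait values.

All thresholds above are the package defaults and every one is a
parameter. See the methods vignette
(`vignettes/cooccurrence-methods.Rmd`) for conventions, rationale, and
limitations.

## Worked example

Generate a synthetic two-group community (2 × 16 samples, 200 taxa,
five planted blocks of 10 taxa at latent correlation 0.9), build one
group's network, and characterize it:

```r
library(coocnet)

spec <- synthetic_spec(module_sizes = rep(10L, 5), latent_corr = 0.9, seed = 42)
out  <- generate_community(spec)
tab  <- out$table

g1   <- tab$values[tab$groups == "G1", , drop = FALSE]
corr <- spearman_matrix(g1)
net  <- build_network(corr, network_config(), group_label = "G1")
net
#> cooc_network[G1]: 64 nodes, 201 edges

topo <- topology_summary(net)
sprintf("ACC %.3f, APL %.3f, diameter %d, positive edges %.0f%%",
        topo$acc, topo$apl, topo$diameter, 100 * topo$positive_fraction)

part <- detect_modules(net, seed = 7)
part
#> cooc_partition: 10 modules, Q = 0.804 (modular, Q > 0.4)

roles <- node_roles(net, part)
table(roles$role)
#> peripheral
#>         64

alpha <- alpha_diversity(tab)
round(tapply(alpha$shannon, tab$groups, mean), 3)
#>    G1    G2
#> 2.871 2.990

da <- differential_abundance(tab)
sum(da$p_adjusted < 0.05)
#> [1] 0
```

The numbers illustrate the method's behaviour honestly: the five
planted 10-taxon blocks surface as a 64-node network whose detected
partition is strongly modular (Q = 0.804 > 0.4); with only 16 samples
and the strict double threshold, nodes stay peripheral (dense small
modules give low within-module spread); and because the generator
draws both groups from the same distribution by default, the Wilcoxon
screen correctly finds nothing.

The full pipeline — both groups, null ensembles, roles, diversity,
differential abundance, optional traits, JSON report plus GraphML and
TSV exports — runs from one config:

```r
cfg <- run_config(abundance = "abundance.tsv", groups = "groups.tsv",
                  out_dir = "results/run1", seed = 1L)
run_pipeline(cfg)
```

A thin command-line wrapper with subcommands
(`simulate`, `network`, `roles`, `run`, …) ships in
`inst/cli/coocnet.R`.

## License

MIT.
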