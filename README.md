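# phona

Phenotype-OTU network analysis (PhONA) for amplicon microbiome data.

## The problem

Microbiome surveys routinely produce co-occurrence networks — nodes are
OTUs, edges are significant abundance associations — but a network alone
does not say which taxa matter for the host. `phona` anchors the
association network to a measured host phenotype (crop yield, disease
severity, any continuous trait), so that candidate taxa for synthetic
communities or biocontrol consortia can be read off the graph: OTUs
directly predictive of the phenotype, and OTUs indirectly tied to it
through their associations with the predictive ones. It is aimed at
microbial ecologists working from a rarefied OTU table, per-sample
metadata, and a per-sample phenotype.

## The method

Two models are fit per treatment/compartment subset and merged into one
graph:

1. **OTU-OTU associations (SparCC).** Counts are compositional, so
   correlations are estimated from log-ratio variances
   *t*<sub>ij</sub> = var log(*f*<sub>i</sub>/*f*<sub>j</sub>). Under a
   sparsity assumption the latent basis variances ω<sub>i</sub>² solve a
   linear system in the *t*<sub>ij</sub>, giving

   ρ<sub>ij</sub> = (ω<sub>i</sub>² + ω<sub>j</sub>² − *t*<sub>ij</sub>) / (2 ω<sub>i</sub> ω<sub>j</sub>),

   averaged over 20 Dirichlet(counts + 1) resamples, with iterative
   exclusion of strongly correlated pairs from the system. Edge
   significance comes from 500 bootstrap tables in which each OTU's
   counts are independently resampled over samples (association
   destroyed, marginals kept); pairs with |ρ| > 0.5 and p < 0.05 become
   signed edges.

2. **Phenotype-OTU links (lasso → GLM).** The phenotype is regressed on
   standardised relative abundances with an L1 penalty tuned by
   repeated 5-fold cross-validation (one-standard-error rule by
   default). The OTUs with nonzero coefficients are refit in an
   unpenalised Gaussian GLM; each selected OTU is linked to a single
   phenotype node with the sign of its GLM coefficient.

The merged graph is summarised (node degree = edges/nodes, density over
unordered pairs, negative/positive edge ratio), partitioned into modules
by simulated-annealing modularity maximisation, and each node receives
one of four roles from its within-module degree z and participation
coefficient P (thresholds z = 2.5, P = 0.62): peripheral, connector,
module hub, network hub. Supporting community statistics (richness and
Shannon entropy, Bray-Curtis + PERMANOVA, per-OTU negative-binomial
differential abundance with Benjamini-Hochberg FDR) are included, as is
a synthetic compositional data generator with planted ground truth used
throughout the tests. See `vignettes/phona-methods.Rmd` for the full
account.

## Worked example

Simulate a 60-sample, 30-OTU community with a planted OTU-OTU
correlation (pair 1-2, ρ = 0.8) and two planted yield drivers (OTU 1
positive, OTU 5 negative), then run the full analysis:

```r
library(phona)

cfg <- synth_config(
  n_samples = 60, n_otus = 30, depth = 3000,
  correlations = data.frame(i = c(1, 3), j = c(2, 4), rho = c(0.8, -0.7)),
  phenotype = list(otus = c(1, 5), betas = c(2, -2), sd = 0.5),
  seed = 11)
gen   <- generate_counts(cfg)
ph    <- generate_phenotype(gen$table, cfg)

assoc <- sparcc_association(gen$table, n_iterations = 20,
                            n_bootstraps = 200, seed = 12)
edges <- filter_associations(assoc, min_abs_rho = 0.5, alpha = 0.05)
edges
#>     otu_i   otu_j    weight     sign
#> 1 OTU_001 OTU_002 0.6698107 positive

model <- phenotype_model(gen$table, ph$y, n_repeats = 50, seed = 13)
round(model$glm_coefficients, 2)
#> OTU_005 OTU_001
#>   -2.04    1.86

g    <- build_phona(edges, model)
part <- detect_modules_sa(g, seed = 14)
network_attributes(g, n_modules = part$n_modules)[, 1:8]
#>   n_nodes n_edges node_degree density n_modules n_negative n_positive
#> 1       3       1         0.3    0.33         2          0          1
#>   neg_pos_ratio
#> 1             0
```

The planted correlated pair is the one edge surviving the |ρ| > 0.5,
p < 0.05 filter at this sample size (the weaker −0.7 pair does not),
and both planted yield drivers are recovered with the right signs and
near-true effect sizes. `node_roles(g, part)` classifies the three OTU
nodes (all peripheral in a graph this small), and
`write_phona_graph(g, "phona.graphml")` exports the annotated graph for
any GraphML viewer.

The same analysis runs end to end from a YAML configuration with
`run_pipeline(config, output_dir)` or from a shell via the bundled CLI:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "phona.R", package = "phona"))') \
    run --config config.yml --out results/
```

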