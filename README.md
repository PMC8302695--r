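# methanet

Constrained Bayesian-network inference for methanogenic communities:
who feeds electrons to the methanogens, and by which route?

Methanogenesis in engineered anaerobic systems runs on two competing
syntrophies: **interspecies hydrogen transfer** (IHT — fermenters and
*Geobacter*-like partners evolve H₂ that hydrogenotrophic methanogens
oxidize via the MvhADG/HdrABC complex) and **direct interspecies electron
transfer** (DIET — electrons pass through extracellular electron transfer
machinery such as *omc* cytochromes and conductive *pilA* pili, possibly
into methanogen *mvhB* polyferredoxins). `methanet` ranks the two routes
statistically: it learns a linear-Gaussian Bayesian network over multi-omic
feature tables under a tier blacklist that forces inference strictly from
fermentative bacteria/*Geobacter* over methanogens to CH₄ production,
validates the network by leave-one-out cross-validation, and then silences
IHT- or DIET-labelled genes in silico to measure how much predictive power
for methane production each mechanism carries.

The package is aimed at microbial ecologists and environmental engineers
working with 16S rRNA (gene) tables, MAG-derived gene expression (RPKM) and
reactor performance data.

## The method in brief

1. **Preprocess** — select the core population (mean relative abundance
   > 0.5 % and occurrence > 50 % across DNA + RNA samples), assemble one
   model matrix, min-max normalize each variable to [0, 1]:
   `v_norm = (v - min) / (max - min)`.
2. **Learn** — greedy hill climbing on the Gaussian BIC score
   `Σ_v [ logLik_v − (|pa(v)|+2)/2 · ln n ]` under blacklist/whitelist
   edge constraints; maximum-likelihood parameters per family (OLS,
   residual variance RSS/n).
3. **Validate** — leave-one-out cross-validation; Bray–Curtis similarity
   `1 − Σ|u−v|/Σ(u+v)` of reconstructed communities against an
   average-abundance null model; squared Pearson R²; relative RMSE
   `sqrt(mean((y−t)²))/max(y)`.
4. **Knock out** — set the expression of a mechanism's genes to 0, rerun
   the whole pipeline, and compare R² for CH₄ prediction across scenarios
   (complete, ΔIHT, ΔDIET).

A seeded synthetic-data generator (linear-Gaussian structural equation
model over the fermenter → *Geobacter* → methanogen → CH₄ cascade, plus
compositional community tables) makes every stage testable without
sequencing data.

## Worked example

```r
library(methanet)

# a synthetic study at the default conditions: 24 samples, strong hydrogen
# path (0.8) vs weak direct path (0.2)
cfg <- pipeline_config(seed = 3, scenario = list(n_samples = 200))
sem  <- build_template_sem(cfg$scenario)
expr <- simulate_expression(sem, 200, seed = 11)

nrm <- minmax_normalize(expr)$table
bl  <- build_blacklist(nrm)              # tiers -> forbidden edge set
run_knockout_experiment(nrm, bl, output_var = "ch4_production")
#>     scenario    mode  method r_squared relative_rmse delta_r_squared
#> 1   complete retrain parents 0.9859166    0.02297373      0.00000000
#> 2  delta_IHT retrain parents 0.4700167    0.14094222     -0.51589994
#> 3 delta_DIET retrain parents 0.9722975    0.03221796     -0.01361914
```

Reading the output: with all genes present the network predicts methane
production almost perfectly (R² ≈ 0.99). Silencing the hydrogen-metabolism
genes (ΔIHT) collapses R² to ≈ 0.47 and sextuples the relative RMSE, while
silencing the EET/DIET genes (ΔDIET) barely moves either metric — under
this generating model, hydrogen transfer is the route that carries the
predictive signal, which is exactly what the knockout contrast is designed
to detect.

The community-level analysis runs the same way from abundance tables:

```r
sim <- run_simulation(cfg, "out/sim")                    # writes TSVs
res <- run_community_network(cfg, "out/community", tables = sim)
res$report
#> <validation_metrics> Bray-Curtis bn = 0.854, null = 0.782 (joint prediction)
```

A thin command-line wrapper is installed at `inst/cli/methanet`
(`methanet simulate|community-network|gene-network --config cfg.yaml
--out DIR`).

## Package tour

| Area | Functions |
|---|---|
| Tables & IO | `feature_table`, `read/write_feature_table`, `assemble_model_matrix` |
| Preprocessing | `minmax_normalize`, `select_core_taxa`, `compute_rpkm`, `drop_zero_variance` |
| Constraints | `build_blacklist`, `edge_constraints` |
| Network core | `hill_climb`, `exhaustive_search`, `bic_score`, `fit_mle`, `predict_nodes` |
| Validation | `loo_cv`, `null_model_predict`, `bray_curtis_similarity`, `relative_rmse`, `r_squared`, `community_reconstruction_report` |
| Knockout | `silence_genes`, `select_mechanism_genes`, `run_knockout_experiment` |
| Synthetic data | `scenario_config`, `build_template_sem`, `simulate_expression`, `simulate_community`, `simulate_counts` |
| Pipelines | `pipeline_config`, `run_simulation`, `run_community_network`, `run_gene_network`, `export_network` |

See `vignettes/methanogenic-network-inference.Rmd` for the model,
assumptions, numerical conventions and known limitations.
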