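# netprior

Network-based systems genetics in R: prioritize disease risk genes from
GWAS loci and molecular QTLs on the protein–protein interactome, screen
repurposable drugs by permutation-calibrated network proximity, and
validate candidates with emulated target trials on longitudinal patient
records.

The package grew out of the neurodegeneration setting — non-coding
Parkinson's disease GWAS loci acting through brain expression, protein,
splicing, methylation and histone-acetylation QTLs — but every stage is
disease-agnostic: the inputs are plain tables (edge lists, summary
statistics, QTL records, TPM matrices, drug–target tables, patient
records) and the outputs are tibbles that chain with the pipe.

## What it computes

1. **Interactome** — clean an edge-list TSV into an undirected
   gene-symbol graph, extract the largest connected component, and form
   the symmetrically normalized adjacency
   $\hat A = D^{-1/2} A D^{-1/2}$.
2. **QTL mapping** — filter GWAS variants ($p < 10^{-5}$ by default),
   clump to lead SNPs on a supplied LD table (greedy, $r^2 > 0.1$ within
   1 Mb), find proxies ($r^2 > 0.8$), join SNP-linked QTLs by rsID and
   assign interval QTLs to nearest protein-coding genes; summarize the
   regulatory connections and the regulated-gene universe.
3. **Module learning** — a self-supervised two-layer graph network,
   $H^{(i+1)} = \mathrm{ReLU}\bigl(\sum_{j=0}^{2}\hat A^j H^{(i)} W_j^{(i)}\bigr)$,
   with jumping-knowledge concatenation and a softmax module head trained
   to maximize soft modularity plus an edge-reconstruction term (and a
   collapse regularizer that keeps separable modules from fusing).
4. **Risk scoring** — score genes by the evidence concentration of their
   modules, ensemble over seeds, standardize to Z, evaluate against a
   benchmark set by pairwise AUROC, and call risk genes.
5. **Expression & enrichment** — tissue-specificity z-scores
   $z_{it} = (E_{it}-\bar E_i)/\sigma_i$ (clamped at 0) and one-sided
   Fisher enrichment against the interactome background.
6. **Drug proximity** — closest distance
   $d(S,T)=\frac{1}{|T|}\sum_{t\in T}\min_{s\in S}\mathrm{sp}(s,t)$
   with $Z=(d-\mu)/\sigma$ from degree-matched permutations of both sets;
   screen approved drugs at $Z<-3$, $p<0.05$.
7. **Trial emulation** — eligibility, index dates, ATC-L3 comparator
   cohorts, ridge-logistic propensity scores, caliper-gated 1:1 matching
   with SMD balance checks, and Cox hazard ratios with bootstrap CIs,
   summarized as the median HR over balanced emulations.

A synthetic-data generator (`fixture_spec()`, `write_fixtures()`) plants
ground truth in every input format, so the full pipeline runs and is
tested end to end without any external download.

## Worked example

Everything below runs in a few seconds from a fresh session; the numbers
shown are the output of this exact code.

```r
library(netprior)
library(dplyr)

spec <- fixture_spec(
  seed = 42,
  graph = list(n_nodes = 300L, k_modules = 4L, p_in = 0.12, p_out = 0.01),
  evidence = list(n_evidence = 15L, module = 1L)
)
net <- generate_interactome(spec)
ppi <- extract_lcc(net$graph)
ppi
#> <interactome> 300 nodes, 1700 edges, 1 connected component(s)

qtl <- generate_gwas_qtl(spec, net)
evidence <- intersect(qtl$truth$evidence_genes, ppi$nodes)

fits <- lapply(1:3, function(i) train_modules(ppi, K = 4, seed = i))
fits[[1]]
#> <module_fit> 300 nodes, K = 4, soft modularity = 0.4134 (seed 1)
#>   occupied modules: 4; largest module: 76 nodes

scores <- ensemble_scores(lapply(fits, score_genes, evidence = evidence))
head(scores, 4)
#> # A tibble: 4 x 7
#>   gene  score_s1 score_s2 score_s3 ensemble     z  rank
#>   <chr>    <dbl>    <dbl>    <dbl>    <dbl> <dbl> <int>
#> 1 G0036    0.998    0.986    0.998    0.994  1.91     1
#> 2 G0040    0.982    0.990    0.997    0.990  1.90     2
#> 3 G0067    0.998    0.977    0.992    0.989  1.90     3
#> 4 G0027    1        0.985    0.982    0.989  1.90     4
```

The top-ranked genes all come from the module where the QTL evidence was
planted; their ensemble Z separates cleanly from the rest of the network.
The induced disease module then anchors the drug screen:

```r
risk <- select_risk_genes(scores, top_n = 75)
dm   <- disease_module(ppi, risk$gene)
dm
#> <interactome> 75 nodes, 328 edges, 1 connected component(s)

drugs <- generate_drug_targets(spec, net)
scr <- proximity_screen(ppi, dm$nodes, drugs, n_perm = 1000, seed = 7)
head(as_tibble(scr) |>
  select(drug_id, n_targets, distance, mu, sigma, z, p_normal), 3)
#> # A tibble: 3 x 7
#>   drug_id n_targets distance    mu sigma      z p_normal
#>   <chr>       <int>    <dbl> <dbl> <dbl>  <dbl>    <dbl>
#> 1 D_CLOSE         4     0    0.795 0.232 -3.42  0.000313
#> 2 D002            4     0.5  0.766 0.237 -1.12  0.132
#> 3 D007            4     0.75 0.798 0.232 -0.205 0.419

screen_drugs(scr)$drug_id
#> [1] "D_CLOSE"
```

The planted proximal drug sits at distance 0 from the disease module,
3.4 permutation standard deviations closer than degree-matched chance,
and is the only drug passing the $Z<-3$, $p<0.05$, approved screen. Its
protective effect is then checked against the longitudinal cohort, where
the generator's true hazard ratio is 0.5 under strong confounding:

```r
ehr <- generate_ehr_cohort(fixture_spec(seed = 42,
  cohort = list(n_patients = 2000L)))
tr <- emulate_trials(ehr$patients, ehr$diagnoses, ehr$prescriptions,
  drug = ehr$drug, codes = ehr$codes,
  covariate_spec = ehr$covariate_spec,
  n_emulations = 10, n_boot = 200, min_balanced = 5,
  min_users = 100, seed = 11)
tr
#> <emulation_result> drug simva: 10/10 balanced trials;
#>   median HR 0.567 [0.507, 0.637]
```

All ten emulated trials pass the covariate-balance gate and the matched
Cox estimate recovers the protective effect (the naive unmatched estimate
is biased upward by the planted confounder). `tidy()`, `glance()` and
`autoplot()` methods are available for module fits, proximity results and
emulation results.

## Package layout

- `R/interactome.R`, `R/qtl_mapping.R`, `R/module_learning.R`,
  `R/risk_scoring.R`, `R/expression_enrichment.R`,
  `R/drug_proximity.R`, `R/trial_emulation.R` — one file per analysis
  stage;
- `R/fixtures.R` — the synthetic-data generator; `R/pipeline.R` — the
  end-to-end seeded pipeline; `R/plots.R` — ggplot2 views;
- `vignettes/netprior-methods.Rmd` — the models, parameters, design
  decisions and limitations in full.
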