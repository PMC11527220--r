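---
title: "Network systems genetics with netprior: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network systems genetics with netprior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netprior)
library(dplyr)
```

netprior chains five analyses that are usually run as separate tools:
mapping GWAS loci to genes through molecular QTLs, partitioning the
protein–protein interactome into functional modules, scoring genes by how
strongly their modules concentrate regulatory evidence, screening drugs by
network proximity against a permutation null, and validating candidate
drugs with emulated target trials on longitudinal patient records. This
vignette explains each model, the tunable parameters with their defaults
and units, the synthetic-data generator used throughout the test suite,
and the design decisions taken where the methodology was genuinely open.

## The interactome substrate

All network computation happens on the largest connected component (LCC)
of an undirected, unweighted gene-symbol graph. Cleaning is deliberately
minimal: symbols are upper-cased and whitespace-stripped, self-loops
dropped, duplicate and reversed pairs collapsed. No alias resolution is
attempted — harmonizing symbols across source databases is the caller's
job, because any mapping we hard-coded would silently go stale. Nodes are
held in lexicographic order so every derived matrix is identical across
runs and platforms.

The propagation operator is the symmetrically normalized adjacency
$\hat A = D^{-1/2} A D^{-1/2}$, i.e.
$\hat A_{uv} = 1/\sqrt{\deg(u)\deg(v)}$ for each edge. It is only defined
when every node has degree at least one, which the LCC guarantees;
`symmetric_normalize()` refuses to proceed otherwise rather than emit
infinities.

## QTL mapping rules

Variants from one or more GWAS summary tables are concatenated (a SNP in
several studies keeps its minimum p) and filtered at `p_threshold`
(default $10^{-5}$, the conventional "suggestive" level; source texts in
this literature also quote $5\times10^{-5}$, so the threshold is a
parameter rather than a constant). SNP-linked QTL classes (eQTL, pQTL,
sQTL) are joined by rsID; interval classes (meQTL, haQTL peaks) are
assigned to the nearest protein-coding gene on the same chromosome.

Coordinate conventions: GWAS/QTL positions are 1-based inclusive; BED
input is 0-based half-open and converted on read. Nearest-gene distance is
the difference between the facing interval endpoints (zero on overlap),
with equidistant candidates tie-broken lexicographically and reported in a
message — a deterministic rule matters more here than any particular
choice. Strand is ignored.

LD handling consumes a supplied pairwise $r^2$ table rather than
genotypes (reference-panel processing is upstream of this package).
Clumping is greedy: the most significant remaining variant becomes a lead
and absorbs every variant on its chromosome within `window_bp` (default
1 Mb) with $r^2$ above `r2_cutoff` (default 0.1). Pairs absent from the
table are treated as independent. Proxy status requires $r^2$ strictly
greater than 0.8.

## Module learning

The network model propagates node features through the 0th-, 1st- and
2nd-order neighborhood simultaneously,
$$H^{(i+1)} = \mathrm{ReLU}\Bigl(\sum_{j=0}^{2}\hat A^{j} H^{(i)} W_j^{(i)}\Bigr),$$
with depth $L = 2$: each layer already reaches second-order neighbors,
and in dense interactomes higher orders mostly revisit the same genes, so
additional orders add parameters without adding information. Layer
outputs are concatenated (jumping knowledge), letting every node draw on
all neighborhood radii at once. Input features are one-hot node identity
for graphs up to 256 nodes and a Gaussian random projection of the
one-hot basis (width 128) beyond that.

Training is self-supervised; the loss is
$$\mathcal{L} = -\,Q_{\mathrm{soft}}(P, A)
  \;+\; \lambda\,\mathrm{BCE}\bigl(\sigma(ZZ^{\top}), A\bigr)
  \;+\; \gamma\Bigl(\tfrac{\sqrt K}{n}\bigl\lVert\textstyle\sum_i P_i\bigr\rVert_2 - 1\Bigr),$$
where $P$ is the softmax module assignment and $Z$ a linear embedding
head used to reconstruct sampled edges and non-edges. All three terms are
computable from the graph alone. The collapse regularizer (third term,
$\gamma = 1$) deserves a note: plain soft-modularity maximization has
degenerate local optima in which pairs of genuinely separate modules
fuse — on a 300-node four-block benchmark the unregularized objective
reliably occupied only two of four modules. The regularizer is zero for
balanced assignments and maximal under collapse, and restores essentially
perfect recovery at both scales we test. Optimization is full-batch Adam
(`lr = 1e-3`, 200 epochs); every random draw (initialization, feature
projection, non-edge sampling) comes from the single `seed`, so a fixed
seed is bit-reproducible. Backpropagation is written directly on the
dense linear algebra — at interactome-module scale an autodiff framework
would add a heavy dependency for no benefit.

$K$, the module count, is a configuration value. On fixtures with planted
structure we use the planted count; on a real interactome a small grid
(e.g. 50/100/200) compared by soft modularity is the intended procedure.

## Risk scoring

Given a soft assignment and a set of evidence genes (the QTL-regulated
set), each module receives an evidence concentration
$e(m) = \sum_{v\in E} P(v\in m) / \sum_v P(v\in m)$ — the share of its
membership mass carried by evidence — and each gene the
membership-weighted average $s(g) = \sum_m P(g\in m)\,e(m)$. This is our
operationalization of "functional similarity to the evidence through
shared modules": genes co-modular with much evidence score high whether
or not they carry direct evidence. Scores from several seeds are min-max
scaled to $[0,1]$ (no seed dominates), averaged, and standardized across
genes with the population standard deviation (so two genes map exactly to
$\pm 1$). Risk genes are called at `z_cutoff` (default 1.645, one-sided
5%) or by `top_n`; at fixture scale, where a handful of planted modules
makes the ensemble Z strongly bimodal, the rank-based call is the stable
choice and is what `run_pipeline()` uses.

Benchmark evaluation uses the pairwise (Mann–Whitney) AUROC with
half-credit ties. Evidence genes are model inputs, so they are removed
from the evaluation universe entirely rather than counted as negatives;
leaving them in caps the attainable AUROC for reasons that have nothing
to do with ranking quality.

## Expression specificity and enrichment

Tissue specificity is $z_{it} = (E_{it}-\bar E_i)/\sigma_i$ per gene
across tissues, clamped at zero (we care about *specifically high*
expression), with the pre-clamp value retained for diagnostics. The
standard deviation uses `ddof = 1` by default — the convention is not
forced by anything upstream, so it is a documented parameter. Genes
constant across tissues get $z = 0$. The input matrix is assumed already
collapsed to per-tissue means.

Enrichment is the one-sided Fisher exact test against a fixed background
universe (in the pipeline: all LCC genes), computed as the hypergeometric
tail via `stats::phyper` and reported with the sample odds ratio;
batteries of tests get Benjamini–Hochberg q-values.

## Drug proximity

The closest distance
$d(S,T) = \frac{1}{|T|}\sum_{t\in T}\min_{s\in S}\mathrm{sp}(s,t)$ is
judged against degree-matched random re-draws of *both* the disease set
and the target set (the proximity literature permutes both; permuting
only targets is a switchable alternative). Degree bins are contiguous
degree ranges guaranteed to hold at least `min_bin` nodes (default 20);
on graphs smaller than about twice `min_bin` this collapses to uniform
sampling, which is also what makes the exhaustive-enumeration check on a
10-node graph meaningful. $Z = (d - \mu)/\sigma$ from `n_perm`
permutations (default 1000); both the normal-theory one-sided p and the
empirical $(1 + \#\{d_{perm}\le d_{obs}\})/(n_{perm}+1)$ are reported,
since which one a screening criterion couples with Z is a matter of
convention — screening uses the normal-theory p. Candidates must satisfy
$Z < -3$, $p < 0.05$ and be approved. Each drug consumes an RNG
substream derived from the master seed and its id by stable hashing, so
results do not depend on screening order. All-pairs distances are cached
for graphs up to 2000 nodes.

## Trial emulation

Eligibility: at least one qualifying diagnosis, age $\ge 50$ at the first
one, no exclusion diagnosis strictly before it. The disease initiation
date is six *calendar* months before the first diagnosis; the index date
is the first prescription of the arm's drug; patients need
index > initiation and first outcome strictly after index; the baseline
window is `[initiation, index)`. Comparators are other drugs in the same
ATC level-3 class; drugs with fewer than `min_users` (default 100) users
are excluded; a patient exposed to both tested drug and comparator is
treated (configurable — the alternative of first-exposure assignment
would split such patients).

Covariates are binary comorbidity and medication flags from the baseline
window (absent evidence is 0, not missing), sex, race dummies, age at
index (years) and days from initiation to index. The propensity model is
ridge-penalized logistic regression (`glmnet`, $\alpha=0$, fixed
$\lambda = 0.01$ — a fixed penalty keeps the pipeline deterministic and
the ridge stabilizes many correlated binary flags). Matching is 1:1
nearest-neighbor without replacement on the logit-propensity scale with a
caliper of 0.2 logit-SD (the conventional choice), and treated patients
are visited in *seeded random order*: a deterministic order such as
descending score makes caliper exclusions systematically selective —
high-score treated monopolize the scarce comparable controls and the
leftovers are dropped non-randomly, which we observed to imbalance
exactly the covariates feeding the score. Balance requires at most 2% of
covariates with SMD > 0.2. IPTW weights are computed and exported for
diagnostics but the hazard ratio is estimated on the matched sample —
matching is what builds the control group here; the role the weights
play relative to matching in this design is ambiguous in the source
methodology and we flag it as such.

Each of `n_emulations` (default 100) trials re-draws a fraction
(default 0.8) of the control pool before matching; balanced trials get a
Cox proportional-hazards fit with treatment as the sole covariate and a
patient-level bootstrap CI (default 1000 replicates; whether to resample
patients or whole trials is not determined by the source description —
patient-level is implemented). A drug's estimate is the median HR across
balanced trials with the medians of the CI bounds; drugs with fewer than
10 balanced trials are excluded. Censoring is at the last recorded
encounter of any kind.

## The synthetic-data generator

`fixture_spec()` plants ground truth in every input format the pipeline
reads: a planted-partition interactome (default two blocks of 30,
$p_{in}=0.3$, $p_{out}=0.01$ — dense enough that block recovery is
information-theoretically easy, which is the point of a correctness
fixture); GWAS/QTL/LD/annotation tables in which evidence genes from one
module receive QTL links through significant lead SNPs with clumpable
satellites, strict-threshold proxies and both kinds of decoys; an
expression matrix with one elevated target tissue; a drug-target table
with one planted proximal drug; and a confounded patient cohort with a
known treatment hazard ratio (default 0.5), a binary confounder that both
promotes treatment (log-odds +1.2) and doubles the hazard, a baseline
treatment log-odds of $-1.0$ so the comparator pool is roughly twice the
treated arm (1:1 matching needs pool headroom), administrative censoring
at four years, and planted eligibility violations. Every artifact is a
pure function of the spec and a master seed, fanned out into per-component
substreams by stable hashing so regenerating one fixture never perturbs
another.

What the generator does *not* emulate — realistic LD block structure,
ICD ontologies, heavy-tailed TPM distributions, informative censoring,
time-varying confounding — bounds what green tests mean: they demonstrate
the machinery is correct and calibrated under its stated model, not that
the model assumptions hold in any particular real dataset.

## Problem sizes and numerical choices

The test suite exercises distance computations against Floyd–Warshall on
graphs up to 30 nodes, propagation against explicit dense matrix powers,
null calibration with 200 null drugs at 500 permutations on a 300-node
network, exhaustive permutation enumeration on 10 nodes, Fisher p-values
against explicit hypergeometric sums for every 2×2 table with background
up to 60, module recovery on the 60- and 300-node fixtures, and hazard
ratio recovery on cohorts of 5200 patients (about 2000 per arm) across
15 emulations with 200 bootstrap replicates — sizes chosen so the whole
suite completes in a few minutes while each check still has the power to
fail. Ties in ranks use mid-ranks; min-max scaling of a constant score
vector yields zeros; SMD with two zero variances is 0 when means agree
and infinite otherwise; degenerate permutation nulls ($\sigma=0$) flag
the result instead of dividing by zero.

## Known limitations

Gene-symbol identity is the only join key; no alias or ortholog service
is consulted. The LD table is trusted as given. The module learner's $K$
must be supplied; no automatic model selection is run inside
`train_modules()`. The proximity screen assumes the disease module and
drug targets live in one connected component (guaranteed inside the LCC).
Trial emulation supports one outcome definition per run, binary treated
versus ATC-L3 comparator designs only, and estimates marginal hazard
ratios — non-collapsibility means these are not the conditional effects
a covariate-adjusted Cox model would report.
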