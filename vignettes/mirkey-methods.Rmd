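---
title: "Methods: prioritizing key genes and crucial pathways of a miRNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prioritizing key genes and crucial pathways of a miRNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirkey)
```

# The problem

A microRNA that is upregulated in a tumor type is, on its own, an
observation, not a mechanism. To move from "miR-106b-5p is high in cervical
cancer" to "miR-106b-5p plausibly acts through GSK3B, VEGFA and PTK2 in
PI3K-Akt signaling and focal adhesion", an in-silico cascade has to combine
several independent evidence layers: case/control expression of the miRNA
itself across cohorts, tumor-versus-normal mRNA expression, computational
target predictions, protein-protein interaction topology, pathway
membership, cross-cohort replication of the candidate genes, and finally
sequence-level evidence that the miRNA can bind the candidates' 3'UTRs.
`mirkey` implements that cascade as composable, tested R functions, together
with a synthetic-data module that plants a known truth in every layer so the
whole chain can be verified end to end at desk scale.

# The cascade, stage by stage

## Marker meta-analysis

Each case/control study contributes a Hedges g standardized mean difference
of the log2 marker expression (tumor minus normal), with the small-sample
correction $J = 1 - 3/(4(n_t+n_n-2)-1)$ and sampling variance
$(n_t+n_n)/(n_t n_n) + g^2/(2(n_t+n_n))$. We use Hedges g because "SMD"
without qualification conventionally means the bias-corrected estimator in
expression meta-analysis. Fixed-effect pooling is inverse-variance; the
random-effects model is DerSimonian–Laird, with
$\tau^2 = \max\{0, (Q - df)/(\sum w_i - \sum w_i^2/\sum w_i)\}$.
A Mantel–Haenszel fixed-effect formula is sometimes named in this context,
but MH weighting is defined for binary outcome tables, not continuous SMDs;
inverse-variance is the defined fixed-effect estimator for SMDs and is what
we implement. Confidence intervals use the normal 1.96 multiplier, matching
conventional SMD meta-analysis output.

The model is chosen by the conventional rule: random effects when the
heterogeneity p-value is below 0.05 **or** $I^2 > 50\%$ (strict
inequalities; $I^2 = \max(0, (Q-df)/Q) \times 100$ on the percent scale).
Publication bias is assessed by Egger's regression of the standardized
effect on precision, with the intercept tested on $k-2$ degrees of freedom
and significance declared strictly below 0.1. Influence analysis re-pools
after omitting each study; an omission is flagged when the full-analysis
point estimate leaves the omitted-analysis CI or when significance at 0.05
flips — an operationalization of the usual prose criterion. Subgroup
pooling applies the same model-selection rule within each subtype.

## Candidate screening

Differential expression uses a per-gene Welch t-test on log2 values with
Benjamini–Hochberg FDR and the selection rule |log2FC| > 1 and
FDR < 0.05. The Welch test is a deliberate, declared replacement for a
moderated empirical-Bayes test: the cascade's contribution is the
thresholding and intersection logic, not variance shrinkage, and the test
is pluggable behind the same table contract. Constant rows are reported at
p = 1 with a warning rather than NaN. Predicted targets are genes voted by
at least 5 of the 12 prediction databases; candidates are the intersection
of selected DEGs with predicted targets. The clinical battery relates
marker expression to each covariate with the test matched to the
covariate's type (Kruskal–Wallis for multi-class, Wilcoxon rank-sum with
normal approximation and tie correction for binary, Spearman for
continuous, Cox proportional hazards with Efron ties and a Wald test for
overall survival), with one BH FDR column across the battery. BH is
assumed for the battery's FDR column since only "FDR" is ever stated.

## Enrichment

Over-representation is hypergeometric. Both the exact upper tail
$P(X \ge k)$ and the more conservative EASE variant $P(X \ge k-1)$ are
provided; EASE is the default because it is the default of the DAVID
service this stage emulates. The universe is the full gene set of the
expression matrix — the closest desk-scale analog of the service's
background. Zero-overlap terms are excluded; BH is applied within each
category; significance thresholds are 0.01 for the GO-style categories and
0.05 for pathways (the GO threshold is a parameter; workflows of this kind
are reported at 0.01 and sometimes at 0.001, so it is not hard-coded).

## Interaction-network hubs

Edges below confidence 0.7 are removed (STRING-style integer scores are
divided by 1000 on input), the largest connected component is kept, and the
core is the induced subgraph on nodes whose degree **and** raw betweenness
both strictly exceed their means — on a regular graph this core is empty by
construction, which the code reports as an error rather than silently
relaxing. Twelve centralities are computed on the core: Degree,
Betweenness, Stress, Closeness, Radiality, EcCentricity,
ClusteringCoefficient, MNC, DMNC (exponent 1.7), MCC (sum of
$(|C|-1)!$ over maximal cliques), EPC (mean component size over 1000
seeded half-retentions of the edges), and BottleNeck. The named algorithms
are standard in hub screening but are rarely written down precisely, so
their definitions are fixed in the function documentation; two
reproducibility choices deserve mention. EPC is a Monte-Carlo score, so it
takes an explicit seed and its resample count is a parameter. BottleNeck
requires one shortest-path tree per source; we define each node's tree
parent as its smallest-index neighbor one BFS level closer to the source,
which makes the tree — and the score — order-independent and exactly
reproducible by an independent implementation. A node earns a point when
its subtree holds more than $n/4$ nodes; roots are not credited for their
own trees. Hub voting takes the top 20 nodes per algorithm (ties at the
20th score are all included, preventing arbitrary truncation) and keeps
genes appearing in at least two lists.

## Pathway crosstalk and the gene-pathway core

Significant pathways with at least 3 genes form a network whose edges join
pairs sharing at least 2 genes, weighted by the mean of the Jaccard
coefficient $|A \cap B| / |A \cup B|$ and the overlap coefficient
$|A \cap B| / \min(|A|,|B|)$. MCODE clustering runs on the unweighted
topology (the JC/OC weights are edge annotations; they play no role in the
clustering): vertex weights are the core number times the density of the
highest k-core of the closed neighborhood, complexes grow from the
highest-weight seed admitting neighbors within the 0.2 vertex-weight
percentage, haircut iteratively removes singly-connected members, and a
cluster's score is its density times its node count, retained strictly
above 4. Cytoscape's defaults are used for every other MCODE parameter. Hub genes are then mapped into the retained clusters' pathways
as a bipartite membership network, and the "main" genes and pathways are
the nodes whose degree strictly exceeds the mean pooled over both sides
(the rule is applied over nodes of both kinds, not per-side averages).

## Key genes and crucial pathways

The main genes are re-tested across independent validation cohorts with a
median-rank meta-analysis emulating the proprietary Oncomine-style
procedure: genes are ranked by Welch p within each study, the
statistic is the median rank across studies, and the combined p is the
permutation tail probability of a median rank at least as small under
independent uniform ranks, with the add-one correction
$p = (b+1)/(B+1)$. The null is seeded and shared across genes; its
resolution ($B$) is a parameter, since rank-based nulls produce p-values
on a discrete grid whose spacing the analyst may need to control. Ranks
are computed over the full tested universe, not only the reported genes —
p-values far below $1/m$ are only attainable when the rank pool is large.
Stability requires the combined p **and** every leave-one-out combined p
to stay below 0.05; key genes are the stable main genes, and the crucial
pathways are the pathways every key gene participates in (set
intersection). Stability is monotone in the threshold by construction.

## Seed sites and AU-rich elements

A seed site is an exact occurrence on the UTR of the reverse complement of
miRNA positions 2–8 (1-based from the 5' end) — the 7-mer perfect-pairing
criterion. Supplemental pairing, wobbles and hybridization energy are out
of scope: the stated criterion is exact 2–8 complementarity, and a
thermodynamic model would add a second, undeclared filter. Coordinates are
0-based half-open; overlapping matches are all reported; T is accepted and
mapped to U. AU-rich-element classification scans AUUUA pentamers and
U-rich windows: class II requires an overlapping AUUUA pair (offset
difference < 5) near a U-rich window, class I a lone AUUUA near one, class
III a U-rich region with no AUUUA at all. "U-rich" is a 10-nt sliding
window with U fraction at least 0.8 and "near" is 20 nt — declared
defaults, since the classical verbal taxonomy of AREs gives no numbers; the AU
fraction of each site is reported rather than thresholded for the same
reason.

# The synthetic-data module

Every generator plants a recoverable truth and returns it alongside the
data; the same master seed drives stream-derived seeds per generator, so
outputs are byte-identical under a fixed seed and independent of call
order.

The defaults are the study conditions the cascade is tested under:

* **Marker studies** — four case/control studies with group sizes 19/19,
  30/26, 8/8 and 10/10 (the sizes of the four qRT-PCR cohorts in which
  this miRNA has been profiled in cervical tissue), planted SMD 2.85 on
  the log2 scale,
  within-group SD 1. Values are emitted on the raw scale ($2^x$) so the
  pipeline's log2 step is exercised.
* **Tumor/normal matrix** — 1200 genes, 30/30 samples, exactly
  $\lfloor 0.1 \times 1200 \rfloor = 120$ planted DE genes shifted by 3
  log2 units (95% up — cervical tumor DEG splits are heavily up-skewed),
  Gaussian noise on the log2 scale.
* **Target votes** — 12 databases voting independently,
  Bernoulli(0.9) on true targets and Bernoulli(0.05) elsewhere; the true
  target set contains all DE genes plus background targets.
* **Interaction network** — a 15-gene near-clique module (edge probability
  0.9, confidences 0.75–0.99) planted among the DE genes, extended to 120
  nodes by preferential attachment. Each module member is guaranteed three
  dedicated partners among the early joiners — complex members carry their
  own specific interactors — and each new node's strongest edge draws its
  confidence from 0.70–0.95 while further edges draw from 0.30–0.90,
  emulating the low-skewed STRING confidence distribution. These two
  choices make the module's recovery through the degree-and-betweenness
  core a property of the construction rather than of luck: dedicated
  high-confidence spokes give every module node both degree and
  betweenness above the component means.
* **Pathways** — 25 sets of 10–18 genes; the first nine form a crosstalk
  cluster drawing 60% of their members from a shared pool of non-module DE
  genes plus two module "hub member" genes each; the three designated
  pathways contain all three anchor genes, and each anchor additionally
  joins its own disjoint share of the remaining cluster pathways. The
  pathways common to every anchor are therefore exactly the designated
  trio, while anchors still out-degree other genes in the bipartite
  gene-pathway network.
* **Validation cohorts** — nine studies of 20/20 samples over the full
  universe in which only the anchors are shifted (2 SD), emulating
  cross-cohort replication in which most screen hits fail to validate and
  the true key genes replicate everywhere.
* **Sequences** — 300-nt UTRs; positive UTRs carry the planted seed sites
  inside 17-nt windows whose flanks are drawn from {A, U} (window AU
  fraction ≥ 0.6, by construction), rejection-sampled so no accidental
  site exists anywhere else; negative UTRs carry none.
* **Clinical table** — 300 samples; the lymph-node class depends on marker
  expression through a latent Gaussian (slope 0.8), every other covariate
  and the censored survival time are independent of it.

What the generators deliberately do **not** emulate: batch and platform
effects, correlated prediction databases, gene-gene expression correlation,
HPV biology, and realistic pathway size distributions. Passing the
end-to-end recovery tests therefore shows the cascade's logic is correct
and its thresholds behave as printed — not that the cascade would be robust
to the confounding structure of real survey data.

# Numerical and design notes

* Strict inequalities everywhere a rule is printed as strict: the
  confidence filter removes scores `< 0.7`, model selection switches at
  `I^2 > 50`, degree/betweenness cores and bipartite cores use `>` mean,
  MCODE retains `score > 4`, hub voting keeps `count >= 2`, the vote
  filter keeps `>= 5`.
* Degenerate inputs are errors or warnings, never silent: empty candidate
  intersections warn and halt the pipeline, an empty degree/betweenness
  core errors with advice, single-level clinical covariates are skipped
  with a warning, zero pooled SD and empty gene sets are errors.
* The permutation null of the median-rank meta-analysis draws ranks with
  replacement (independent uniform ranks); exhaustive enumeration at small
  size is the test oracle.
* `run_all` derives every stage seed from the config seed; rerunning with
  the same config reproduces the report byte for byte, and the manifest
  records the seed, a config fingerprint, the package version and
  per-stage row counts.
* Problem sizes in the tests (1200-gene universe, 120-node network, 50
  end-to-end seeds, 300 meta-analysis replicates, 1000-replicate null
  calibrations) were chosen as the smallest scales at which the planted
  effects are clearly identifiable; they keep the full suite within a few
  minutes on one core.

# Known limitations

The centrality consensus is computed on the core subnetwork, and the
degree/betweenness means used by the core filter are computed on that
step's input graph and recorded on the result, so the provenance of every
threshold is explicit. The EASE variant, the MCODE score formula
(density × size) and the median-rank permutation null are declared
emulations of services whose exact internals are unpublished; each is
pinned by its own oracle tests rather than by comparison to the service.
Real-data ingestion is deliberately format-level only (TSV/GMT/FASTA
readers): no download clients are included.
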