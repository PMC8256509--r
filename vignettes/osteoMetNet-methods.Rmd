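---
title: "Methods: integrated biomarker and metabolite prioritization"
author: "osteoMetNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated biomarker and metabolite prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoMetNet)
```

# Scope

osteoMetNet re-implements, as a tested library, an integrated osteosarcoma
transcriptomics workflow: two-group moderated differential expression on a
cell-line vs normal-bone contrast, over-representation and sample-wise
gene-set scoring, a confidence-filtered protein-protein interaction (PPI)
network intersected with disease-association gene tables, median-split
survival screening of the resulting feature genes, and a heat-diffusion
model on a heterogeneous KEGG-style metabolic graph that prioritizes
disease-associated metabolites and assembles a disease-metabolic network.
All external resources (expression series, survival cohort, PPI scores,
disease-gene tables, compound mappings, the metabolic graph) enter as
plain-text files; nothing is downloaded. A synthetic-data module generates
every input with planted ground truth so each stage is testable at desk
scale.

# Models and procedures

## Moderated differential expression

Each gene is fitted by ordinary least squares on the two-group design; the
log2 fold change is the case-minus-control mean difference and the residual
variance $s_g^2$ is pooled over both groups with $d_g = n_1 + n_2 - 2$
degrees of freedom. Variances are then shrunk toward a prior
$(d_0, s_0^2)$ estimated by moment matching on $\log s_g^2$: with
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$, the prior solves
$\psi'(d_0/2) = \mathrm{Var}(e) - \psi'(d_g/2)$ by trigamma inversion and
$s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}$. The posterior
variance is $\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and the
moderated t-statistic is referred to a t distribution on $d_0 + d_g$
degrees of freedom. When the observed log-variances are no more dispersed
than chi-square sampling noise alone predicts, $d_0 = \infty$ and the
prior collapses to the pooled mean variance (the normal-theory limit).
Two numerical choices matter:

* genes with $s_g^2 = 0$ (possible in noiseless simulations) are floored
  at machine epsilon so the moment equations stay finite rather than
  discarding the gene;
* p-values are two-sided throughout.

DEGs are called at BH-adjusted $q < 0.05$ **and** $|\log_2 FC| > 2$, both
strict, with direction taken from the sign of the fold change. Whether the
original workflow used moderated or ordinary t is not stated; the
moderated statistic is the default of the empirical-Bayes framework it
names, so it is used here. BH adjustment itself is delegated to
`stats::p.adjust`.

## Over-representation analysis

Up- and down-regulated DEGs are tested as separate queries against a GMT
collection by the upper-tail hypergeometric test, with the universe set to
the genes on the expression matrix (standard practice for array data, not
the whole genome). Sets are retained at raw $p < 0.05$ with overlap count
$\ge 1$; BH q-values are reported across all tested sets but are not part
of the filter, matching the stated cut-offs.

## Sample-wise gene-set scoring

The gene-set variation score follows the kernel variant appropriate for
continuous log-intensity data: for gene $i$ and sample $j$,
$z_{ij} = \frac{1}{n}\sum_k \Phi\{(x_{ij}-x_{ik})/h_i\}$ with bandwidth
$h_i = s_i/4$; constant genes get $z = 0.5$. Per sample, genes are ranked
by $z$ (largest first) and rank positions are symmetrized about the middle
of the list, giving weights $|N/2 - r_{ij}|^{\tau}$ with $\tau = 1$. The
enrichment score of a set is the maximum positive deviation minus the
magnitude of the maximum negative deviation of the weighted
Kolmogorov-style random walk (up-steps at member genes, normalized;
down-steps $1/(N-m)$ elsewhere). Sets with fewer than 2 members after
intersection with the matrix are dropped (a 1-gene walk is defined but
degenerate; it is exercised only in tests). In the degenerate case where
every member sits exactly at the middle rank (total member weight zero)
the walk falls back to unweighted steps. Differential pathway activity
re-uses the moderated two-group machinery with sets in the role of genes,
retained at adjusted $p < 0.05$.

## PPI network and feature genes

Edges with confidence score $\ge 0.7$ (inclusive — the conventional
"medium confidence" setting includes the boundary) whose both endpoints
are DEGs are retained; unordered duplicates keep the maximum score, and
DEGs left without an edge are excluded from the node set, since downstream
intersection is defined on network members. Gene symbols are upper-cased
before any matching because cross-database tables differ in case. Feature
genes are the three-way intersection of the PPI node set with two
disease-association tables; the output keeps per-source membership flags
so Venn-style counts are recoverable.

## Survival screening

For each candidate gene the cohort splits at the median expression, ties
to the low group (deterministic and reproducible). Groups are compared by
the standard two-group log-rank test (the usual companion of
median-split Kaplan-Meier analysis; the original description names only
the KM comparison). The Kaplan-Meier estimator is the product-limit form
over distinct event times. Genes with $p < 0.05$ are called prognostic;
the direction is decided by the larger restricted mean survival (area
under the KM curve up to the longest observed follow-up), which yields a
total ordering even when curves cross. Times are in months.

## Heat diffusion on the metabolic graph

The typed graph has compound, reaction, enzyme, pathway and module nodes;
gene nodes exist only in the final overlay and never enter the diffusion.
On the scored (non-gene) subgraph, $L = D - A$ is the unnormalized
Laplacian and $B$ is diagonal with $B_{ii} = 1$ exactly for pathway nodes
(module nodes get 0 — the rule is applied literally). The conductance
matrix is $KI = L + B$, which is symmetric positive definite whenever
every connected component contains a pathway node; components without one
are excluded from scoring with a warning. The printed description of the
temperature score omits an inverse: a literal product of a Laplacian-like
matrix with an indicator vector produces degree-local artifacts, not a
diffusion, so the score is defined as the solution of the linear system
$KI \, T = G$, where $G$ indicates the affected input metabolites — heat
injected at the affected compounds, draining at pathway anchors. The
global sign and scale of this convention are immaterial because
significance uses only the rank of the observed score among permuted
scores (asserted by a convention-flip test). Solves go through sparse
symmetric factorization (package Matrix) and the relative residual is
checked against $10^{-10}$.

Significance is Monte-Carlo: the affected set is redrawn uniformly among
compound-type nodes at the same cardinality (the affected metabolites are
the permuted entity; a parametric normalization is out of scope) and each
node's p-value is the add-one estimator
$p = (1 + \#\{T_{perm} \ge T_{obs}\})/(n_{perm} + 1)$ with a mandatory
seed; the default is 10000 permutations (1000 in the bundled tests and
pipeline defaults, which keeps the Monte-Carlo floor at $1/1001$ while
staying fast). Nodes with $p < 0.05$ (strict) form the significant
subnetwork; DEG-compound interactions are then overlaid for retained
compounds only, and compounds are ranked by descending DEG-interaction
count (ties by smaller p, then id) — the top compound is the key
metabolite.

On calibration: p-values of graph-adjacent nodes within one run are
strongly dependent (they share sources), so a goodness-of-fit test across
the nodes of a single run does not measure calibration. The package's
calibration check is marginal: for a fixed node, the p-value across
independent replicate draws of the affected set is uniform by
exchangeability of the observed draw with the permutation draws, up to
the $1/(n_{perm}+1)$ discreteness, and that is what the test suite
asserts.

## qPCR quantification

The relative-expression helper implements
$2^{-\Delta\Delta Ct}$ with
$\Delta\Delta Ct = (Ct_{target,sample} - Ct_{ref,sample}) -
(Ct_{target,calibrator} - Ct_{ref,calibrator})$; it is a closed-form
convenience for validating screened genes against qPCR panels.

# The synthetic-data generator

The generator's defaults are the study conditions the package emulates:

* **Expression**: 1000 genes, 19 case vs 4 control samples (the cell-line
  vs normal-long-bone design), simulated directly on the log2 scale
  (matching the downstream linear model) with per-gene base means uniform
  on [4, 10], 40 planted DE genes at $|\log_2 FC| = 3$ (alternating
  sign) and Gaussian noise with s.d. 1.
* **Survival cohort**: 80 samples on a log2(fpkm+1)-like scale; event
  times exponential with a 36-month baseline median and multiplicative
  hazards — each planted prognostic gene multiplies the hazard by its
  hazard ratio when the sample is above that gene's median (defaults: 3
  and 1/3, one harmful, one protective). Censoring is per-subject
  Bernoulli at the configured rate, with the censoring time uniform
  before the event; this keeps the censored fraction directly
  controllable (and makes a zero rate yield an all-event cohort), which
  an administrative-window scheme cannot guarantee.
* **Metabolic graph**: 80 compounds, 50 reactions, 15 enzymes, 5
  pathways, 2 modules. Every reaction carries a pathway edge and every
  module links back to the first pathway, so the graph is one
  pathway-anchored component by construction. The planted affected
  compounds (3) all attach to reactions of the first pathway, forming the
  hot cluster the diffusion should recover; with 80 compounds the
  permutation base rate of a self-source draw is 3/80, comfortably below
  the 0.05 retention threshold.
* **Association tables**: STRING-like scores dense among DE genes;
  disease tables carry 80% of the DE set plus background genes, always
  including the planted prognostic genes when the overlap is positive;
  the CTD-like compound-gene table links every chemical that resolves to
  a planted affected compound to a prognostic gene (so the discovery
  chain — prognostic genes to chemicals to compound ids to graph — can
  seed the diffusion), and wires the key chemical to six DEGs; the
  mapping table resolves only half the chemical names, and some resolved
  ids are absent from the graph, exercising the unmapped/unmatched paths.

Every generator is a pure function of the configuration (the master seed
included; stages draw from fixed seed offsets), so identical
configurations reproduce identical bytes. What the generator does **not**
emulate: probe-level microarray noise, batch effects, correlated gene
blocks, realistic KEGG topology statistics, or informative censoring.
Passing tests therefore demonstrate algorithmic correctness and
calibration under a clean generative model, not robustness to the
artifacts of real array or FPKM data.

# Problem sizes and runtime

The test suite runs the oracle comparisons at 50x10 matrices (20 seeds),
exhaustive hypergeometric enumeration up to a 20-gene universe,
random-walk enumeration up to 12 genes, 500 label permutations for the
log-rank null, 150 replicate draws at 1000 permutations for diffusion
calibration, 20 replicates for planted-compound recovery, and one full
1000-gene end-to-end run — sizes chosen so the whole suite completes in
about two minutes while keeping Monte-Carlo error far from each test's
margin.

# Known limitations

* The workflow's published gene and metabolite lists depend on specific
  database snapshots (GEO, STRING, CTD, GeneCards, KEGG, MSigDB) and are
  not reproducible from synthetic inputs; the package asserts properties,
  not those lists.
* Single two-group contrast only: no covariates, batch terms or
  multi-factor designs; no Cox regression or optimal cut-point scanning
  in the survival screen.
* The ORA module treats gene sets as flat lists (no ontology topology or
  redundancy reduction).
* The diffusion null redraws the affected set at fixed cardinality; it
  does not model uncertainty in the compound-mapping step itself.
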