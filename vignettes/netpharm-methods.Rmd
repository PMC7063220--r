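---
title: "Methods: network pharmacology and chemometrics in netpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network pharmacology and chemometrics in netpharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

`netpharm` implements the two arms of a formula-level pharmacology study —
compound screening with network construction, and pharmacodynamic evaluation
by latent-variable discriminant modelling — together with a seeded generator
of synthetic inputs. This vignette documents the models, their assumptions,
the tunable parameters, and the design decisions taken where the underlying
methodology left choices open.

## Screening model

Drug-likeness is a Tanimoto coefficient on a fixed, shared schema of
non-negative molecular descriptors,

$$T(A,B) = \frac{A \cdot B}{\lVert A\rVert^2 + \lVert B\rVert^2 - A \cdot B},$$

where $A$ is the compound's descriptor vector and $B$ a reference profile
(conventionally the average of approved drugs). On non-negative vectors the
coefficient lies in $[0, 1]$, is symmetric, and equals 1 exactly at identity;
these are enforced properties, not assumptions. The exact descriptor schema
behind published per-compound DL values is database-specific and not
recoverable, so `drug_likeness()` is validated analytically and the reference
vector is an explicit input. When a compound table carries both a precomputed
`dl` column and a descriptor vector, the precomputed value wins (it usually
originates from the same database as the rest of the record); recomputation
can be forced.

The ADMET gate retains a compound when it passes *all three* criteria —
oral bioavailability, Caco-2 permeability, drug-likeness — or when it is
whitelisted. Defaults are OB ≥ 30 %, Caco-2 ≥ −0.4, DL ≥ 0.18, applied
*inclusively*: the published phrasing uses ≥ for these thresholds, while the
target-prediction scores (SEA Max TC > 0.57, Swiss Possibility > 0) are
stated strictly; both conventions are configurable (`screen_config()`,
`filter_predictions()`). Malformed compound records are collected as error
records and skipped rather than aborting the run, because database extracts
are messy and a single bad row should not cost the batch.

## Network model

Module networks are **undirected and unweighted** tripartite graphs with two
admissible edge types, herb–compound attribution and compound–target
interaction. Nothing in the source methodology assigns direction or weight to
these edges, and the convention of the common visualisation tools for such
maps is undirected; the constructor enforces the tripartite constraint
structurally, so a forbidden edge type is a hard error, as is an edge naming
an undeclared node.

Degree is the raw incident-edge count. Because a compound's degree mixes
herb edges and target edges, `centrality_table()` also reports
`target_degree` (compound–target edges only); published degree tables for
such networks are consistent with the mixed counting, but both are exposed.
Betweenness uses Brandes' algorithm (via igraph) with fractional credit among
tied shortest paths; the normalized form divides by $(n-1)(n-2)/2$ with $n$
the whole-network node count, matching the common tool output, and the raw
form is available by flag. Rankings break ties by the secondary metric and
then node id, so they are fully deterministic.

Cross-module overlap supports two modes. With memberships it counts
directly; with printed sizes only, the intersection is recovered by
inclusion–exclusion, $|A \cap B| = |A| + |B| - |A \cup B|$, and inconsistent
size triples are rejected.

## Over-representation model

Enrichment of a module target set against an annotation collection uses the
one-sided hypergeometric tail $P(X \ge k)$ for $X \sim
\mathrm{Hypergeom}(N, K, n)$. The conservative EASE variant, which replaces
$k$ by $k-1$ (so singleton overlaps are never significant), is available as a
mode. The adjustment across tested categories is Benjamini–Hochberg; raw
p-values are always reported alongside. The background defaults to the union
of annotated genes in the collection and can be overridden with a user gene
universe. Only categories with at least one query hit are tested — a ranked
over-representation analysis, not a global goodness-of-fit. GO-graph
propagation is deliberately out of scope; annotation sets are taken as given.

## Chemometric model

The cohort matrix holds ten indices per animal: whole-blood viscosity at
shear rates 200, 100, 50, 5 and 1 s⁻¹ and plasma viscosity (mPa·s), thrombin
time, prothrombin time and activated partial thromboplastin time (s), and
fibrinogen (g/L).

**Preprocessing.** Columns are autoscaled (centred, unit variance). The
original analysis tool's default is unit-variance scaling and the source does
not state otherwise; Pareto scaling was considered and rejected because under
mixed units it concentrates all weight on the large-variance viscosity
indices and could never select a low-variance index like WBV200, which
contradicts the reported variable selection. Scaling is still exposed as an
option.

**PLS-DA.** The class structure is one-hot encoded and both blocks scaled;
the fit is NIPALS PLS2 with successive deflation. Reported statistics follow
the standard conventions: per-component and cumulative $R^2X$ and $R^2Y$
(explained sums of squares of the scaled blocks), and $Q^2 = 1 -
\mathrm{PRESS}/\mathrm{SS}$ from venetian-blind cross-validation (row $i$ in
fold $((i-1) \bmod 7) + 1$ by default; fold count configurable). Each
training fold re-estimates its own scaling. The implementation agrees with
the independent `mixOmics` implementation to machine precision on shared
fixtures (verified in the test suite).

**VIP.** Variable importance in projection over $A$ components,

$$\mathrm{VIP}_j = \sqrt{\; p \, \frac{\sum_a \mathrm{SSY}_a \, w_{ja}^2}
{\sum_a \mathrm{SSY}_a}},$$

with unit-norm weight vectors, so $\sum_j \mathrm{VIP}_j^2 = p$ identically;
VIP > 1 is the conventional selection rule.

**Permutation validation.** Class labels are permuted (default 200 times,
seeded), the model refit each time, and the model is declared valid when
every permuted $R^2Y$ and $Q^2$ falls below the real model's values.
Intercepts at zero label correlation are estimated by regressing the permuted
statistics on the absolute correlation between permuted and original dummy
matrices; a negative $Q^2$ intercept is the classical non-overfitting
signature. CV-ANOVA is not implemented: its formulation is proprietary to the
original analysis software, and permutation testing already covers model
validity.

**Distance to normality.** Group centroids are computed in score space and
ranked by Euclidean distance to the control centroid — the closer a treated
group, the stronger its normalising effect.

**Summary ANOVA.** One-way ANOVA per index is reconstructed exactly from
group means, SDs and sizes ($SS_B = \sum_i n_i(\bar x_i - \bar x)^2$,
$SS_W = \sum_i (n_i - 1) s_i^2$); with two groups the F statistic equals the
squared two-sample t statistic, and the reconstruction agrees with
`stats::aov` on raw data round-trips. Pairwise contrasts against the control
and the model group use Welch t tests from the same summaries, since the
original post-hoc procedure is unnamed; Welch is the conservative default
when group variances differ by an order of magnitude, as they do for several
indices here.

## The synthetic-data generator

The generator exists so every downstream stage has inputs with *known*
planted structure.

**Compound universe** (`generate_universe()`): each compound passes the ADMET
gate with probability `frac_pass_admet` (a Bernoulli indicator, so the
retained-set size is Binomial-consistent by construction); passing compounds
draw OB, Caco-2 and DL uniformly above the thresholds, failing compounds
violate one to three criteria. Compound–target degrees follow a truncated
power law (exponent 2.5, minimum 2, cap 15) with preferential target
attachment — real compound–target maps are heavy-tailed, with top-compound
degrees an order of magnitude above the background — and planted hub
compounds receive a fixed elevated degree (default 30, against a background
mean near 3). Edges are routed through curated/SEA/Swiss sources with
passing scores, and ~10 % decoy edges (sub-threshold scores, wrong species)
are added so the prediction filter has genuine work to do. Targets carry
independent module labels (hemorheology with probability 0.35, coagulopathy
0.40, so roughly a seventh of targets are shared). Pathway annotation sets of
mean size 15 are sampled from the target universe; a planted enriched
pathway up-weights hemorheology-module targets by its odds multiplier.

A power note on planted enrichment: with a 200-target background of which
~35 % form the query, a category of size 15 and odds multiplier 10 yields an
expected overlap near 13 against a null mean of 5.3 — detectable, but after
Benjamini–Hochberg across 20 categories the recovery probability is only
about 85 % because Poisson size variation occasionally produces small
categories. The recovery property tests therefore plant categories of size
30, where the expected planted overlap sits about six null standard
deviations out and recovery is essentially certain. This is a designed
experiment about the *mechanism*, not a statement that all real pathways are
large.

**Cohorts** (`generate_cohort()`): each index is drawn independently from
$\mathcal N(\mu, \sigma^2)$ per group. Only per-index means ± SD are
available for the source cohort, so independence is the honest default; a
user-supplied correlation matrix induces within-animal dependence via the
Cholesky factor. `qsbss_reference_groups()` carries the published parameters
of all six groups (control, model, three dose groups, positive control) with
a default of 8 animals per group — the stated design size; the observed
tables note 6–8 per group, so `n` is configurable per group rather than
guessing the attrition. One printed SD ("012" for the mid-dose WBV100) is
read as 0.12, consistent with its neighbours.

What the generator does **not** emulate: correlations among the ten indices
(they are strong in real blood, where the five viscosity readings come from
one curve), non-normal tails, batch effects, and any mechanistic link between
ADMET values and structure. Consequently, tests passing on synthetic cohorts
demonstrate that the *estimators and rankings behave correctly under the
stated generative model*, not that the biological conclusions transfer; in
particular, with independent indices the population VIP ordering is fully
determined by the per-index standardised group separation, and the five
viscosity/fibrinogen indices with the largest separations are exactly the
ones whose population VIP exceeds 1, with TT and APTT just below — the
generator reproduces the reported selection pattern structurally, while
individual n = 8 replicates fluctuate around it.

## Numerical choices and degenerate inputs

* NIPALS converges on the relative change of the score vector
  (tolerance 1e−10, cap 500 iterations); an exhausted X or Y residual stops
  extraction early rather than dividing by ~0.
* Constant columns are a hard error in `autoscale()` (named in the message);
  dummy-Y columns that become constant inside a CV training fold fall back
  to unit scale instead of exploding.
* Two all-zero descriptor vectors make the Tanimoto coefficient undefined
  and raise; negative descriptors are rejected because boundedness in
  $[0,1]$ then fails.
* Disconnected networks are allowed; unreachable pairs contribute zero
  betweenness.
* All generators and the permutation test take explicit integer seeds;
  identical seeds give identical output, byte for byte, including the
  pipeline's `summary.json` (deterministic key order, fixed float
  formatting).

## Problem sizes

The bundled tests and the reproduction script run on deliberately small
instances: universes of 20–400 compounds and up to 200 targets, cohorts of
6–16 animals per group (10,000 only for law-of-large-numbers moment checks),
betweenness oracles on graphs of ≤ 15 nodes where exhaustive path
enumeration is feasible, and 100-replicate VIP summaries. These sizes keep
every property check exact or tightly calibrated while remaining fast; all
operations scale to realistically sized extracts (hundreds of compounds,
thousands of edges) without modification.

## Known limitations

* No live database clients: all inputs are files (TSV/GMT/YAML), by design.
* The exact published compound tables cannot be regenerated — DL descriptor
  schemas and database versions are unavailable — so screening is validated
  on analytic cases and synthetic ground truth.
* Enrichment results depend on the annotation collection supplied; category
  counts from any specific web service release are not reproducible targets.
* CV-ANOVA is not provided; permutation validation is the supported model
  check.
* PCA's cross-validated $Q^2$ uses row-held-out projection onto training
  loadings, which is mildly optimistic compared to element-wise deletion
  schemes; it is used for descriptive model sizing only.
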