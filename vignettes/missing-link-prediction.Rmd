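---
title: "Two-stage prediction of missing PPI links: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage prediction of missing PPI links: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgefill)
```

## The problem

Experimentally mapped protein–protein interaction (PPI) networks are
incomplete: only a fraction of the true interactome of even
well-studied organisms such as *Saccharomyces cerevisiae* has been
observed, and that incompleteness degrades every downstream analysis
that leans on network topology — essential-protein prediction in
particular. `edgefill` implements a two-stage strategy for proposing
the missing edges and then isolating the subset of proposals most
likely to be real.

## Stage 1: scoring unlinked pairs

Interacting proteins tend to be co-expressed and to share function.
Stage 1 therefore scores every *unlinked* pair of network proteins by
two complementary similarities.

**Expression correlation.** For genes $X$ and $Y$ profiled over $n$
samples, the Pearson correlation is computed from its definition,

$$\mathrm{PCC}(X,Y) \;=\; \frac{1}{n-1}\sum_{i=1}^{n}
\left(\frac{X_i-\bar X}{s_X}\right)\left(\frac{Y_i-\bar Y}{s_Y}\right),$$

with the sample ($n-1$) standard deviation. Pairs where either gene is
missing from the expression compendium, or where the correlation is
undefined (zero variance, non-finite entries), score 0 so that any
positive threshold excludes them; a `missing = "pairwise"` switch
drops incomplete samples pairwise instead. All-pairs scoring is done
blockwise on the standardised matrix and is contractually equal to the
pairwise definition (tested to $10^{-10}$).

**GO semantic similarity.** Functional similarity uses a Wang-style
decomposition of Gene Ontology terms. For an anchor term $A$, every
ancestor $t$ receives an S-value: $S_A(A)=1$ and, walking up the DAG,

$$S_A(t) \;=\; \max_{c\,\in\,\mathrm{children}(t)} \; w_e \cdot S_A(c),$$

where $w_e$ is 0.8 for `is_a` and 0.6 for `part_of` links (the
customary constants of this measure; both configurable). Protein-level
similarity is the set form

$$\mathrm{sim}(u,v)\;=\;\frac{\sum_{t\in T_u\cap T_v}\bigl(S_u(t)+S_v(t)\bigr)}
{\sum_{t\in T_u}S_u(t)+\sum_{t\in T_v}S_v(t)},$$

where $T_u$ is, by default, the ancestor closure of all terms
annotated to $u$ and $S_u(t)$ the maximum S-value over those anchors.
The closure reading is the natural interpretation of a term-set
intersection for multi-term proteins; a best-match-average alternative
(`aggregate = "bma"`) is available because the set form dilutes the
similarity of proteins with many unrelated annotations. Proteins
without annotation score 0. Only the Biological Process aspect is used
by default; `regulates`-type relations are ignored.

**Thresholding.** A pair is predicted when
$\mathrm{PCC} \ge \theta_{\mathrm{pcc}}$ and, when the GO filter is
enabled, $\mathrm{sim} \ge \theta_{\mathrm{go}}$. Comparisons are
inclusive, making results deterministic at ties, and GO similarity is
only evaluated for correlation-passing pairs — the two-stage gate both
matches the method's design and bounds compute. The canonical
operating points are a strict correlation-only filter
($\theta_{\mathrm{pcc}}=0.98$, "network 1") and a relaxed correlation
with a GO filter ($\theta_{\mathrm{pcc}}=0.95$,
$\theta_{\mathrm{go}}=0.5$, "network 2"); both add roughly the same
proportion of links on the yeast data the method was developed on, and
the added proportion is non-increasing in both thresholds.

## Stage 2: selecting the significant predictions

Predicted links are added to the observed network
(`augment_network()`), and protein rankings under centrality measures
are compared between the original and the two augmented networks. Six
centralities ship in a pluggable registry:

| method | definition | notes |
|---|---|---|
| DC | degree | |
| BC | shortest-path betweenness | via igraph |
| CC | closeness | component-restricted, scaled by $(m-1)/(N-1)$ for component size $m$ so disconnected graphs need no infinite distances |
| EC | principal eigenvector | power iteration on $A+I$ to $10^{-10}$ (the shift suppresses two-periodic oscillation on bipartite graphs), nonnegative, unit maximum |
| SC | subgraph centrality $\sum_k (A^k)_{ii}/k!$ | symmetric eigendecomposition; contractually equal to the truncated power series |
| NC | $\sum_{v \in N(u)} \mathrm{ECC}(u,v)$ with $\mathrm{ECC}=z_{uv}/\min(d_u-1,d_v-1)$ | $z_{uv}$ = triangles on the edge; ECC is 0 when the denominator is 0 |

Rankings are descending with lexicographic tie-breaks (recorded in the
object), so every run is reproducible.

A protein becomes a **candidate** when it is gold-standard essential,
reaches the top $K$ under at least one of DC/NC/SC in *both* augmented
networks, and is absent from the top $K$ under *every* method in the
original network. Candidates whose original-network rank exceeds a
threshold $R$ under **all** methods are flagged *deep-ranked*: these
are the proteins whose essentiality was invisible without the
predicted links, and the predicted links incident to them are the
"selected" group. Both quantifiers are configurable
(`topk_rule`, `deep_rule`); the ALL-methods deep-rank default is the
reading consistent with how the method's published candidate tables
are marked. Defaults are $K=200$ and $R=1000$, with $R$ meant to be
lowered when the essential set is small.

Validation looks each selected link up in a confidence-scored
reference interaction set (STRING-style three-column file; duplicate
pairs keep the maximum confidence) and counts links with confidence
$\ge 0.7$ as confirmed. Proteins not in the gold-standard essential
list are counted as non-essential throughout (the "unknown-protein"
policy; only listed proteins ever count as hits).

## Random-walk baselines

Two standard topology-only link predictors provide the comparison:

* **RWR** — random walk with restart, restart probability $c = 0.8$:
  per-seed stationary vectors solving
  $p = (1-c)Wp + c\,e_x$ on the column-normalised adjacency, iterated
  to an L1 tolerance of $10^{-10}$ and symmetrised as
  $s(x,y)=p_x[y]+p_y[x]$. Isolated nodes teleport to themselves.
* **LRW** — local random walk of $t = 3$ steps:
  $s(x,y)=q_x\pi_x(t)[y]+q_y\pi_y(t)[x]$ with $q_x = d_x/2|E|$. The
  exact-$t$ variant is the default; the superposed variant (summing
  steps $1..t$) sits behind a flag because the literature uses both.

Baselines select the top-scored unlinked pairs at the same proportion
of $|E|$ as stage 1, ties again broken lexicographically. Further
scorers (e.g. supervised or resistance-based walks) can be registered
by any function returning the same symmetric score-matrix contract.

## The synthetic benchmark

Because the method's real inputs (a curated PPI network, an expression
compendium, a GO release, a reference interaction database) are
external, the package ships a seeded generator whose defaults define
the evaluation conditions used throughout the tests: 300 proteins in a
preferential-attachment graph (2 links per arriving node), 10% of
edges hidden, 36 expression samples, planted correlation
$\rho = 0.99$ on hidden pairs, and an 8-subtree toy ontology of depth
6 with 12 leaves per subtree.

Hidden edges are organised into *modules* that share one latent
expression factor and a triplet of deep sibling GO leaves — the
generative picture is a protein complex whose members co-express and
share specific annotations. Two hiding policies exist:

* `"matching"` (default): hidden edges form a matching (no protein in
  two modules), so each hidden pair has population correlation exactly
  $\rho$; no node is ever isolated.
* `"essential-biased"`: modules are stars centred on mid-tier
  essential proteins (the very top hubs would retain too much degree
  to ever leave the top ranks), hiding all but two of each seed's
  edges. This is the scenario in which stage-2 selection is
  exercised: the seeds crash in the original ranking and are rescued
  only by the predicted links. A side effect worth knowing about is
  that the star's partners also correlate with one another, so stage 1
  predicts partner–partner pairs that are *not* truth edges — which is
  precisely what makes the selected (candidate-incident) group
  validate at a much higher rate than the total prediction, the
  qualitative contrast the method is built around.

Annotations are coherent per protein: every protein draws its leaves
from a single "home" subtree (its module's subtree when it has one).
Without this coherence, the set-based similarity of hub proteins
dilutes towards zero as annotations accumulate — real annotation sets
are hierarchically clustered in just this way, and the toy model
reproduces that property rather than the pathology. The reference set
scores truth edges $\mathrm{Uniform}(0.7, 1)$ except a 5%
false-negative fraction below 0.7, plus an equal number of decoy
non-edges at $\mathrm{Uniform}(0, 0.7)$, so the 0.7 confidence cut is
exercised in both directions.

What the generator does *not* emulate: yeast-scale networks and degree
distributions, correlated measurement noise across expression samples,
evidence codes and annotation bias in the GAF, or false positives in
the observed network itself. Passing the planted-recovery tests
therefore demonstrates the machinery is correct and the method behaves
as designed when its assumptions hold — not that the same precision
would be obtained on real data.

## Numerical choices

* S-values are computed by best-first relaxation over the ancestor
  subgraph (a max-product shortest path); tested against exhaustive
  path enumeration on random DAGs to $10^{-12}$.
* SC uses the symmetric eigendecomposition; on sparse test graphs the
  25-term power series agrees to well below $10^{-8}$.
* RWR iterates all seeds simultaneously as one matrix fixed point;
  tested against the direct solve
  $c\,(I-(1-c)W)^{-1}$ to $10^{-8}$, and stationary columns sum to 1
  within $10^{-8}$.
* Ties anywhere (rankings, top-proportion selection) break
  lexicographically on protein identifier or canonical pair; edge
  storage is canonical with the lexicographically smaller endpoint
  first.
* Degenerate inputs: zero-variance expression rows are undefined and
  score 0; empty candidate sets or empty prediction sets warn and
  yield empty/zero results rather than erroring; an empty reference
  set makes validation fractions `NA` in the pipeline report.

## Problem sizes

The shipped tests and the acceptance script run entirely on the
synthetic conditions above (300-node scenarios; 50-node graphs for the
eigendecomposition contracts; DAGs of up to 30 terms for the
exhaustive oracles; 200 sampled graphs of up to 12 nodes for the
exhaustive DC/NC sweep). These sizes were chosen so that exhaustive,
independently-coded oracles remain feasible for every assertion; the
implementation itself handles networks of tens of thousands of edges,
where the dominant costs are the dense correlation matrix and
betweenness.

## Known limitations

* The GO similarity's set aggregation dilutes for heavily annotated
  proteins; the BMA alternative mitigates but changes the scale.
* Expression thresholds near 1 with few samples make stage 1
  conservative by construction; there is no calibration of scores into
  interaction probabilities.
* Stage 2 requires the essential gold standard to be meaningful on the
  analysed network; with very small essential sets $R$ must be lowered
  (the package does not auto-tune it).
* The pipeline assumes all three rankings live on the same node set;
  proteins absent from a ranking are treated as rank $\infty$.

## A worked run

```{r, eval = FALSE}
sc <- synthetic_scenario(seed = 1, hide_policy = "essential-biased")
paths <- write_scenario(sc, tempdir())
report <- run_pipeline(list(
  network = paths[["observed"]], expression = paths[["expression"]],
  obo = paths[["obo"]], gaf = paths[["gaf"]],
  essential = paths[["essential"]], reference = paths[["reference"]],
  K = 45L, R = 60L, out_dir = tempdir(), seed = 1L))
report
```
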