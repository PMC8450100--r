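---
title: "Building query-specific biomedical knowledge graphs with kgforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building query-specific biomedical knowledge graphs with kgforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgforge)
```

## The problem

Integrated biomedical databases record millions of associations between
genes/proteins, diseases, pathways, phenotypes, drugs and bioactive
compounds. A query such as "show me everything relevant to this disease"
is useless if answered literally: the transitive closure of associations
around almost any starting term covers a large fraction of the database.
kgforge implements a construction pipeline that grows a small, typed
knowledge graph around a user query and, at every expansion step, keeps
only the entities most specifically tied to the graph so far.

The package operates on flat-file collections (TSV plus a JSON manifest)
that mirror the sections of such an integrated resource: a protein table
with per-component annotation lists, a PPI table with confidence scores,
ontology terms for diseases/pathways/phenotypes, drugs with targets and
indications, compounds with structural fingerprints, experimental
bioactivity records, and computationally predicted drug-target
interactions. Everything downstream consumes the association indices a
`kg_datastore` exposes (term to protein-set per component).

## The enrichment score

At each filtering step every candidate term $D$ is scored against the
graph $W$ under construction:

$$E_{D,W} = \frac{m_D^2 / n_W}{M_D / N}$$

where $m_D$ is the number of graph proteins associated with $D$, $n_W$
the number of gene/protein nodes in the graph, $M_D$ the number of
datastore proteins associated with $D$, and $N$ the component total (the
number of datastore proteins carrying at least one association in $D$'s
component). The numerator is the in-graph association density; the
denominator is the background association density of $D$. Squaring $m_D$
deliberately departs from the classical overrepresentation ratio: among
terms with similar relative enrichment it promotes the one with the
higher absolute degree in the graph, which keeps the output connected.
The score also penalises promiscuous hub terms, whose $M_D/N$ approaches
one, so a term annotating most of the proteome must blanket the graph to
compete with a small term whose few associations are all inside the
graph.

Alongside $E$ we report the one-tailed hypergeometric significance

$$S_{D,W} = \sum_{i = m_D}^{n_W} \frac{\binom{M_D}{i}\binom{N - M_D}{n_W - i}}{\binom{N}{n_W}},$$

equivalent to a one-tailed Fisher's exact test. Ranking and selection use
$E$ only; $S$ is reported (for the top 100 candidates per component) so
users can judge whether a ranked term is also statistically surprising.
Filtering is a relevance cut, not an inference, which is also why no
multiple-testing correction is applied.

Numerical notes. The tail is evaluated through `stats::phyper` in its
log-space implementation, not by naive summation; terms with $i > M_D$
vanish under the $\binom{a}{b} = 0$ convention, so the printed upper
limit $n_W$ equals the effective $\min(n_W, M_D)$. Degenerate inputs
($n = 0$ or $M = 0$) yield $E = 0$, $S = 1$: such a term is simply not
enrichable. An empty component ($N = 0$) is an error rather than a
silent zero. Within a ranking, graph proteins carrying no annotation in
the component are excluded from the draw so that $n \le N$ always holds;
as $n$ is a common factor across terms this never reorders candidates.
Ties in $E$ are broken by ascending $S$, then descending $m$, then
lexicographic term id, making every ranking fully deterministic.

## The construction workflow

`build_knowledge_graph()` executes, in order:

1. **Taxon/review filter.** Default: human (taxon 9606), reviewed
   entries only, with an explicit allow-list for unreviewed accessions
   that must be retained.
2. **Core proteins.** Each query term contributes its directly
   associated proteins (a gene/protein term contributes itself); a
   combinatory query continues with the union.
3. **Neighbour expansion.** PPI first-neighbours of the core are scored
   with the same $E$, treating a candidate's partner list as its
   association set ($m$ = core partners, $M$ = total partners, $N$ =
   proteins with at least one PPI); the top $k$ enter as neighbour
   proteins.
4. **Enriched terms.** Pathways, phenotypes and diseases are ranked
   against the full protein set (core and neighbours weighted equally —
   the natural reading of using "the whole gene/protein set") and the
   top $k$ of each are added with their association edges.
5. **Ligands.** Drugs are enriched on their target sets (evidence
   `approved`); the experimental compound pool is assembled and
   diversified (below) with evidence `experimental`; predicted DTIs pass
   through the same selection with evidence `predicted`, spending the
   remaining per-component node budget so the $k$-cap holds across all
   three passes.
6. **Evidence reconciliation.** For every ligand-protein pair reported
   by several sources a single `targets` edge survives, carrying the
   most reliable evidence (`approved` > `experimental` > `predicted`).
   Drugs additionally receive their secondary-evidence edges to graph
   proteins not already covered (experimental bioactivities of the
   drug's compound cross-reference; predictions for the drug or its
   cross-reference). The operation is idempotent.
7. **Cross-component edges.** `indicates` (drug to disease),
   `modulates` (disease to pathway) and `is associated with` (disease to
   phenotype) are attached wherever both endpoints are present and the
   datastore records the relation.
8. **Pruning.** Degree-0 nodes are removed, except query anchors, which
   stay visible even when nothing attaches to them.

The build draws no random numbers; for a given (query, datastore,
parameters) the serialized graph is byte-identical across runs, which
the test suite asserts.

Eight relation types are legal, keyed by endpoint components
(protein-protein `interacts with`, protein-disease `is related to`,
ligand-protein `targets`, protein-pathway `is involved in`,
protein/disease-phenotype `is associated with`, drug-disease
`indicates`, disease-pathway `modulates`); `is ortholog of` is accepted
in the vocabulary for imported curated graphs but never emitted by the
automatic pipeline. Edge evidence is present exactly on `targets` edges.

## Compound selection

Bioactivity records are first reduced to the comparable core: single-
protein targets, assay organism in the configured taxa, standard types
in {IC50, EC50, AC50, XC50, Ki, Kd, Potency} (case-insensitive), and a
recorded pChEMBL value of at least 5 — i.e. a half-maximal activity of
10 µM or better, the conventional boundary of the active binding range.

Even after filtering, a protein set can retain tens of thousands of
compound candidates, so the pool is sized by an iterative cutoff scan:
start at pChEMBL 8; if the first run returns fewer than 1000 distinct
compounds, lower the cutoff in steps of 0.5 (never below the floor of
5) until at least 1000 are gathered; if it returns more than 2500,
raise it stepwise until at most 2500 remain. The direction is keyed on
the first run and the count is monotone in the cutoff, so the scan
terminates at the first admissible cutoff whenever one exists on the
grid; otherwise the floor (or the iteration cap of 20) is accepted and
flagged. The step size and iteration cap are this package's choices —
the bounds and the starting cutoff define the procedure. The bounds
count distinct compounds, the stricter reading of "compound entries"
(configurable).

Pooled compounds are ranked by enrichment ($m$, $M$ over the
pool-cutoff bioactivity associations) and then diversified: compounds
are clustered on ECFP4-style fingerprint Tanimoto similarity at 0.5,
and the ranking is walked best-first, discarding any compound whose
cluster is already represented in the graph or earlier in the
selection. This prevents filling the compound budget with same-scaffold
analogues that earned near-identical scores in the same assay. A
selected compound that is the cross-reference of a drug node already in
the graph is merged into that drug node (drugs carry stronger evidence
than candidate compounds), with its bioactivity edges attached there.

Clustering uses leader (representative-based) clustering over a
canonical visiting order (descending on-bit count, then id): each
compound joins the first representative within the threshold or founds
a cluster. The enforced contract is member-to-representative similarity
at or above the threshold; full within-cluster clique similarity is not
guaranteed. Leader clustering costs O(compounds × clusters) and is
permutation-invariant by construction; single-linkage connected
components are available behind `cluster_method = "single_linkage"` as
a quadratic sensitivity check. Fingerprints are supplied precomputed in
the compounds table (on-bit indices plus width), so the package needs
no chemistry toolkit; any binary fingerprint of consistent width works.

An optional absolute threshold pair (`ligand_min_E = 1`,
`ligand_max_S = 0.05`) reproduces the stricter ligand admission used
for curated infectious-disease graphs; both are off by default.

## Diversity and stability analyses

`node_identity()` and `kg_identity_matrix()` measure content overlap
between graphs by node identifier and component. Because a headline
identity percentage is meaningless without its denominator, the
convention is always recorded: `jaccard` (shared over union, default),
`min` (shared over the smaller graph) and `mean` are provided.

`term_frequency_analysis()` tests whether a term appears across a graph
collection more or less often than its connectivity predicts. The
expected frequency of term $D$ is $t \cdot M_D / M_{sum}$, with $t$ the
per-component node budget of the builds, and $M_{sum}$ the total number
of protein associations in $D$'s component. Observed is $g_D/G$ over
$G$ graphs. Significance comes from a one-tailed Fisher's exact test on
the pseudo-table $[g, G-g; \mathrm{round}(G \cdot e), G -
\mathrm{round}(G \cdot e)]$; constructing a contingency table from an
expected frequency is genuinely under-determined, so the rounded-count
table is the documented choice and an exact binomial test
($g \sim \mathrm{Bin}(G, e)$) is available via `method = "binomial"`.
Expected frequencies above 1 (possible for extreme hubs) are clamped
with a warning; a hub blanket-annotating the proteome "should" appear
in every graph, and any shortfall below certainty is evidence of
suppression.

## The synthetic datastore

`generate_datastore()` emulates structure, not content. Its defaults
are the package's reference conditions: 200 proteins in 10 functional
modules (85% human, 5% unreviewed); PPIs with mean degree 4
concentrated (90%) within modules plus two promiscuous hub proteins
touching half the proteome; per ontology component, 15 module-specific
terms per module each annotating 8 module proteins, plus two hub terms
annotating 80% of all proteins; 150 module-specific drugs (4 targets
each) plus two hub drugs; 60 compounds in 10 planted scaffold clusters;
bioactivities with pChEMBL uniform on [4, 10] so both the activity
floor and the cutoff scan have bite, with 5% off-type, 5% missing-value
and 5% non-single-target records to exercise every filter. The module
structure is what makes the generator informative: real annotation data
is correlated (disease genes share pathways and interaction partners),
and without that correlation specific terms would never accumulate the
in-graph degree that lets them outrank hubs.

Scaffold clusters are planted by sampling a 64-bit-on seed fingerprint
(width 1024) per cluster and replacing a fraction $f$ of each member's
scaffold bits with fresh bits. Two members then share an expected
$(1-f)^2$ of the scaffold, giving expected pairwise Tanimoto
$t = (1-f)^2 / (2 - (1-f)^2)$; inverting, $(1-f)^2 = 2t/(1+t)$, which
for the default within-cluster target of 0.7 gives $f \approx 0.093$.
Cross-cluster similarity for independent sparse fingerprints is around
$b/W \approx 0.03$, far below the 0.5 clustering threshold.

What passing tests on this generator do and do not show: they establish
that the pipeline's selection logic behaves as designed under
controlled association structure (hub suppression, cluster recovery,
cap enforcement, determinism). They do not certify behaviour on real
databases, whose annotation biases, degree distributions and ontology
depths are far messier than ten clean modules.

## Reference experiment sizes

The packaged analyses run at desk scale, chosen so the whole suite
stays fast while every statistical claim is still testable: the hub
suppression experiment builds 200 graphs (33 random single-term queries
per component plus 2 combinatory queries) over the default 200-protein
datastore and tests the 8 planted hubs at $t = 10$; the pool-bound
experiment uses 5000 compounds against 20 targets with pChEMBL uniform
on [5, 10]; the enumeration oracle for the hypergeometric tail covers
every universe up to $N = 15$ exhaustively.

## Known limitations

* Collections are loaded whole into memory; the design targets
  desk-scale slices, not a production database.
* Leader clustering guarantees member-representative similarity only;
  a cluster's diameter can exceed the threshold.
* Name resolution is exact (id, then name, then case-folded name);
  there is no fuzzy matching, and ambiguity is an error by design.
* The layout emits coordinates only; rendering is left to downstream
  tools (Cytoscape, igraph plotting).
* `is ortholog of` edges are accepted on import but never inferred.

## A worked example

```{r example}
ds <- synth_datastore(synth_params(rng_seed = 11))
graph <- build_knowledge_graph(query_spec(gene = "P0003"), ds)
graph
head(graph$report$disease[, c("term_id", "m", "M", "E", "S", "included")])
```

The report shows the enrichment ranking behind the disease layer:
small-$M$ module terms with several graph associations dominate, while
the planted hubs (ids containing `HUB`), despite their large $m$, fall
below the inclusion cut.
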