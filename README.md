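# ontorank

Ontology-based relevance ranking of biomedical articles, with adaptive
edge reweighting that encodes the *intention* behind a multi-article query.

## The problem

Keyword search over the protein structure/function literature fails when two
articles discuss the same biology in different vocabulary. If articles are
annotated with concepts from curated hierarchies — Gene Ontology (GO) terms
for function, the six-level SCOP classification (class, fold, superfamily,
family, protein, species) for structure, MeSH descriptors for medical
topics — relevance can instead be measured on the hierarchies themselves.
And when a user supplies *several* query articles, what the articles have in
common reveals which aspect of the initial article the user cares about;
the ranking should adapt to it.

`ontorank` implements that scheme for R: hierarchy parsing (OBO, SCOP
classification listings, MeSH ASCII descriptors), concept and document
relevance, intention-driven edge reweighting, corpus ranking, and the
co-citation evaluation protocol, plus a synthetic fixture generator so that
everything runs without downloading any ontology release.

## The model

**Concept relevance.** For concepts *t₁*, *t₂* on a hierarchy *H* with depth
*d(H)* (longest root-to-node path, in edges):

    d(H, t1, t2) = 2 d(H) − [ P(t1, cp) + P(t2, cp) ]

where *cₚ(t₁,t₂)* is the lowest common ancestor and *P(t, cₚ)* the path
length from *t* up to it — among the paths with the fewest edges, the
minimum total edge length (each edge has length 1 by default). Identical
concepts score the maximum 2 *d(H)*; concepts sharing no ancestor score 0.

**Document relevance.** For a query article *D₁* and a target *D₂*,
each viewpoint sums best-match concept relevances,

    d_GO(H, D1, D2) = Σ_{t1 ∈ GO(D1)} ω_{t1} · max_{t2 ∈ GO(D2)} d(H, t1, t2)

with user weights *ω* on GO terms, all weights 1 on SCOP leaves, and a
Major-Topic factor (default 2) on MeSH descriptors. Normalizing by
Σω · 2 *d(H)* makes the three viewpoints commensurable; the combined score
is their weighted mean.

**Intention feedback.** Additional query articles *L₁..Lₘ* reweight the
hierarchy: for every concept pair (t₁ ∈ initial, t₂ ∈ additional), the edges
*E(t₁,t₂)* on the shortest paths through their common ancestor receive
weight ω(e) = 1 − S(t₁,t₂), where S = exp(−α·l)·tanh(β·hc) is a hybrid
path-length/ancestor-depth similarity (α = 0.2, β = 0.6 by default).
Similar concepts thus *shorten* the paths that connect them, raising the
relevance of every article annotated near those paths. AND-search keeps
only edges common to all additional articles' edge sets, OR-search their
union; conflicting weights on one edge resolve to the smallest.

**Evaluation.** An article is *correct* for a query pair if it is cited by
at least one article co-citing the pair. Rankings are summarised by
precision–recall curves, average precision (AP) and mean average precision
(MAP).

## Worked example

```r
library(ontorank)

f <- worked_example_fixture()          # depth-4 cell-cycle hierarchy
hierarchy_depth(f$hierarchy)
#> [1] 4
best_common_ancestor(f$hierarchy, f$t1, f$t2)
#> Common ancestor 'cell cycle control': path lengths 2 and 1
concept_relevance(f$hierarchy, f$t1, f$t2)
#> [1] 5
```

"M/G1 Transition" and "cell cycle arrest" sit 2 and 1 edges below their
lowest common ancestor on a depth-4 hierarchy, so their relevance is
2 × 4 − (2 + 1) = 5.

End-to-end on a synthetic corpus with a planted relevant cluster:

```r
spec  <- synthetic_spec(seed = 7, n_articles = 20)
h_go  <- generate_hierarchy(spec, "GO")
h_sc  <- generate_scop_hierarchy(spec)
h_me  <- generate_hierarchy(synthetic_spec(seed = 107), "MESH")
cx    <- generate_corpus(spec, h_go, h_sc, h_me)

rel <- cocitation_relevant_set(cx$citations, cx$query[1], cx$query[2])
r   <- rank_corpus(cx$query[1], cx$query[2], cx$corpus,
                   list(go = h_go, scop = h_sc, mesh = h_me), mode = "or")
print(r, n = 5)
#> Article ranking: initial 'art001' + 1 additional (OR-search), 18 candidates
#>  rank article_id combined go_raw go_norm scop_raw scop_norm mesh_raw mesh_norm
#>     1     art006   0.9021  38.70  0.8062   12.000   1.00000    54.01    0.9002
#>     2     art005   0.8982  41.73  0.8695   12.000   1.00000    49.50    0.8251
#>     3     art003   0.8191  41.11  0.8564    8.884   0.74033    51.62    0.8604
#>     4     art007   0.8172  39.22  0.8171    8.884   0.74033    53.66    0.8943
#>     5     art004   0.8128  39.23  0.8174    8.884   0.74033    52.85    0.8808
average_precision(r, rel)
#> [1] 1
```

The five planted articles (`art003`–`art007`) occupy the top five ranks, so
AP = 1: the additional article's concepts pulled the planted cluster — which
shares the query pair's common concept neighbourhood — above the background.
The per-viewpoint columns show raw sums and their normalized values in
[0, 1].

The bundled benchmark table of 30 published query pairs:

```r
tab <- retrieval_ap_benchmark()
mean_average_precision(tab$proposed)   # 0.7256667  -> 0.725 at 3 decimals
mean_average_precision(tab$pubmed)     # 0.6606667  -> 0.660 at 3 decimals
```

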