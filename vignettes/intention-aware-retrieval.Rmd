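---
title: "Concept-hierarchy relevance and intention-aware article retrieval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concept-hierarchy relevance and intention-aware article retrieval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontorank)
```

## The model

`ontorank` scores articles by where their annotated concepts sit on curated
hierarchies. Three viewpoints are supported, each with its own hierarchy:
gene-product function (GO, restricted to `is_a` edges), protein structure
(the six-level SCOP classification tree) and medical topic (MeSH
descriptors linked through their tree numbers). All three are represented
uniformly as rooted DAGs of child-to-parent edges.

The relevance of two concepts is

$$d(H, t_1, t_2) = 2\,d(H) - \bigl[P(t_1, c_p) + P(t_2, c_p)\bigr],$$

where $d(H)$ is the hierarchy depth, $c_p$ the lowest common ancestor of
$t_1$ and $t_2$, and $P$ a path length. The intuition: two concepts are
related to the extent that their common ancestor is specific, and close to
both. Identical concepts attain the maximum $2\,d(H)$; concepts sharing
only disjoint roots (e.g. GO terms from different namespaces) score 0
rather than raising an error, so mixed annotations degrade gracefully.

Document-level relevance between a query article $D_1$ and a target $D_2$
sums, for each query concept, the relevance of its best-matching target
concept, weighted by a per-concept weight: user-assigned weights for GO,
all ones for SCOP, and a Major-Topic factor (default 2) for MeSH. Scores
are normalized by their attainable maximum $\sum\omega \cdot 2 d(H)$ and
combined across viewpoints as a weighted mean, with empty viewpoints
dropped and the mix renormalized.

### Assumptions worth stating

* **Best-match inner aggregation.** The inner aggregation over the target's
  concepts uses the maximum, so a target annotated with many concepts is
  not rewarded for sheer annotation count. A `agg = "sum"` switch exists
  for sensitivity checks.
* **Asymmetry.** Document relevance is oriented query → target: weights
  come from the query article, and the best-match runs over the target's
  concepts. Swapping the arguments can change the score.
* **Global depth.** $d(H)$ is the depth of the full hierarchy, not of the
  ancestry sub-hierarchy extracted around the two concepts; the extracted
  sub-hierarchy (`extract_isa_ancestry()`) exists for display and
  inspection. Using the global depth keeps relevances of different concept
  pairs on one scale, which matters because document scores compare and sum
  them.

## Path semantics and numerical choices

$P(t, a)$ is defined in two stages: among all upward paths with the fewest
edges, take the minimum total edge length, where an edge's length is its
entry in the current weight map (1.0 when absent). With unit weights this
is plain hop count; with weights it stays anchored to the same geodesics,
which is what lets reweighting only ever *shorten* paths (weights are
capped at 1). The implementation is a layered BFS with a dynamic program
over the hop-shortest predecessor structure; tests compare it against
exhaustive path enumeration.

On DAGs many common ancestors can tie. `best_common_ancestor()` minimizes
the weighted path-length total, breaking ties by greater node depth
(longest root-to-node path), then lexicographically smaller id — fully
deterministic, and the depth tie-break prefers the more specific ancestor,
consistent with the relevance measure's intuition.

Degenerate inputs are handled explicitly: a concept paired with itself
skips the ancestor search ($P = 0$ both ways); empty annotation sets yield
a zero score carrying an `empty` flag so the combination step can exclude
the viewpoint; unresolvable concept ids are skipped with a warning rather
than failing a whole ranking.

## Intention feedback: edge reweighting

With additional query articles, every concept pair $(t_1, t_2)$ drawn from
the initial and an additional article assigns to each edge of
$E(t_1, t_2)$ — the edges on hop-shortest paths through their best common
ancestor — the candidate weight $\omega(e) = 1 - S(t_1, t_2)$, keeping the
smallest candidate per edge. AND-search intersects the per-article edge
sets, OR-search unites them; both resolve conflicts with the minimum. The
similarity is

$$S(t_1, t_2) = e^{-\alpha l}\,\tanh(\beta\,h_c),$$

with $l$ the unit-weight path length through the common ancestor and $h_c$
the ancestor's depth. Two properties motivated this hybrid form: similarity
should decay with distance between the concepts, and it should account for
*where* the common ancestor sits — sharing a deep, specific ancestor means
much more than sharing the root ($S = 0$ there, since $\tanh 0 = 0$).

Tunable parameters, their defaults, and why:

| parameter | default | role |
|---|---|---|
| `alpha` | 0.2 | path-length decay; at 0.2 a 3-edge separation still keeps ~55% of the depth term, so reweighting reaches beyond immediate neighbours |
| `beta` | 0.6 | depth saturation; $\tanh(0.6 h_c)$ passes 0.5 at depth 1 and saturates near depth 4–5, the regime of real ontology LCA depths |
| `eps` | 0.01 | floor on edge weights; keeps lengths positive so the path metric stays non-degenerate |
| `major_topic_factor` | 2 | MeSH Major-Topic descriptors count double in the query article |
| `mix` | equal | per-viewpoint combination weights |

Because every kept weight lies in $[\varepsilon, 1]$, reweighted path
lengths never exceed unit-weight lengths and every relevance is at least
its baseline value — reweighting can only promote, never demote. The
acceptance suite asserts this monotonicity on random weight maps.

## What the synthetic generator emulates

`generate_corpus()` reproduces the *shape* of the retrieval experiment
without any external data. The planted query pair shares a concept
neighbourhood; a planted cluster of "relevant" articles draws concepts from
the region around the paths connecting the pair's concepts — exactly the
edges the intention mechanism reweights; half of the background is
distractors drawing from the initial article's neighbourhood *off* those
paths (relevant-looking at unit edge lengths), the rest uniform. The
citation graph contains one co-citer citing exactly the planted cluster,
so the co-citation ground truth is recovered constructively, plus
non-co-citing noise citers.

This emulation supports two kinds of conclusions: that the machinery is
correct (oracle equivalence, recovery guarantees), and that the qualitative
mechanism works — with the additional article, mean AP over seeded
replicates rises significantly (sign test across 20 seeds), because the
distractors do not benefit from the reweighted paths while the planted
cluster does. It does **not** show that real GO/SCOP/MeSH annotations have
the statistical structure of the generator: real annotation sets are
correlated across viewpoints, unevenly deep, and sparse in ways the
uniform sampler is not, so absolute AP values here say nothing about
performance on a real corpus. The default study sizes — hierarchies of 60
concepts (depth 6), SCOP trees of six levels, corpora of 40 articles with
4 concepts per viewpoint and a planted cluster of 5 — keep replicated runs
cheap while leaving room for rank movement; they are stated in
`synthetic_spec()` and used by the test suite as-is.

The bundled 30-pair AP benchmark (`retrieval_ap_benchmark()`) is a
transcription of a published comparison against a keyword-search baseline;
its column means reproduce the published MAP values (0.725 / 0.660) at the
table's printed 3-decimal precision. The baseline ranking itself is not
reimplemented — it came from an external search engine — but
`read_ranking_tsv()` accepts any externally produced ranking for
evaluation against the same ground truth.

## Open design points, resolved

* **Inner aggregation of document relevance** (max vs. sum): max, so the
  score is independent of the target's annotation count; configurable.
* **Similarity-to-weight mapping**: $\omega = 1 - S$, because more similar
  concept pairs must shorten their connecting paths more; clamped to
  $[\varepsilon, 1]$.
* **Cross-article conflicts**: the within-set minimum rule is extended
  across additional articles' maps, keeping AND/OR combination commutative
  and associative.
* **Initial-article user weights in the similarity**: they do not enter
  $S$; user weights express emphasis for scoring (the document sums), not
  evidence of concept similarity.
* **Query pair in the ground truth**: the pair itself is excluded from
  both the relevant set and the ranked universe — the query articles are
  inputs, not retrieval targets.

## Known limitations

`part_of` and other non-`is_a` GO relations are ignored by design; GO
evidence codes, MeSH qualifiers and SCOPe/CATH are out of scope. The edge
enumeration in $E(t_1, t_2)$ and the path DP are exact but enumerate the
ancestor closure per query; on full-size GO (~45k terms) per-pair queries
remain fast, but corpus-scale ranking benefits from the fact that only the
query article's concepts appear on the outer loop. Rankings are
deterministic (ties broken by article id), so two runs on identical inputs
are byte-identical.
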