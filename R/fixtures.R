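# Synthetic fixtures: the worked-example hierarchy, random DAG hierarchies,
# and annotated corpora with planted co-citation structure. Everything is
# generated in code; no external ontology releases are needed.

#' The cell-cycle worked-example hierarchy
#'
#' A fixed GO-flavoured hierarchy of depth 4 around cell-cycle regulation:
#' "M/G1 Transition" sits two is_a edges below "cell cycle control" and
#' "cell cycle arrest" one edge below it, so their lowest common ancestor is
#' "cell cycle control" with path lengths 2 + 1, giving concept relevance
#' 2 x 4 - 3 = 5 under unit edge lengths.
#'
#' @return list with `hierarchy` (a `concept_hierarchy`), `t1`
#'   ("M/G1 Transition"), `t2` ("cell cycle arrest") and `ancestor`
#'   ("cell cycle control").
#' @export
worked_example_fixture <- function() {
  concepts <- data.frame(
    id = c("biological process", "cell cycle", "cell cycle control",
           "cell cycle arrest", "cell cycle phase transition",
           "M/G1 Transition"),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    child = c("cell cycle", "cell cycle control", "cell cycle arrest",
              "cell cycle phase transition", "M/G1 Transition"),
    parent = c("biological process", "cell cycle", "cell cycle control",
               "cell cycle control", "cell cycle phase transition"),
    stringsAsFactors = FALSE
  )
  list(hierarchy = concept_hierarchy(concepts, edges, source = "SYNTHETIC"),
       t1 = "M/G1 Transition", t2 = "cell cycle arrest",
       ancestor = "cell cycle control")
}

#' Specification for synthetic generation
#'
#' Bundles the knobs of the synthetic generators; identical spec + seed
#' yields identical output.
#'
#' @param n_concepts concepts per generated hierarchy (>= 1).
#' @param max_parents maximum parents per concept (>= 1; 1 gives a tree).
#' @param target_depth hierarchy depth to reach (<= n_concepts - 1).
#' @param n_articles corpus size including the two query articles.
#' @param concepts_per_article annotated concepts per article and viewpoint.
#' @param planted_cluster_size number of planted relevant articles.
#' @param seed integer random seed.
#' @return class `synthetic_spec` (a list).
#' @export
synthetic_spec <- function(n_concepts = 60, max_parents = 2,
                           target_depth = 6, n_articles = 40,
                           concepts_per_article = 4,
                           planted_cluster_size = 5, seed = 1) {
  s <- list(n_concepts = as.integer(n_concepts),
            max_parents = as.integer(max_parents),
            target_depth = as.integer(target_depth),
            n_articles = as.integer(n_articles),
            concepts_per_article = as.integer(concepts_per_article),
            planted_cluster_size = as.integer(planted_cluster_size),
            seed = as.integer(seed))
  stopifnot(s$n_concepts >= 1, s$max_parents >= 1, s$target_depth >= 0,
            s$n_articles >= 2, s$concepts_per_article >= 1,
            s$planted_cluster_size >= 0)
  if (s$target_depth > s$n_concepts - 1L) {
    stop("infeasible spec: target_depth exceeds n_concepts - 1")
  }
  if (s$n_articles < 2L + s$planted_cluster_size) {
    stop("infeasible spec: corpus too small for the planted cluster")
  }
  class(s) <- "synthetic_spec"
  s
}

# run fn with a private RNG state seeded from `seed`
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate a random concept hierarchy
#'
#' A single-rooted DAG: a backbone chain realises the target depth, every
#' other concept attaches to one primary parent one level up plus up to
#' `max_parents - 1` extra parents at shallower levels, so concept depth
#' equals its level and overall depth equals `target_depth`.
#'
#' @param spec a `synthetic_spec` (fields `n_concepts`, `max_parents`,
#'   `target_depth`, `seed` are used).
#' @param source provenance tag for the result.
#' @return a `concept_hierarchy`.
#' @export
generate_hierarchy <- function(spec, source = "SYNTHETIC") {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_concepts
  td <- min(spec$target_depth, n - 1L)
  if (td == 0L && n > 1L) {
    stop("infeasible spec: a single-rooted hierarchy with more than one ",
         "concept cannot have depth 0")
  }
  ids <- sprintf("C%03d", seq_len(n))
  with_seed(spec$seed, function() {
    level <- integer(n)
    level[seq_len(td + 1L)] <- 0:td            # backbone chain
    if (n > td + 1L) {
      level[(td + 2L):n] <- sample(seq_len(td), n - td - 1L, replace = TRUE)
    }
    child <- character(); parent <- character()
    for (i in seq_len(n)) {
      if (i == 1L) next
      upper <- which(level == level[i] - 1L & seq_len(n) < i)
      if (!length(upper)) upper <- 1L
      ps <- upper[sample.int(length(upper), 1L)]
      extra <- spec$max_parents - 1L
      if (extra > 0L) {
        pool <- setdiff(which(level < level[i] & seq_len(n) != i), ps)
        if (length(pool)) {
          k <- sample.int(min(extra, length(pool)) + 1L, 1L) - 1L
          if (k > 0L) ps <- c(ps, pool[sample.int(length(pool), k)])
        }
      }
      child <- c(child, rep(ids[i], length(ps)))
      parent <- c(parent, ids[ps])
    }
    concept_hierarchy(
      data.frame(id = ids, name = ids, stringsAsFactors = FALSE),
      data.frame(child = child, parent = parent, stringsAsFactors = FALSE),
      source = source
    )
  })
}

# deepest non-root concepts make realistic annotation candidates
annotation_pool <- function(h) {
  pool <- setdiff(h$ids, h$roots)
  if (!length(pool)) h$ids else pool
}

# concepts on/near the unit-length LCA paths between two concept sets:
# the nodes touched by E(t1, t2) plus their children (one step down)
path_region <- function(h, ids_a, ids_l) {
  nodes <- character()
  for (t1 in ids_a) {
    for (t2 in ids_l) {
      e <- weighted_edge_set(h, t1, t2)
      nodes <- c(nodes, e$child, e$parent)
    }
  }
  nodes <- unique(nodes)
  unique(c(nodes, unlist(h$children[nodes], use.names = FALSE)))
}

#' Generate an annotated corpus with planted co-citation structure
#'
#' Builds `n_articles` annotated articles over the three hierarchies. The
#' first two articles form the planted query pair (a1 = initial, a2 =
#' additional): their concepts are drawn from a common neighbourhood so
#' their annotation sets share ancestry. `planted_cluster_size` "relevant"
#' articles draw their concepts from the region around the paths connecting
#' a1's and a2's concepts — exactly the edges the intention mechanism
#' reweights. Half of the background articles are distractors drawing from
#' a1's ancestral neighbourhood off those paths (relevant-looking at unit
#' edge lengths but not reflecting the pair's shared topic), the rest
#' sample uniformly. The citation graph contains one article co-citing the
#' pair and citing exactly the planted cluster, so
#' [cocitation_relevant_set()] recovers it, plus non-co-citing noise
#' citers.
#'
#' @param spec a `synthetic_spec`.
#' @param h_go,h_scop,h_mesh the three hierarchies (`h_scop` must be a
#'   six-level classification tree, e.g. from [parse_scop_classification()]
#'   or [generate_scop_hierarchy()]).
#' @return list with `corpus` (named list of `article_annotation`),
#'   `citations` (a `citation_graph`), `query` (c(a1, a2)) and `relevant`
#'   (the planted article ids).
#' @export
generate_corpus <- function(spec, h_go, h_scop, h_mesh) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_articles
  k <- spec$planted_cluster_size
  m <- spec$concepts_per_article
  art <- sprintf("art%03d", seq_len(n))
  a1 <- art[1]; a2 <- art[2]
  planted <- if (k > 0) art[2L + seq_len(k)] else character()

  scop_leaves <- h_scop$ids[vapply(h_scop$children, length, 1L) == 0L]
  scop_leaves <- setdiff(scop_leaves, h_scop$roots)

  with_seed(spec$seed + 1L, function() {
    sample_some <- function(pool, size) {
      pool <- unique(pool)
      pool[sample.int(length(pool), min(size, length(pool)))]
    }
    # query pair: a2 samples from the ancestral neighbourhood of a1's
    # concepts so the pair shares structure without being identical
    dag_ann <- function(h) {
      pool <- annotation_pool(h)
      c1 <- sample_some(pool, m)
      near <- unique(unlist(lapply(c1, function(t)
        ancestor_set(h, t)), use.names = FALSE))
      near <- unique(c(near, unlist(h$children[near], use.names = FALSE)))
      near <- setdiff(near, c(h$roots, c1))
      c2 <- sample_some(if (length(near) >= m) near else pool, m)
      region <- setdiff(path_region(h, c1, c2), h$roots)
      # distractor pool: near the initial article but off the query paths
      offpath <- setdiff(near, region)
      if (length(offpath) < m) offpath <- setdiff(pool, region)
      list(c1 = c1, c2 = c2, region = region, offpath = offpath, pool = pool)
    }
    go <- dag_ann(h_go); mesh <- dag_ann(h_mesh)
    # SCOP: the pair shares a family (preferring one with several species);
    # planted articles stay in that family, distractors leave it
    fams <- unique(vapply(scop_leaves, function(l)
      h_scop$parents[[h_scop$parents[[l]][1]]][1], ""))
    fam_size <- vapply(fams, function(f) sum(vapply(scop_leaves, function(l)
      f %in% ancestor_set(h_scop, l), TRUE)), 1L)
    big <- fams[fam_size >= 2L]
    fam <- if (length(big)) sample_some(big, 1L) else sample_some(fams, 1L)
    fam_leaves <- scop_leaves[vapply(scop_leaves, function(l)
      fam %in% ancestor_set(h_scop, l), TRUE)]
    leaf1 <- sample_some(fam_leaves, 1L)
    leaf2 <- sample_some(setdiff(fam_leaves, leaf1), 1L)
    if (!length(leaf2)) leaf2 <- leaf1
    other_leaves <- setdiff(scop_leaves, fam_leaves)
    if (!length(other_leaves)) other_leaves <- scop_leaves

    draw <- function(v, kind) {
      # planted: on-path region; distractor: near initial, off the paths
      pool <- switch(kind, planted = v$region, distractor = v$offpath,
                     v$pool)
      if (!length(pool)) pool <- v$pool
      base <- sample_some(pool, max(1L, m - 1L))
      c(base, sample_some(setdiff(v$pool, base), m - length(base)))
    }
    bg <- setdiff(art[-(1:2)], planted)
    distractors <- bg[seq_len(length(bg) %/% 2L)]
    corpus <- list()
    for (i in seq_len(n)) {
      id <- art[i]
      kind <- if (id %in% planted) "planted"
              else if (id %in% distractors) "distractor" else "background"
      if (i == 1L) {
        g <- go$c1; me <- mesh$c1; sc <- leaf1
      } else if (i == 2L) {
        g <- go$c2; me <- mesh$c2; sc <- leaf2
      } else {
        g <- draw(go, kind)
        me <- draw(mesh, kind)
        sc <- switch(kind,
                     planted = sample_some(fam_leaves, 1L),
                     distractor = sample_some(other_leaves, 1L),
                     sample_some(scop_leaves, 1L))
      }
      corpus[[id]] <- article_annotation(
        id,
        go = weighted_concept_set(g),
        scop = weighted_concept_set(sc),
        mesh = weighted_concept_set(me, major = c(TRUE, rep(FALSE,
                                                            length(me) - 1L)))
      )
    }
    # citation graph: one co-citer covering the planted set exactly, plus
    # noise citers that never co-cite the pair
    citing <- character(); cited <- character()
    cc <- "cociter01"
    citing <- c(citing, rep(cc, 2L + k))
    cited <- c(cited, a1, a2, planted)
    bg <- setdiff(art, c(a1, a2, planted))
    if (length(bg) >= 2L) {
      citing <- c(citing, rep("noise01", 2L), rep("noise02", 2L))
      cited <- c(cited, a1, bg[1], a2, bg[2])
    }
    list(corpus = corpus,
         citations = citation_graph(citing, cited),
         query = c(a1, a2),
         relevant = planted)
  })
}

#' Generate a synthetic six-level SCOP-like tree
#'
#' A strict classification tree (class / fold / superfamily / family /
#' protein / species) under one root, with a branching factor drawn to
#' reach roughly `n_concepts` nodes.
#'
#' @param spec a `synthetic_spec` (`n_concepts` and `seed` are used).
#' @return a `concept_hierarchy` with source `"SCOP"`, depth 6.
#' @export
generate_scop_hierarchy <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed + 2L, function() {
    root <- "scop_root"
    ids <- root; child <- character(); parent <- character()
    level_nodes <- root
    b <- 3L   # 1..3 children per node: roughly 2^6 species leaves
    for (lev in seq_along(scop_levels)) {
      nxt <- character()
      for (p in level_nodes) {
        for (j in seq_len(sample(1:b, 1L))) {
          # ids are the slash paths of the six classification components,
          # matching the ids parse_scop_classification() builds from TSV
          nid <- paste0(if (p == root) "" else paste0(p, "/"),
                        substr(scop_levels[lev], 1, 2), j)
          ids <- c(ids, nid)
          child <- c(child, nid); parent <- c(parent, p)
          nxt <- c(nxt, nid)
        }
      }
      level_nodes <- nxt
    }
    concept_hierarchy(
      data.frame(id = ids, name = ids, stringsAsFactors = FALSE),
      data.frame(child = child, parent = parent, stringsAsFactors = FALSE),
      source = "SCOP"
    )
  })
}
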