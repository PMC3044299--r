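# Brute-force oracles, independent of the package internals: everything is
# computed by exhaustive recursive path enumeration over the edge list.

# all upward paths (vectors of node ids) from t; optionally stopping at `to`
oracle_paths_up <- function(h, t, to = NULL) {
  edges <- h$edges
  recurse <- function(path) {
    x <- path[length(path)]
    if (!is.null(to) && x == to) return(list(path))
    ps <- edges$parent[edges$child == x]
    if (!length(ps)) {
      return(if (is.null(to)) list(path) else list())
    }
    out <- if (is.null(to)) list(path) else list()
    for (p in ps) out <- c(out, recurse(c(path, p)))
    out
  }
  recurse(t)
}

# all ancestors of t (t included), from enumerated paths
oracle_ancestors <- function(h, t) {
  unique(unlist(oracle_paths_up(h, t), use.names = FALSE))
}

# hop count and min weighted length among hop-shortest paths from t to a
oracle_path_length <- function(h, t, a, w = NULL) {
  if (t == a) return(list(hops = 0L, plen = 0))
  paths <- oracle_paths_up(h, t, to = a)
  if (!length(paths)) return(NULL)
  hops <- vapply(paths, length, 1L) - 1L
  wtab <- if (is.null(w) || nrow(w) == 0L) NULL else w
  plen_of <- function(p) {
    tot <- 0
    for (i in seq_len(length(p) - 1L)) {
      wt <- 1
      if (!is.null(wtab)) {
        hit <- wtab$child == p[i] & wtab$parent == p[i + 1L]
        if (any(hit)) wt <- wtab$weight[hit][1]
      }
      tot <- tot + wt
    }
    tot
  }
  best <- min(hops)
  list(hops = best,
       plen = min(vapply(paths[hops == best], plen_of, numeric(1))))
}

# longest root-to-node path over all downward walks
oracle_depth <- function(h) {
  down <- function(x) {
    ch <- h$edges$child[h$edges$parent == x]
    if (!length(ch)) return(0L)
    1L + max(vapply(ch, down, 1L))
  }
  roots <- setdiff(h$ids, h$edges$child)
  max(vapply(roots, down, 1L))
}

oracle_node_depth <- function(h, t) {
  paths <- oracle_paths_up(h, t)
  ends <- vapply(paths, function(p) p[length(p)], "")
  roots <- setdiff(h$ids, h$edges$child)
  max(vapply(paths[ends %in% roots], length, 1L)) - 1L
}

# best common ancestor: scan every common ancestor, min weighted total,
# ties by node depth then id
oracle_bca <- function(h, t1, t2, w = NULL) {
  common <- intersect(oracle_ancestors(h, t1), oracle_ancestors(h, t2))
  if (!length(common)) return(NULL)
  tot <- vapply(common, function(a) {
    oracle_path_length(h, t1, a, w)$plen + oracle_path_length(h, t2, a, w)$plen
  }, numeric(1))
  cand <- common[tot == min(tot)]
  if (length(cand) > 1L) {
    dp <- vapply(cand, function(a) oracle_node_depth(h, a), 1L)
    cand <- sort(cand[dp == max(dp)])[1L]
  }
  list(ancestor = cand,
       length_t1 = oracle_path_length(h, t1, cand, w)$plen,
       length_t2 = oracle_path_length(h, t2, cand, w)$plen)
}

oracle_relevance <- function(h, t1, t2, w = NULL) {
  if (t1 == t2) return(2 * oracle_depth(h))
  b <- oracle_bca(h, t1, t2, w)
  if (is.null(b)) return(0)
  2 * oracle_depth(h) - (b$length_t1 + b$length_t2)
}

# union of edges over all hop-shortest paths t -> cp, for t in {t1, t2}
oracle_edge_set <- function(h, t1, t2) {
  if (t1 == t2) return(character())
  b <- oracle_bca(h, t1, t2, NULL)
  if (is.null(b)) return(character())
  keys <- character()
  for (t in c(t1, t2)) {
    if (t == b$ancestor) next
    paths <- oracle_paths_up(h, t, to = b$ancestor)
    hops <- vapply(paths, length, 1L) - 1L
    for (p in paths[hops == min(hops)]) {
      for (i in seq_len(length(p) - 1L)) {
        keys <- c(keys, paste(p[i], p[i + 1L], sep = "\x1f"))
      }
    }
  }
  sort(unique(keys))
}

# keys in row order (align with m$weight); sort separately where needed
map_keys <- function(m) paste(m$child, m$parent, sep = "\x1f")

# random weight map over a fraction of a hierarchy's edges
random_weight_map <- function(h, frac = 0.5, eps = 0.01) {
  ne <- nrow(h$edges)
  if (ne == 0L) return(edge_weight_map())
  k <- max(1L, round(frac * ne))
  pick <- sample.int(ne, k)
  edge_weight_map(h$edges$child[pick], h$edges$parent[pick],
                  stats::runif(k, eps, 1))
}

# small random DAG for oracle comparisons
random_dag <- function(seed, n_max = 25L) {
  n <- sample(4:n_max, 1L)
  generate_hierarchy(synthetic_spec(
    n_concepts = n,
    max_parents = sample(1:3, 1L),
    target_depth = sample(1:min(6L, n - 1L), 1L),
    seed = seed))
}
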