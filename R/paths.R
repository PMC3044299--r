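# Path primitives on a concept hierarchy.
#
# P(t, a) is defined in two stages: among all upward paths from t to its
# ancestor a, take those with the fewest edges (hop-shortest), then the
# minimum total edge length among them, where an edge length is omega(e)
# from the weight map (default 1.0). With an empty map P is just the hop
# count. The two-stage definition keeps the weighted measure anchored to the
# same geodesics as the unit-length one.

# Upward BFS from t. Returns hop count to every ancestor (t included) and,
# via a layered DP, the minimum weighted length among hop-shortest paths.
ancestor_paths <- function(h, t, w = NULL) {
  lut <- if (is.null(w)) stats::setNames(numeric(0), character(0)) else weight_lookup(w)
  hops <- stats::setNames(0L, t)
  plen <- stats::setNames(0, t)
  frontier <- t
  k <- 0L
  while (length(frontier)) {
    k <- k + 1L
    nxt <- character()
    for (x in frontier) {
      for (p in h$parents[[x]]) {
        wt <- lut[edge_key(x, p)]
        if (is.na(wt)) wt <- 1
        cand <- plen[[x]] + wt
        if (is.na(hops[p])) {            # first time reached: hop distance k
          hops[p] <- k
          plen[p] <- cand
          nxt <- c(nxt, p)
        } else if (hops[[p]] == k && cand < plen[[p]]) {
          plen[p] <- cand                # another hop-shortest route, cheaper
        }
      }
    }
    frontier <- unique(nxt)
  }
  list(nodes = names(hops), hops = hops, plen = plen)
}

#' Weighted path length to an ancestor
#'
#' P(t, a): among the upward paths from `t` to `a` with the fewest edges,
#' the minimum sum of edge lengths, an edge's length being its weight-map
#' entry or 1.0 by default. P(t, t) = 0.
#'
#' @param h a `concept_hierarchy`.
#' @param t concept id.
#' @param a an ancestor of `t` (or `t` itself).
#' @param w an `edge_weight_map` or NULL for unit lengths.
#' @return non-negative number.
#' @export
path_length <- function(h, t, a, w = NULL) {
  assert_concept(h, t); assert_concept(h, a)
  if (!is.null(w)) validate_weight_map(h, w)
  ap <- ancestor_paths(h, t, w)
  if (!(a %in% ap$nodes)) {
    stop("'", a, "' is not an ancestor of '", t, "'")
  }
  unname(ap$plen[a])
}

#' Best common ancestor of two concepts
#'
#' The lowest common ancestor c_p(t1, t2): among all concepts ancestral to
#' both, the one minimising P(t1, c) + P(t2, c) under the given edge
#' weights. On a DAG several common ancestors can tie; ties are broken by
#' greater concept depth, then lexicographically smaller id, so the result
#' is deterministic.
#'
#' @param h a `concept_hierarchy`.
#' @param t1,t2 concept ids.
#' @param w an `edge_weight_map` or NULL for unit lengths.
#' @return A list of class `path_query_result` with elements `ancestor`,
#'   `length_t1`, `length_t2` (weighted path lengths), and `hops_t1`,
#'   `hops_t2` (edge counts of the underlying hop-shortest paths).
#' @export
best_common_ancestor <- function(h, t1, t2, w = NULL) {
  assert_concept(h, t1); assert_concept(h, t2)
  if (!is.null(w)) validate_weight_map(h, w)
  a1 <- ancestor_paths(h, t1, w)
  a2 <- ancestor_paths(h, t2, w)
  common <- intersect(a1$nodes, a2$nodes)
  if (!length(common)) {
    stop("concepts '", t1, "' and '", t2,
         "' share no common ancestor (disjoint roots)")
  }
  total <- a1$plen[common] + a2$plen[common]
  best <- common[total == min(total)]
  if (length(best) > 1L) {
    dp <- h$depth[best]
    best <- best[dp == max(dp)]
    best <- sort(best)[1L]
  }
  structure(
    list(ancestor = best,
         length_t1 = unname(a1$plen[best]),
         length_t2 = unname(a2$plen[best]),
         hops_t1 = unname(a1$hops[best]),
         hops_t2 = unname(a2$hops[best])),
    class = "path_query_result"
  )
}

#' @export
print.path_query_result <- function(x, ...) {
  cat("Common ancestor '", x$ancestor, "': path lengths ",
      format(x$length_t1), " and ", format(x$length_t2), "\n", sep = "")
  invisible(x)
}

# Edges lying on any hop-shortest upward path from t to its ancestor cp.
# An edge (x -> p) is on such a path iff hops(t,x) + 1 + hops(p,cp) equals
# hops(t,cp), with hops(p,cp) measured downward from cp over its descendants.
shortest_path_edges <- function(h, t, cp) {
  if (t == cp) {
    return(data.frame(child = character(), parent = character(),
                      stringsAsFactors = FALSE))
  }
  up <- ancestor_paths(h, t)           # hops from t to each ancestor
  if (!(cp %in% up$nodes)) stop("'", cp, "' is not an ancestor of '", t, "'")
  # downward BFS from cp, restricted to ancestors of t (plus t)
  inset <- up$nodes
  down <- stats::setNames(0L, cp)
  frontier <- cp
  k <- 0L
  while (length(frontier)) {
    k <- k + 1L
    nxt <- character()
    for (p in frontier) {
      for (x in intersect(h$children[[p]], inset)) {
        if (is.na(down[x])) {
          down[x] <- k
          nxt <- c(nxt, x)
        }
      }
    }
    frontier <- unique(nxt)
  }
  total <- up$hops[[cp]]
  child <- character(); parent <- character()
  for (x in names(down)) {
    if (x == cp) next
    for (p in intersect(h$parents[[x]], names(down))) {
      if (up$hops[[x]] + 1L + down[[p]] == total && !is.na(up$hops[x])) {
        child <- c(child, x); parent <- c(parent, p)
      }
    }
  }
  unique(data.frame(child = child, parent = parent, stringsAsFactors = FALSE))
}
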