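# Query-intention feedback: similarity between query-article concepts turns
# into edge weights < 1 on the hierarchy edges connecting them, shortening
# those paths and raising the relevance of everything near them.

#' Similarity between two query-article concepts
#'
#' A hybrid path/depth measure: S = exp(-alpha * l) * tanh(beta * hc), where
#' l is the unit-length shortest path t1 -> c_p -> t2 through the best
#' common ancestor and hc is the depth of that ancestor. The exponential
#' decays with path length; the saturating tanh term discounts shallow
#' common ancestors (S = 0 when the only shared ancestor is the root),
#' so the measure respects both the path between the concepts and the
#' position of their common node. S = 0 when no common ancestor exists.
#'
#' @param h a `concept_hierarchy`.
#' @param t1,t2 concept ids.
#' @param alpha path-length decay rate (>= 0), default 0.2.
#' @param beta depth saturation rate (> 0), default 0.6.
#' @return a similarity in [0, 1].
#' @export
concept_similarity <- function(h, t1, t2, alpha = 0.2, beta = 0.6) {
  stopifnot(alpha >= 0, beta > 0)
  assert_concept(h, t1); assert_concept(h, t2)
  if (t1 == t2) {
    return(exp(0) * tanh(beta * unname(h$depth[t1])))
  }
  bca <- tryCatch(best_common_ancestor(h, t1, t2, NULL),
                  error = function(e) NULL)
  if (is.null(bca)) return(0)
  l <- bca$hops_t1 + bca$hops_t2
  hc <- unname(h$depth[bca$ancestor])
  exp(-alpha * l) * tanh(beta * hc)
}

#' Edges connecting two concepts
#'
#' E(t1, t2): the union of edges lying on any hop-shortest upward path from
#' t1 to the best common ancestor and from t2 to it. Empty when t1 = t2 or
#' the concepts share no ancestor.
#'
#' @param h a `concept_hierarchy`.
#' @param t1,t2 concept ids.
#' @return data.frame with columns `child`, `parent`.
#' @export
weighted_edge_set <- function(h, t1, t2) {
  assert_concept(h, t1); assert_concept(h, t2)
  empty <- data.frame(child = character(), parent = character(),
                      stringsAsFactors = FALSE)
  if (t1 == t2) return(empty)
  bca <- tryCatch(best_common_ancestor(h, t1, t2, NULL),
                  error = function(e) NULL)
  if (is.null(bca)) return(empty)
  unique(rbind(shortest_path_edges(h, t1, bca$ancestor),
               shortest_path_edges(h, t2, bca$ancestor)))
}

#' Edge weights from one initial/additional article pair
#'
#' For every concept pair (t1 in T_A, t2 in T_L), every edge of E(t1, t2)
#' receives the candidate weight omega(e) = 1 - S(t1, t2), clamped to
#' [eps, 1]; when several pairs put a candidate on the same edge the
#' smallest is kept. WE(A, L) is the keyed edge set of the result.
#'
#' @param h a `concept_hierarchy`.
#' @param t_a `weighted_concept_set` of the initial article (user weights
#'   play no role here; they act only in the document-relevance sums).
#' @param t_l `weighted_concept_set` of one additional article.
#' @param alpha,beta similarity parameters, see [concept_similarity()].
#' @param eps floor keeping edge lengths positive, default 0.01.
#' @return an `edge_weight_map`.
#' @export
edge_weights_for_pair <- function(h, t_a, t_l, alpha = 0.2, beta = 0.6,
                                  eps = 0.01) {
  stopifnot(eps > 0, eps <= 1)
  best <- new.env(parent = emptyenv())
  ids_a <- intersect(t_a$id, h$ids)
  ids_l <- intersect(t_l$id, h$ids)
  for (t1 in ids_a) {
    for (t2 in ids_l) {
      e <- weighted_edge_set(h, t1, t2)
      if (!nrow(e)) next
      s <- concept_similarity(h, t1, t2, alpha, beta)
      omega <- min(max(1 - s, eps), 1)
      for (k in seq_len(nrow(e))) {
        key <- edge_key(e$child[k], e$parent[k])
        cur <- best[[key]]
        if (is.null(cur) || omega < cur$w) {
          best[[key]] <- list(child = e$child[k], parent = e$parent[k],
                              w = omega)
        }
      }
    }
  }
  vals <- as.list(best)
  edge_weight_map(
    child = vapply(vals, function(v) v$child, ""),
    parent = vapply(vals, function(v) v$parent, ""),
    weight = vapply(vals, function(v) v$w, numeric(1))
  )
}

combine_maps <- function(maps, keys_fun) {
  stopifnot(length(maps) >= 1L)
  keysets <- lapply(maps, function(m) edge_key(m$child, m$parent))
  keys <- Reduce(keys_fun, keysets)
  if (!length(keys)) return(edge_weight_map())
  all <- do.call(rbind, lapply(maps, as.data.frame))
  all <- all[edge_key(all$child, all$parent) %in% keys, , drop = FALSE]
  agg <- stats::aggregate(weight ~ child + parent, data = all, FUN = min)
  edge_weight_map(agg$child, agg$parent, agg$weight)
}

#' Combine weight maps, AND mode
#'
#' With several additional articles in an AND-search, only edges common to
#' every article's weighted-edge set keep a weight; conflicting weights on
#' a shared edge resolve to the smallest.
#'
#' @param maps list of `edge_weight_map`s (one per additional article).
#' @return an `edge_weight_map` keyed by the intersection of the inputs.
#' @export
combine_and <- function(maps) combine_maps(maps, intersect)

#' Combine weight maps, OR mode
#'
#' In an OR-search the union of the weighted-edge sets is kept, again with
#' the smallest weight on any edge keyed more than once.
#'
#' @param maps list of `edge_weight_map`s.
#' @return an `edge_weight_map` keyed by the union of the inputs.
#' @export
combine_or <- function(maps) combine_maps(maps, union)
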