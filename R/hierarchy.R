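#' Build a concept hierarchy
#'
#' A concept hierarchy is a rooted directed acyclic graph of concepts linked by
#' is_a-style child-to-parent edges. GO namespaces, SCOP classification trees
#' and the MeSH descriptor forest are all represented this way. The object
#' caches, per concept, the depth (longest root-to-concept path in edges), and
#' the overall hierarchy depth d(H) used by the relevance measure.
#'
#' @param concepts data.frame with columns `id` (unique, non-empty character)
#'   and `name` (label; defaults to the id).
#' @param edges data.frame with columns `child` and `parent`, each row one
#'   directed is_a edge from child to parent. May have zero rows.
#' @param source provenance tag, one of `"GO"`, `"SCOP"`, `"MESH"`,
#'   `"SYNTHETIC"`.
#' @return An object of class `concept_hierarchy` with components:
#'   `ids`, `labels` (named by id), `parents`/`children` (named lists of
#'   adjacent ids), `edges`, `roots`, `depth` (named integer vector),
#'   `d` (the hierarchy depth), `source`.
#' @examples
#' h <- concept_hierarchy(
#'   data.frame(id = c("root", "a", "b")),
#'   data.frame(child = c("a", "b"), parent = c("root", "a"))
#' )
#' hierarchy_depth(h)
#' @export
concept_hierarchy <- function(concepts, edges, source = "SYNTHETIC") {
  stopifnot(is.data.frame(concepts), "id" %in% names(concepts))
  ids <- as.character(concepts$id)
  if (any(!nzchar(ids))) stop("concept ids must be non-empty strings")
  if (anyDuplicated(ids)) {
    stop("duplicate concept ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  labels <- if ("name" %in% names(concepts)) as.character(concepts$name) else ids
  labels[is.na(labels) | !nzchar(labels)] <- ids[is.na(labels) | !nzchar(labels)]
  names(labels) <- ids

  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(child = character(), parent = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(child = as.character(edges$child),
                        parent = as.character(edges$parent),
                        stringsAsFactors = FALSE)
    edges <- unique(edges)
  }
  missing <- setdiff(unique(c(edges$child, edges$parent)), ids)
  if (length(missing)) {
    stop("edge endpoints not among the concepts: ",
         paste(missing, collapse = ", "))
  }
  if (any(edges$child == edges$parent)) stop("self-edges are not allowed")

  parents <- split(edges$parent, factor(edges$child, levels = ids))
  children <- split(edges$child, factor(edges$parent, levels = ids))

  # acyclicity (igraph) and a reverse-topological order for the depth sweep
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = ids))
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1)][1L]
    stop("cycle among parent edges involving concept '", cyc, "'")
  }
  # edges point child -> parent, so topo order lists children first; reverse it
  topo <- rev(names(igraph::topo_sort(g, mode = "out")))

  depth <- stats::setNames(integer(length(ids)), ids)
  for (v in topo) {
    p <- parents[[v]]
    depth[v] <- if (length(p)) max(depth[p]) + 1L else 0L
  }
  roots <- ids[vapply(parents, length, 1L) == 0L]
  if (!length(roots)) stop("hierarchy has no root")

  structure(
    list(ids = ids, labels = labels, parents = parents, children = children,
         edges = edges, roots = roots, depth = depth,
         d = max(depth), source = source),
    class = "concept_hierarchy"
  )
}

#' @export
print.concept_hierarchy <- function(x, ...) {
  cat("Concept hierarchy (", x$source, "): ",
      length(x$ids), " concepts, ", nrow(x$edges), " is_a edges, ",
      length(x$roots), " root(s), depth d(H) = ", x$d, "\n", sep = "")
  invisible(x)
}

#' @export
summary.concept_hierarchy <- function(object, ...) {
  cat("Concept hierarchy [", object$source, "]\n", sep = "")
  cat("  concepts :", length(object$ids), "\n")
  cat("  edges    :", nrow(object$edges), "\n")
  cat("  roots    :", paste(object$roots, collapse = ", "), "\n")
  cat("  depth    :", object$d, "\n")
  tb <- table(object$depth)
  cat("  concepts per depth level:\n")
  print(tb)
  invisible(object)
}

has_concept <- function(h, t) t %in% h$ids

assert_concept <- function(h, t) {
  if (!has_concept(h, t)) stop("unknown concept '", t, "'")
  invisible(t)
}

#' Depth of a concept hierarchy
#'
#' d(H) is the maximum number of edges on any root-to-concept path; a
#' single-concept hierarchy has depth 0.
#'
#' @param h a `concept_hierarchy`.
#' @return non-negative integer.
#' @export
hierarchy_depth <- function(h) {
  stopifnot(inherits(h, "concept_hierarchy"))
  h$d
}

#' Depth of one concept
#'
#' Longest root-to-concept path in edges; roots have depth 0.
#'
#' @param h a `concept_hierarchy`.
#' @param t concept id.
#' @return non-negative integer.
#' @export
concept_depth <- function(h, t) {
  assert_concept(h, t)
  unname(h$depth[t])
}

#' Extract the is_a ancestry of a concept
#'
#' Returns the sub-hierarchy induced by a concept and all its ancestors,
#' obtained by tracking is_a edges back to the root(s); all parent edges
#' among the retained concepts are kept. Idempotent.
#'
#' @param h a `concept_hierarchy`.
#' @param t concept id.
#' @return A `concept_hierarchy` restricted to `t` and its ancestors.
#' @export
extract_isa_ancestry <- function(h, t) {
  assert_concept(h, t)
  keep <- ancestor_set(h, t)
  edges <- h$edges[h$edges$child %in% keep & h$edges$parent %in% keep, ,
                   drop = FALSE]
  concept_hierarchy(
    data.frame(id = keep, name = unname(h$labels[keep]),
               stringsAsFactors = FALSE),
    edges, source = h$source
  )
}

# all ancestors of t, t included, via upward BFS on parent edges
ancestor_set <- function(h, t) {
  seen <- t
  frontier <- t
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(h$parents[frontier], use.names = FALSE)),
                   seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}
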