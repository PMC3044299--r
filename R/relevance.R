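#' Weighted concept sets
#'
#' The annotation of one article under one viewpoint: a set of concepts with
#' positive user weights (default 1) and, for MeSH, a Major-Topic flag.
#'
#' @param id character vector of concept ids (unique).
#' @param weight positive numeric weights, recycled; default 1.
#' @param major logical Major-Topic flags, recycled; default FALSE.
#' @return class `weighted_concept_set` (a data.frame with columns `id`,
#'   `weight`, `major`).
#' @export
weighted_concept_set <- function(id = character(), weight = 1, major = FALSE) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("concepts must be unique within a set")
  weight <- rep_len(as.numeric(weight), length(id))
  major <- rep_len(as.logical(major), length(id))
  if (length(id) && any(!is.finite(weight) | weight <= 0)) {
    stop("concept weights must be positive")
  }
  s <- data.frame(id = id, weight = weight, major = major,
                  stringsAsFactors = FALSE)
  class(s) <- c("weighted_concept_set", "data.frame")
  s
}

#' Relevance between two concepts
#'
#' d(H, t1, t2) = 2 d(H) - [P(t1, c_p) + P(t2, c_p)], where d(H) is the
#' hierarchy depth, c_p the best common ancestor and P the (optionally
#' edge-weighted) path length. Larger values mean more relevant; a concept
#' compared with itself scores the maximum 2 d(H). Concepts with no common
#' ancestor (different roots) score 0.
#'
#' @param h a `concept_hierarchy`.
#' @param t1,t2 concept ids.
#' @param w an `edge_weight_map` or NULL for unit edge lengths.
#' @return a number in [0, 2 d(H)].
#' @examples
#' f <- worked_example_fixture()
#' concept_relevance(f$hierarchy, f$t1, f$t2)   # 5 on the depth-4 example
#' @export
concept_relevance <- function(h, t1, t2, w = NULL) {
  assert_concept(h, t1); assert_concept(h, t2)
  if (t1 == t2) return(2 * h$d)
  bca <- tryCatch(best_common_ancestor(h, t1, t2, w),
                  error = function(e) NULL)
  if (is.null(bca)) return(0)
  2 * h$d - (bca$length_t1 + bca$length_t2)
}

viewpoint_score <- function(viewpoint, raw, weight_sum, d, empty = FALSE) {
  denom <- weight_sum * 2 * d
  structure(
    list(viewpoint = viewpoint, raw = raw,
         normalized = if (denom > 0) raw / denom else 0,
         empty = empty),
    class = "viewpoint_score"
  )
}

#' @export
print.viewpoint_score <- function(x, ...) {
  cat(sprintf("%s relevance: raw %.4g, normalized %.4f%s\n", x$viewpoint,
              x$raw, x$normalized, if (x$empty) " (empty annotation)" else ""))
  invisible(x)
}

# shared engine for the three document-level relevance forms: for each query concept
# t1 take the best-matching target concept (or the sum over targets), weight
# by omega_t1, and normalise by the attainable maximum sum(omega) * 2 d(H)
document_relevance <- function(h, d1, d2, w = NULL, viewpoint = "GO",
                               weights = d1$weight, agg = c("max", "sum")) {
  agg <- match.arg(agg)
  ok1 <- d1$id %in% h$ids
  ok2 <- d2$id %in% h$ids
  if (any(!ok1) || any(!ok2)) {
    warning("skipping concepts unresolvable in the ", viewpoint,
            " hierarchy: ",
            paste(c(d1$id[!ok1], d2$id[!ok2]), collapse = ", "))
  }
  ids1 <- d1$id[ok1]; wt1 <- weights[ok1]; ids2 <- d2$id[ok2]
  if (!length(ids1) || !length(ids2)) {
    return(viewpoint_score(viewpoint, 0, 0, h$d, empty = TRUE))
  }
  raw <- 0
  for (i in seq_along(ids1)) {
    rels <- vapply(ids2, function(t2) concept_relevance(h, ids1[i], t2, w),
                   numeric(1))
    raw <- raw + wt1[i] * (if (agg == "max") max(rels) else sum(rels))
  }
  viewpoint_score(viewpoint, raw, sum(wt1), h$d)
}

#' Document relevance, functional viewpoint (GO)
#'
#' d_GO(H, D1, D2) = sum over t1 in GO(D1) of omega_t1 times the relevance
#' of t1 to its best-matching concept in GO(D2). D1 is the query (input)
#' article, D2 the retrieval target; user weights omega_t1 come from D1.
#' The normalized score divides by sum(omega) * 2 d(H), its attainable
#' maximum, so the three viewpoints are commensurable.
#'
#' @param h a `concept_hierarchy`.
#' @param d1,d2 `weighted_concept_set`s (query, target).
#' @param w an `edge_weight_map` or NULL.
#' @param agg inner aggregation over the target's concepts: `"max"`
#'   (best match, the default) or `"sum"` (for sensitivity checks).
#' @return a `viewpoint_score`.
#' @export
document_relevance_go <- function(h, d1, d2, w = NULL, agg = c("max", "sum")) {
  document_relevance(h, d1, d2, w, viewpoint = "GO",
                     weights = d1$weight, agg = match.arg(agg))
}

#' Document relevance, structural viewpoint (SCOP)
#'
#' As the functional viewpoint but over SCOP leaves on the six-level
#' classification tree, with all concept weights fixed to 1.
#'
#' @inheritParams document_relevance_go
#' @return a `viewpoint_score`.
#' @export
document_relevance_scop <- function(h, d1, d2, w = NULL,
                                    agg = c("max", "sum")) {
  document_relevance(h, d1, d2, w, viewpoint = "SCOP",
                     weights = rep(1, nrow(d1)), agg = match.arg(agg))
}

#' Document relevance, medical-term viewpoint (MeSH)
#'
#' As the functional viewpoint over the MeSH descriptor hierarchy; a query
#' term flagged as a Major Topic carries weight `major_topic_factor`
#' (default 2), others weight 1.
#'
#' @inheritParams document_relevance_go
#' @param major_topic_factor weight for Major-Topic descriptors of the query.
#' @return a `viewpoint_score`.
#' @export
document_relevance_mesh <- function(h, d1, d2, w = NULL,
                                    major_topic_factor = 2,
                                    agg = c("max", "sum")) {
  stopifnot(major_topic_factor > 0)
  document_relevance(h, d1, d2, w, viewpoint = "MESH",
                     weights = ifelse(d1$major, major_topic_factor, 1),
                     agg = match.arg(agg))
}

#' Combine viewpoint scores
#'
#' Weighted mean of the normalized per-viewpoint scores. Viewpoints whose
#' annotation was empty on either side are excluded and the mix weights
#' renormalized over the rest; if every viewpoint is empty the combined
#' score is 0.
#'
#' @param scores list of `viewpoint_score`s.
#' @param mix named non-negative weights (by viewpoint), not all zero;
#'   viewpoints missing from `mix` get weight 0.
#' @return a number in [0, 1]; attribute `empty` is TRUE when no viewpoint
#'   contributed.
#' @export
combined_score <- function(scores, mix = c(GO = 1, SCOP = 1, MESH = 1)) {
  stopifnot(length(scores) > 0)
  mix <- mix[mix > 0]
  if (!length(mix)) stop("mix weights must not all be zero")
  vp <- vapply(scores, function(s) s$viewpoint, "")
  keep <- !vapply(scores, function(s) isTRUE(s$empty), TRUE) & vp %in% names(mix)
  if (!any(keep)) return(structure(0, empty = TRUE))
  wts <- as.numeric(mix[vp[keep]])
  vals <- vapply(scores[keep], function(s) s$normalized, numeric(1))
  structure(sum(wts * vals) / sum(wts), empty = FALSE)
}
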