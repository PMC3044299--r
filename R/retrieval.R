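#' Rank a corpus against a multi-article query
#'
#' End-to-end retrieval: the additional articles' concepts, compared with
#' the initial article's, produce one edge-weight map per hierarchy
#' (combined in AND or OR mode); every other corpus article is then scored
#' per viewpoint under those weights, the normalized viewpoint scores are
#' mixed, and the corpus is sorted. With no additional articles all maps
#' are empty and the ranking is the unit-edge-length baseline.
#'
#' @param initial article id of the initial (query) article; must be in
#'   `corpus`.
#' @param additional character vector of additional article ids (may be
#'   empty); must be in `corpus`.
#' @param corpus named list of `article_annotation`.
#' @param hierarchies list with elements `go`, `scop`, `mesh`, each a
#'   `concept_hierarchy` (any may be NULL to disable that viewpoint).
#' @param mode `"or"` or `"and"` combination of the additional articles'
#'   weight maps; irrelevant with fewer than two additional articles.
#' @param mix named viewpoint mix weights, default equal.
#' @param alpha,beta,eps intention parameters, see
#'   [edge_weights_for_pair()].
#' @param major_topic_factor weight of Major-Topic MeSH descriptors.
#' @param agg inner aggregation of document relevance (`"max"` or `"sum"`).
#' @return class `article_ranking`: a data.frame with one row per corpus
#'   article (query articles excluded), columns `rank`, `article_id`,
#'   `combined`, and raw/normalized per-viewpoint scores, sorted by
#'   `combined` descending with ties broken by id. The fitted weight maps
#'   are attached as attribute `weight_maps`.
#' @export
rank_corpus <- function(initial, additional = character(), corpus,
                        hierarchies, mode = c("or", "and"),
                        mix = c(GO = 1, SCOP = 1, MESH = 1),
                        alpha = 0.2, beta = 0.6, eps = 0.01,
                        major_topic_factor = 2, agg = c("max", "sum")) {
  mode <- match.arg(mode)
  agg <- match.arg(agg)
  if (!initial %in% names(corpus)) {
    stop("initial article '", initial, "' is not in the corpus registry")
  }
  bad <- setdiff(additional, names(corpus))
  if (length(bad)) {
    stop("additional article(s) not in the corpus registry: ",
         paste(bad, collapse = ", "))
  }
  qa <- corpus[[initial]]
  vp <- list(
    GO = list(h = hierarchies$go, get = function(a) a$go),
    SCOP = list(h = hierarchies$scop, get = function(a) a$scop),
    MESH = list(h = hierarchies$mesh, get = function(a) a$mesh)
  )
  # one intention weight map per hierarchy
  maps <- lapply(vp, function(v) {
    if (is.null(v$h) || !length(additional)) return(edge_weight_map())
    per_article <- lapply(additional, function(l)
      edge_weights_for_pair(v$h, v$get(qa), v$get(corpus[[l]]),
                            alpha = alpha, beta = beta, eps = eps))
    if (mode == "and") combine_and(per_article) else combine_or(per_article)
  })

  targets <- setdiff(names(corpus), c(initial, additional))
  if (!length(targets)) stop("corpus holds no candidate articles")

  score_one <- function(a) {
    cand <- corpus[[a]]
    scores <- list(
      if (!is.null(vp$GO$h))
        document_relevance_go(vp$GO$h, qa$go, cand$go, maps$GO, agg = agg),
      if (!is.null(vp$SCOP$h))
        document_relevance_scop(vp$SCOP$h, qa$scop, cand$scop, maps$SCOP,
                                agg = agg),
      if (!is.null(vp$MESH$h))
        document_relevance_mesh(vp$MESH$h, qa$mesh, cand$mesh, maps$MESH,
                                major_topic_factor = major_topic_factor,
                                agg = agg)
    )
    scores <- Filter(Negate(is.null), scores)
    comb <- combined_score(scores, mix)
    row <- list(article_id = a, combined = as.numeric(comb))
    for (s in scores) {
      row[[paste0(tolower(s$viewpoint), "_raw")]] <- s$raw
      row[[paste0(tolower(s$viewpoint), "_norm")]] <- s$normalized
    }
    row
  }
  rows <- lapply(targets, score_one)
  res <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  res <- res[order(-res$combined, res$article_id), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  res <- res[, c("rank", setdiff(names(res), "rank")), drop = FALSE]
  rownames(res) <- NULL
  structure(res,
            class = c("article_ranking", "data.frame"),
            query = list(initial = initial, additional = additional,
                         mode = mode),
            weight_maps = maps)
}

#' @export
print.article_ranking <- function(x, n = 10L, ...) {
  q <- attr(x, "query")
  cat("Article ranking: initial '", q$initial, "'", sep = "")
  if (length(q$additional)) {
    cat(" + ", length(q$additional), " additional (",
        toupper(q$mode), "-search)", sep = "")
  }
  cat(", ", nrow(x), " candidates\n", sep = "")
  print.data.frame(utils::head(x, n), row.names = FALSE, digits = 4)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more\n")
  invisible(x)
}

#' @export
summary.article_ranking <- function(object, ...) {
  print(object, n = 5L)
  maps <- attr(object, "weight_maps")
  nw <- vapply(maps, nrow, 1L)
  cat("Reweighted edges per hierarchy:",
      paste(names(nw), nw, sep = "=", collapse = ", "), "\n")
  invisible(object)
}
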