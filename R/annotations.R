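#' Article annotations
#'
#' One article's concept annotations across the three viewpoints. At least
#' one viewpoint must be non-empty.
#'
#' @param article_id unique article identifier (a PDB code or synthetic id).
#' @param go `weighted_concept_set` of GO terms (with optional user weights).
#' @param scop `weighted_concept_set` of SCOP species-level leaves.
#' @param mesh `weighted_concept_set` of MeSH descriptors (with Major-Topic
#'   flags in the `major` column).
#' @param bibliographic optional free-text metadata.
#' @return class `article_annotation`.
#' @export
article_annotation <- function(article_id,
                               go = weighted_concept_set(),
                               scop = weighted_concept_set(),
                               mesh = weighted_concept_set(),
                               bibliographic = NULL) {
  stopifnot(is.character(article_id), length(article_id) == 1L,
            nzchar(article_id))
  if (!nrow(go) && !nrow(scop) && !nrow(mesh)) {
    stop("article '", article_id, "': at least one viewpoint must be annotated")
  }
  structure(list(article_id = article_id, go = go, scop = scop, mesh = mesh,
                 bibliographic = bibliographic),
            class = "article_annotation")
}

#' @export
print.article_annotation <- function(x, ...) {
  cat("Article '", x$article_id, "': ", nrow(x$go), " GO, ", nrow(x$scop),
      " SCOP, ", nrow(x$mesh), " MeSH concept(s)\n", sep = "")
  invisible(x)
}

#' Read an annotated corpus from JSON
#'
#' One record per article:
#' `{"article_id": ..., "go": [{"id": ..., "weight": ...}], "scop": [ids],
#'   "mesh": [{"id": ..., "major_topic": true/false}]}`.
#'
#' @param path JSON file.
#' @return named list of `article_annotation` (names = article ids).
#' @export
read_corpus_json <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- lapply(recs, function(r) {
    go <- if (length(r$go)) {
      weighted_concept_set(
        vapply(r$go, function(g) g$id, ""),
        vapply(r$go, function(g) if (is.null(g$weight)) 1 else g$weight,
               numeric(1)))
    } else weighted_concept_set()
    scop <- weighted_concept_set(unlist(r$scop))
    mesh <- if (length(r$mesh)) {
      weighted_concept_set(
        vapply(r$mesh, function(m) m$id, ""),
        major = vapply(r$mesh, function(m) isTRUE(m$major_topic), TRUE))
    } else weighted_concept_set()
    article_annotation(r$article_id, go = go, scop = scop, mesh = mesh,
                       bibliographic = r$bibliographic)
  })
  stats::setNames(out, vapply(out, function(a) a$article_id, ""))
}

#' Write an annotated corpus to JSON
#'
#' Inverse of [read_corpus_json()].
#'
#' @param corpus named list of `article_annotation`.
#' @param path output file.
#' @export
write_corpus_json <- function(corpus, path) {
  recs <- lapply(unname(corpus), function(a) {
    list(article_id = a$article_id,
         go = lapply(seq_len(nrow(a$go)), function(i)
           list(id = a$go$id[i], weight = a$go$weight[i])),
         scop = as.list(a$scop$id),
         mesh = lapply(seq_len(nrow(a$mesh)), function(i)
           list(id = a$mesh$id[i], major_topic = a$mesh$major[i])))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Citation graphs
#'
#' Directed citing-to-cited edges over article ids; self-citations are
#' rejected. This is the ground-truth side of the evaluation protocol: an
#' article is "correct" for a query pair if some article co-citing the pair
#' also cites it.
#'
#' @param citing,cited character vectors (edge list).
#' @return class `citation_graph` (a data.frame with columns `citing`,
#'   `cited`).
#' @export
citation_graph <- function(citing = character(), cited = character()) {
  stopifnot(length(citing) == length(cited))
  citing <- as.character(citing); cited <- as.character(cited)
  if (any(citing == cited)) stop("self-citation edges are not allowed")
  g <- unique(data.frame(citing = citing, cited = cited,
                         stringsAsFactors = FALSE))
  class(g) <- c("citation_graph", "data.frame")
  g
}

#' Read a citation graph from two-column TSV
#'
#' Columns: citing_id, cited_id. Lines starting with `#` are skipped.
#'
#' @param path TSV file.
#' @return a `citation_graph`.
#' @export
read_citations_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("citing", "cited"),
                         colClasses = "character", comment.char = "#")
  citation_graph(d$citing, d$cited)
}

#' Write a ranking to two-column TSV
#'
#' Columns: rank, article_id.
#'
#' @param ranking an `article_ranking` (from [rank_corpus()]) or a character
#'   vector of article ids in rank order.
#' @param path output file.
#' @export
write_ranking_tsv <- function(ranking, path) {
  ids <- ranking_ids(ranking)
  utils::write.table(data.frame(rank = seq_along(ids), article_id = ids),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a ranking from two-column TSV
#'
#' Accepts externally produced rankings (e.g. a search-engine baseline) for
#' evaluation; columns rank, article_id.
#'
#' @param path TSV file.
#' @return character vector of article ids in rank order.
#' @export
read_ranking_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = "character", comment.char = "#")
  d[[2]][order(as.numeric(d[[1]]))]
}

ranking_ids <- function(ranking) {
  if (inherits(ranking, "article_ranking")) ranking$article_id
  else as.character(ranking)
}
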