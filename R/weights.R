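#' Edge weight maps
#'
#' An edge weight map assigns a length omega(e) in (0, 1] to selected
#' child-to-parent edges of one hierarchy; every edge not keyed keeps the
#' default unit length 1.0. Weight maps encode the query intention: edges on
#' paths between initial-article and additional-article concepts are
#' shortened, which raises the relevance of concepts near those paths.
#'
#' @param child character vector of child concept ids.
#' @param parent character vector of parent concept ids (same length).
#' @param weight numeric vector of lengths in (0, 1].
#' @return An object of class `edge_weight_map` (a data.frame with columns
#'   `child`, `parent`, `weight`).
#' @examples
#' edge_weight_map("a", "root", 0.25)
#' edge_weight_map()          # empty map: all edges keep length 1
#' @export
edge_weight_map <- function(child = character(), parent = character(),
                            weight = numeric()) {
  stopifnot(length(child) == length(parent),
            length(child) == length(weight))
  weight <- as.numeric(weight)
  if (any(!is.finite(weight)) || any(weight <= 0) || any(weight > 1)) {
    stop("edge weights must lie in (0, 1]")
  }
  m <- data.frame(child = as.character(child), parent = as.character(parent),
                  weight = weight, stringsAsFactors = FALSE)
  key <- edge_key(m$child, m$parent)
  if (anyDuplicated(key)) stop("duplicate edges in weight map")
  class(m) <- c("edge_weight_map", "data.frame")
  m
}

edge_key <- function(child, parent) paste(child, parent, sep = "\x1f")

# fast lookup vector: named weights, absent edges default to 1
weight_lookup <- function(w) {
  if (is.null(w) || nrow(w) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  stats::setNames(w$weight, edge_key(w$child, w$parent))
}

# check that every keyed edge exists in h
validate_weight_map <- function(h, w) {
  if (is.null(w) || nrow(w) == 0L) return(invisible(TRUE))
  known <- edge_key(h$edges$child, h$edges$parent)
  bad <- !(edge_key(w$child, w$parent) %in% known)
  if (any(bad)) {
    stop("weight map keys edges absent from the hierarchy: ",
         paste(paste(w$child[bad], w$parent[bad], sep = " -> "),
               collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.edge_weight_map <- function(x, ...) {
  cat("Edge weight map:", nrow(x), "reweighted edge(s)\n")
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}
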