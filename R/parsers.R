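# Parsers for the three concept-hierarchy resources. Each returns a
# concept_hierarchy built from child -> parent is_a-style edges only.

read_text_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
}

#' Parse an OBO 1.2 ontology file
#'
#' Reads `[Term]` stanzas and builds a hierarchy from `is_a:` lines only;
#' `relationship:` lines (part_of and all others) are ignored, as are
#' obsolete terms. GO's three namespaces load as three roots of one
#' hierarchy unless a namespace filter is given.
#'
#' @param x path to an OBO file, or OBO text.
#' @param namespace optional: keep only terms in this namespace.
#' @return A `concept_hierarchy` with source `"GO"`.
#' @export
parse_obo <- function(x, namespace = NULL) {
  lines <- read_text_lines(x)
  # stanza boundaries
  starts <- grep("^\\[", lines)
  term_starts <- grep("^\\[Term\\]$", trimws(lines))
  ids <- character(); nms <- character(); nss <- character()
  children <- character(); parents <- character()
  obsolete <- character()
  bounds <- c(starts, length(lines) + 1L)
  for (s in term_starts) {
    e <- min(bounds[bounds > s]) - 1L
    block <- lines[(s + 1L):e]
    id <- sub("^id:\\s*", "", grep("^id:", block, value = TRUE)[1])
    if (is.na(id)) next
    id <- trimws(id)
    nm <- sub("^name:\\s*", "", grep("^name:", block, value = TRUE)[1])
    ns <- sub("^namespace:\\s*", "", grep("^namespace:", block, value = TRUE)[1])
    if (any(grepl("^is_obsolete:\\s*true", block))) {
      obsolete <- c(obsolete, id)
      next
    }
    if (!is.null(namespace) && !is.na(ns) && trimws(ns) != namespace) next
    isa <- grep("^is_a:", block, value = TRUE)
    isa <- trimws(sub("!.*$", "", sub("^is_a:\\s*", "", isa)))
    ids <- c(ids, id)
    nms <- c(nms, if (is.na(nm)) id else trimws(nm))
    nss <- c(nss, if (is.na(ns)) "" else trimws(ns))
    children <- c(children, rep(id, length(isa)))
    parents <- c(parents, isa)
  }
  # edges to obsolete terms are dropped with the term; with a namespace
  # filter, edges out of the namespace are dropped silently
  if (!is.null(namespace)) {
    keep <- parents %in% ids
    children <- children[keep]; parents <- parents[keep]
  } else {
    keep <- !(parents %in% obsolete)
    children <- children[keep]; parents <- parents[keep]
  }
  dangling <- setdiff(parents, ids)
  if (length(dangling)) {
    stop("is_a targets never defined: ", paste(dangling, collapse = ", "))
  }
  concept_hierarchy(
    data.frame(id = ids, name = nms, stringsAsFactors = FALSE),
    data.frame(child = children, parent = parents, stringsAsFactors = FALSE),
    source = "GO"
  )
}

scop_levels <- c("class", "fold", "superfamily", "family", "protein", "species")

#' Parse a SCOP classification listing
#'
#' Accepts either SCOP `dir.cla`-style lines (sid, PDB code, description,
#' sccs, sunid, `cl=..,cf=..,sf=..,fa=..,dm=..,sp=..,px=..`) or a simplified
#' two-column TSV (`pdb_id <TAB> class/fold/superfamily/family/protein/species`).
#' Builds a strict six-level tree under a single synthetic root and maps
#' every PDB code to its species-level leaves.
#'
#' @param x path or text.
#' @return list with `hierarchy` (a `concept_hierarchy`, source `"SCOP"`)
#'   and `pdb_map` (named list: pdb_id -> character vector of leaf ids).
#' @export
parse_scop_classification <- function(x) {
  lines <- read_text_lines(x)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  node_ids <- character(); node_names <- character()
  child <- character(); parent <- character()
  pdb_map <- list()
  root <- "scop_root"
  add_chain <- function(parts, pdb, lineno) {
    if (length(parts) < 6L) {
      stop("line ", lineno, ": fewer than six SCOP hierarchy fields")
    }
    parts <- parts[seq_len(6L)]
    prev <- root
    for (k in seq_len(6L)) {
      nid <- paste(parts[seq_len(k)], collapse = "/")
      if (!(nid %in% node_ids)) {
        node_ids <<- c(node_ids, nid)
        node_names <<- c(node_names, paste0(scop_levels[k], " ", parts[k]))
        child <<- c(child, nid); parent <<- c(parent, prev)
      }
      prev <- nid
    }
    pdb_map[[pdb]] <<- unique(c(pdb_map[[pdb]], prev))
  }
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) >= 2L && grepl("/", f[2], fixed = TRUE) &&
        !any(grepl("cl=", f, fixed = TRUE))) {
      # simplified TSV: pdb_id <TAB> slash path
      add_chain(strsplit(f[2], "/", fixed = TRUE)[[1]], f[1], i)
    } else {
      hier <- grep("cl=", f, fixed = TRUE, value = TRUE)
      if (!length(hier)) stop("line ", i, ": no SCOP hierarchy field found")
      kv <- strsplit(strsplit(hier[1], ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
      keys <- vapply(kv, `[`, "", 1L)
      vals <- vapply(kv, `[`, "", 2L)
      want <- c("cl", "cf", "sf", "fa", "dm", "sp")
      if (!all(want %in% keys)) {
        stop("line ", i, ": fewer than six SCOP hierarchy fields")
      }
      add_chain(vals[match(want, keys)], f[2], i)
    }
  }
  h <- concept_hierarchy(
    data.frame(id = c(root, node_ids),
               name = c("SCOP root", node_names), stringsAsFactors = FALSE),
    data.frame(child = child, parent = parent, stringsAsFactors = FALSE),
    source = "SCOP"
  )
  list(hierarchy = h, pdb_map = pdb_map)
}

#' Parse MeSH ASCII descriptor records
#'
#' Reads records with `MH =` (name), `UI =` (descriptor id) and one or more
#' `MN =` tree numbers. The parent of tree number `A.B.C` is the descriptor
#' owning tree number `A.B`; a descriptor with several tree numbers gets one
#' parent per number (a DAG). Top-level tree numbers attach to a synthetic
#' root.
#'
#' @param x path or text.
#' @return A `concept_hierarchy` with source `"MESH"`; the synthetic root
#'   has id `"mesh_root"`.
#' @export
parse_mesh <- function(x) {
  lines <- read_text_lines(x)
  recs <- split(lines, cumsum(grepl("^\\*NEWRECORD", lines) |
                                c(TRUE, !nzchar(trimws(lines[-length(lines)])))))
  ui <- character(); mh <- character(); mn <- list()
  for (r in recs) {
    get <- function(tag) trimws(sub(paste0("^", tag, "\\s*=\\s*"), "",
                                    grep(paste0("^", tag, "\\s*="), r,
                                         value = TRUE)))
    u <- get("UI"); m <- get("MH"); tn <- get("MN")
    if (!length(u) || !length(tn)) next
    ui <- c(ui, u[1])
    mh <- c(mh, if (length(m)) m[1] else u[1])
    mn <- c(mn, list(tn))
  }
  if (!length(ui)) stop("no MeSH descriptor records found")
  owner <- stats::setNames(rep(ui, lengths(mn)), unlist(mn))
  if (anyDuplicated(names(owner))) {
    stop("tree number owned by more than one descriptor: ",
         paste(unique(names(owner)[duplicated(names(owner))]), collapse = ", "))
  }
  root <- "mesh_root"
  child <- character(); parent <- character(); orphans <- character()
  for (i in seq_along(ui)) {
    for (tn in mn[[i]]) {
      if (!grepl(".", tn, fixed = TRUE)) {
        child <- c(child, ui[i]); parent <- c(parent, root)
      } else {
        pfx <- sub("\\.[^.]*$", "", tn)
        if (is.na(owner[pfx])) {
          orphans <- c(orphans, tn)
        } else {
          child <- c(child, ui[i]); parent <- c(parent, unname(owner[pfx]))
        }
      }
    }
  }
  if (length(orphans)) {
    stop("tree numbers whose parent prefix is owned by no descriptor: ",
         paste(orphans, collapse = ", "))
  }
  keep <- !(child == parent)  # a descriptor owning both A.B and A.B.C
  concept_hierarchy(
    data.frame(id = c(root, ui), name = c("MeSH root", mh),
               stringsAsFactors = FALSE),
    unique(data.frame(child = child[keep], parent = parent[keep],
                      stringsAsFactors = FALSE)),
    source = "MESH"
  )
}

#' Write a hierarchy as OBO 1.2 text
#'
#' Serialises a concept hierarchy to minimal OBO: one `[Term]` stanza per
#' concept with its `is_a` parents. [parse_obo()] round-trips the result.
#'
#' @param h a `concept_hierarchy`.
#' @param path output file.
#' @export
write_hierarchy_obo <- function(h, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (id in h$ids) {
    ps <- h$parents[[id]]
    writeLines(c("", "[Term]", paste0("id: ", id),
                 paste0("name: ", h$labels[[id]]),
                 if (length(ps)) paste0("is_a: ", ps)), con)
  }
  invisible(path)
}
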