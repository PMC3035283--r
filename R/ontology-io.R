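#' @title Ontology containers and OBO parsing
#' @description Parse OBO 1.2 flat files (or in-memory edge lists) into a
#'   validated `ontology_dag`: a rooted, acyclic child-to-parent graph of
#'   terms. All specificity metrics in this package run on this object.
#' @name ontology_io
NULL

OBO_EDGE_TYPES <- c("is_a", "part_of")

NAMESPACES <- c("molecular_function", "biological_process",
                "cellular_component", "other")

# Internal constructor + validator shared by parse_obo() and build_dag().
#
# terms: named list of lists(term_id, name, namespace, is_obsolete, parents)
# root_id: NULL to auto-detect (exactly one parentless non-obsolete term
#   required), or an explicit id (any other parentless term is a dangling node).
new_ontology_dag <- function(terms, root_id = NULL, edge_types = "is_a",
                             alt_ids = character(0),
                             orphan_is_dangling = !is.null(root_id)) {
  ids <- vapply(terms, `[[`, "", "term_id")
  if (anyDuplicated(ids)) {
    schema_error(sprintf("duplicate term id '%s'", ids[duplicated(ids)][1L]))
  }
  names(terms) <- ids
  obs <- vapply(terms, `[[`, FALSE, "is_obsolete")

  # obsolete terms keep no parent links and take part in no traversal
  for (id in ids[obs]) terms[[id]]$parents <- character(0)

  active <- ids[!obs]
  for (id in active) {
    for (p in terms[[id]]$parents) {
      if (!p %in% ids) dangling_edge_error(id, p)
      if (terms[[p]]$is_obsolete) dangling_edge_error(id, p)
    }
  }

  parentless <- active[vapply(active, function(id)
    length(terms[[id]]$parents) == 0L, FALSE)]
  if (is.null(root_id)) {
    if (length(parentless) != 1L) root_resolution_error(parentless)
    root_id <- parentless
  } else {
    if (!root_id %in% active) root_resolution_error(character(0))
    if (length(terms[[root_id]]$parents) > 0L) {
      root_resolution_error(c(root_id, "(declared root has parents)"))
    }
    stray <- setdiff(parentless, root_id)
    if (length(stray) > 0L) {
      if (orphan_is_dangling) dangling_edge_error(stray[1L])
      root_resolution_error(c(root_id, stray))
    }
  }

  children <- lapply(stats::setNames(active, active), function(i) character(0))
  for (id in active) {
    for (p in terms[[id]]$parents) {
      children[[p]] <- c(children[[p]], id)
    }
  }

  # Kahn's algorithm from the root; leftovers after the sweep can only be
  # cycle members (multiple roots / dangling parents were ruled out above).
  n_par <- vapply(active, function(id) length(terms[[id]]$parents), 0L)
  names(n_par) <- active
  queue <- root_id
  topo <- character(0)
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    topo <- c(topo, v)
    for (ch in children[[v]]) {
      n_par[[ch]] <- n_par[[ch]] - 1L
      if (n_par[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(topo) < length(active)) {
    cyclic_ontology_error(setdiff(active, topo)[1L])
  }

  parents <- lapply(stats::setNames(active, active),
                    function(id) terms[[id]]$parents)

  structure(
    list(terms = terms, parents = parents, children = children,
         root_id = root_id, edge_types = edge_types, alt_ids = alt_ids,
         topo = topo),
    class = "ontology_dag"
  )
}

check_edge_types <- function(edge_types) {
  bad <- setdiff(edge_types, OBO_EDGE_TYPES)
  if (length(bad) > 0L || length(edge_types) == 0L) {
    spec_error(sprintf("edge_types must be a non-empty subset of {%s}",
                       paste(OBO_EDGE_TYPES, collapse = ", ")))
  }
  edge_types
}

#' Parse an OBO 1.2 flat file into an ontology DAG
#'
#' Reads `[Term]` stanzas (id, name, namespace, is_a, relationship: part_of,
#' is_obsolete, alt_id). Obsolete terms are retained but flagged and carry no
#' edges; `alt_id` entries are recorded so annotation readers can resolve them
#' to the primary id. The loaded graph is validated: it must be acyclic,
#' single-rooted within the chosen namespace, and free of dangling parent
#' references.
#'
#' @param input path to an OBO file (gzip accepted), a connection, or a
#'   character vector of OBO lines.
#' @param namespace_filter restrict to one namespace
#'   (e.g. `"molecular_function"`). Required when the file holds more than one
#'   namespace.
#' @param edge_types which relationship types define "parent"; subset of
#'   `c("is_a", "part_of")`. Default counts only `is_a`, so ancestor/offspring
#'   counts are reproducible and explicit.
#' @return an `ontology_dag`.
#' @examples
#' obo <- c("format-version: 1.2", "",
#'          "[Term]", "id: GO:0003674", "name: molecular_function",
#'          "namespace: molecular_function", "",
#'          "[Term]", "id: GO:0005488", "name: binding",
#'          "namespace: molecular_function", "is_a: GO:0003674 ! molecular_function")
#' dag <- parse_obo(obo)
#' dag$root_id
#' @export
parse_obo <- function(input, namespace_filter = NULL, edge_types = "is_a") {
  check_edge_types(edge_types)
  lines <- read_text_lines(input)

  terms <- list()
  alt_map <- character(0)
  cur <- NULL
  in_term <- FALSE

  flush_term <- function() {
    if (!is.null(cur) && !is.null(cur$term_id)) {
      terms[[length(terms) + 1L]] <<- cur
      for (a in cur$alt_ids) alt_map[[a]] <<- cur$term_id
    }
    cur <<- NULL
  }

  for (raw in lines) {
    line <- trimws(raw)
    if (line == "[Term]") {
      flush_term()
      in_term <- TRUE
      cur <- list(term_id = NULL, name = NA_character_, namespace = "other",
                  is_obsolete = FALSE, parents = character(0),
                  alt_ids = character(0))
      next
    }
    if (grepl("^\\[", line)) {          # [Typedef] etc.
      flush_term()
      in_term <- FALSE
      next
    }
    if (!in_term || line == "") next
    kv <- regmatches(line, regexec("^([A-Za-z_]+):[ \t]*(.*)$", line))[[1L]]
    if (length(kv) != 3L) next
    key <- kv[[2L]]
    val <- kv[[3L]]
    if (key != "name") val <- sub("[ \t]*!.*$", "", val)  # strip trailing comment
    val <- trimws(val)
    if (key == "id") cur$term_id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "alt_id") cur$alt_ids <- c(cur$alt_ids, val)
    else if (key == "is_obsolete") cur$is_obsolete <- identical(val, "true")
    else if (key == "is_a" && "is_a" %in% edge_types) {
      cur$parents <- c(cur$parents, val)
    } else if (key == "relationship") {
      rel <- strsplit(val, "[ \t]+")[[1L]]
      if (length(rel) >= 2L && rel[[1L]] %in% edge_types) {
        cur$parents <- c(cur$parents, rel[[2L]])
      }
    }
  }
  flush_term()

  if (length(terms) == 0L) schema_error("no [Term] stanzas found")

  nss <- unique(vapply(terms, `[[`, "", "namespace")[
    !vapply(terms, `[[`, FALSE, "is_obsolete")])
  if (is.null(namespace_filter)) {
    if (length(nss) > 1L) namespace_error(nss)
  } else {
    kept_ids <- vapply(terms, function(t)
      identical(t$namespace, namespace_filter), FALSE)
    if (!any(kept_ids)) namespace_error(nss)
    defined <- vapply(terms, `[[`, "", "term_id")
    terms <- terms[kept_ids]
    kept_set <- vapply(terms, `[[`, "", "term_id")
    # edges into a term defined in the file but outside the namespace are
    # dropped (cross-namespace edges are out of scope); truly undefined
    # parents still raise dangling_edge_error in the validator
    terms <- lapply(terms, function(t) {
      t$parents <- t$parents[!(t$parents %in% defined & !t$parents %in% kept_set)]
      t
    })
  }

  terms <- lapply(terms, function(t) {
    if (!t$namespace %in% NAMESPACES) t$namespace <- "other"
    t$parents <- unique(t$parents)
    t
  })
  new_ontology_dag(terms, root_id = NULL, edge_types = edge_types,
                   alt_ids = alt_map)
}

#' Build an ontology DAG from an in-memory edge list
#'
#' Fixture constructor: terms are inferred from the edge list plus the root.
#' Validation matches [parse_obo()]: acyclic, single root, every non-root term
#' connected to the root.
#'
#' @param edges two-column `(child_id, parent_id)` data.frame/matrix, or a list
#'   of length-2 character vectors. May be empty.
#' @param root_id id of the root term.
#' @param names optional named character vector of term names.
#' @param namespace namespace recorded for every term.
#' @return an `ontology_dag`.
#' @examples
#' build_dag(list(c("A", "R"), c("B", "A")), root_id = "R")
#' @export
build_dag <- function(edges, root_id, names = character(0),
                      namespace = "molecular_function") {
  if (!is.character(root_id) || length(root_id) != 1L || !nzchar(root_id)) {
    spec_error("root_id must be one nonempty string")
  }
  em <- as_edge_matrix(edges)
  if (any(!nzchar(em))) spec_error("edge ids must be nonempty strings")
  ids <- unique(c(root_id, as.vector(t(em))))
  parents <- lapply(stats::setNames(ids, ids), function(id)
    unique(em[em[, 1L] == id, 2L]))
  terms <- lapply(ids, function(id) {
    list(term_id = id,
         name = if (id %in% base::names(names)) names[[id]] else id,
         namespace = namespace, is_obsolete = FALSE,
         parents = parents[[id]], alt_ids = character(0))
  })
  new_ontology_dag(terms, root_id = root_id, edge_types = "is_a")
}

as_edge_matrix <- function(edges) {
  if (is.null(edges) || (is.list(edges) && length(edges) == 0L) ||
      (is.data.frame(edges) && nrow(edges) == 0L)) {
    return(matrix(character(0), ncol = 2L))
  }
  if (is.data.frame(edges) || is.matrix(edges)) {
    m <- as.matrix(edges)
    storage.mode(m) <- "character"
    if (ncol(m) != 2L) spec_error("edges must have two columns (child, parent)")
    return(m)
  }
  if (is.list(edges)) {
    if (any(lengths(edges) != 2L)) spec_error("each edge must be (child, parent)")
    return(matrix(unlist(lapply(edges, as.character)), ncol = 2L, byrow = TRUE))
  }
  spec_error("edges must be a 2-column table or list of pairs")
}

read_text_lines <- function(input) {
  if (inherits(input, "connection")) return(readLines(input, warn = FALSE))
  if (is.character(input) && length(input) == 1L && file.exists(input)) {
    con <- gzfile(input, "rt")   # reads plain and gzip transparently
    on.exit(close(con))
    return(readLines(con, warn = FALSE))
  }
  if (is.character(input)) return(input)
  spec_error("input must be a file path, connection, or character lines")
}

#' Serialize an ontology DAG back to OBO 1.2 text
#'
#' Emits one `[Term]` stanza per term (obsolete terms included), with all
#' parent links written as `is_a` lines. Round-trips term ids, names and
#' edges through [parse_obo()] exactly.
#'
#' @param dag an `ontology_dag`.
#' @param path optional file path; when `NULL` the lines are returned.
#' @return invisibly (or visibly when `path` is `NULL`) the OBO lines.
#' @export
write_obo <- function(dag, path = NULL) {
  stopifnot(inherits(dag, "ontology_dag"))
  ids <- sort(base::names(dag$terms))
  lines <- c("format-version: 1.2", "")
  for (id in ids) {
    t <- dag$terms[[id]]
    lines <- c(lines, "[Term]", paste0("id: ", t$term_id))
    if (!is.na(t$name)) lines <- c(lines, paste0("name: ", t$name))
    lines <- c(lines, paste0("namespace: ", t$namespace))
    for (a in sort(t$alt_ids %||% character(0))) {
      lines <- c(lines, paste0("alt_id: ", a))
    }
    if (t$is_obsolete) lines <- c(lines, "is_obsolete: true")
    for (p in sort(t$parents)) lines <- c(lines, paste0("is_a: ", p))
    lines <- c(lines, "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Active (non-obsolete) term ids of a DAG
#' @param dag an `ontology_dag`.
#' @return character vector in topological (root-first) order.
#' @export
dag_terms <- function(dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  dag$topo
}

#' Resolve a possibly-secondary term id to its primary id
#' @param dag an `ontology_dag`.
#' @param term_ids character vector of ids (primary or alt).
#' @return character vector of primary ids (`NA` where unresolvable).
#' @export
resolve_term_id <- function(dag, term_ids) {
  out <- term_ids
  alt <- out %in% base::names(dag$alt_ids)
  out[alt] <- dag$alt_ids[out[alt]]
  out[!out %in% base::names(dag$terms)] <- NA_character_
  out
}

#' @export
print.ontology_dag <- function(x, ...) {
  n_obs <- sum(vapply(x$terms, `[[`, FALSE, "is_obsolete"))
  n_edges <- sum(lengths(x$parents))
  cat(sprintf(
    "ontology_dag: %d terms (%d obsolete), %d edges, root %s [%s]\n",
    length(x$terms), n_obs, n_edges, x$root_id,
    paste(x$edge_types, collapse = ",")))
  invisible(x)
}
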