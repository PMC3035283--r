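#' @title Ancestor and offspring sets
#' @description Node-counting traversals over the ontology DAG. A term's
#'   ancestors are all terms reachable by repeatedly following child-to-parent
#'   edges up to and including the root; its offspring are all terms reachable
#'   the other way. Both are sets of unique nodes — a node reached along many
#'   paths is counted once, which is what a visited-marking depth-first search
#'   yields on a DAG.
#' @name dag_core
NULL

check_known_term <- function(dag, t) {
  if (!is.character(t) || length(t) != 1L) unknown_term_error(as.character(t)[1L])
  if (!t %in% names(dag$parents)) unknown_term_error(t)
  invisible(t)
}

# Iterative DFS with a visited set; `links` is dag$parents (ancestors) or
# dag$children (offspring). Kept as the direct, reference implementation.
dfs_reach <- function(links, t) {
  visited <- new.env(parent = emptyenv(), size = 64L)
  stack <- links[[t]]
  while (length(stack) > 0L) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (!is.null(visited[[v]])) next
    visited[[v]] <- TRUE
    stack <- c(stack, links[[v]])
  }
  out <- setdiff(ls(visited), t)   # a term is never its own ancestor/offspring
  sort(out)
}

#' Ancestor set of a term
#'
#' All terms strictly above `t`, up to and including the root. The root itself
#' has no ancestors.
#'
#' @param dag an `ontology_dag`.
#' @param t a non-obsolete term id.
#' @return sorted character vector of term ids.
#' @examples
#' dag <- build_dag(list(c("A", "R"), c("B", "A")), root_id = "R")
#' ancestor_set(dag, "B")   # "A" "R"
#' @export
ancestor_set <- function(dag, t) {
  stopifnot(inherits(dag, "ontology_dag"))
  check_known_term(dag, t)
  dfs_reach(dag$parents, t)
}

#' Offspring set of a term
#'
#' All terms strictly below `t`; a leaf has none.
#'
#' @inheritParams ancestor_set
#' @return sorted character vector of term ids.
#' @export
offspring_set <- function(dag, t) {
  stopifnot(inherits(dag, "ontology_dag"))
  check_known_term(dag, t)
  dfs_reach(dag$children, t)
}

#' Whole-ontology reachability table
#'
#' Computes ancestor and offspring sets for every non-obsolete term in one
#' memoized sweep over a topological order (ancestors top-down, offspring
#' bottom-up), so whole-ontology runs avoid a per-term DFS. Results are
#' identical to [ancestor_set()]/[offspring_set()].
#'
#' @param dag an `ontology_dag`.
#' @return named list, one entry per term: `list(term_id, ancestors, offspring)`.
#' @export
reachability_table <- function(dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  topo <- dag$topo
  anc <- vector("list", length(topo))
  names(anc) <- topo
  for (v in topo) {                      # parents appear before children
    ps <- dag$parents[[v]]
    anc[[v]] <- if (length(ps) == 0L) character(0) else
      sort(unique(c(ps, unlist(anc[ps], use.names = FALSE))))
  }
  off <- vector("list", length(topo))
  names(off) <- topo
  for (v in rev(topo)) {                 # children appear before parents
    cs <- dag$children[[v]]
    off[[v]] <- if (length(cs) == 0L) character(0) else
      sort(unique(c(cs, unlist(off[cs], use.names = FALSE))))
  }
  out <- lapply(stats::setNames(topo, topo), function(v)
    list(term_id = v, ancestors = anc[[v]], offspring = off[[v]]))
  out
}
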