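#' @title Term specificity metrics
#' @description The four specificity measures: number of ancestors, normalized
#'   offspring count (Offsp_N), GO proportion of reachable terms, and
#'   annotation-derived Information Content. The structural measures depend
#'   only on the ontology graph; IC additionally requires an annotation set.
#' @name specificity
NULL

#' Normalized offspring specificity (Offsp_N)
#'
#' `Offsp_N = ln((M + 1) / (k + 1))` where `k` is a term's offspring count and
#' `M` the maximum offspring count in the ontology (the root's, e.g. 8267 for
#' the 2010 molecular-function release). The measure is 0 at the root
#' (`k = M`), maximal (`ln(M + 1)`) for leaves, and increases with
#' specificity like the ancestor count does.
#'
#' @param k offspring count(s), `0 <= k <= M`.
#' @param M maximum offspring count, `>= 1`.
#' @return numeric vector in nats, in `[0, ln(M + 1)]`.
#' @examples
#' round(offsp_n(c(0, 1, 5, 8267), 8267), 2)  # 9.02 8.33 7.23 0.00
#' @export
offsp_n <- function(k, M) {
  if (!is.numeric(k) || !is.numeric(M)) bounds_error("k and M must be numeric")
  if (length(M) != 1L || is.na(M) || M < 1) bounds_error("M must be a single value >= 1")
  bad <- !is.na(k) & (k < 0 | k > M)
  if (any(bad)) {
    bounds_error(sprintf("offspring count %g outside [0, M = %g]", k[bad][1L], M))
  }
  log((M + 1) / (k + 1))
}

#' GO proportion of reachable terms
#'
#' `P_t = 1 - offspring / (offspring + ancestors)`: one minus the fraction of
#' a term's reachable terms that lie below it. Ranges from 0 (root of a
#' nontrivial ontology) to 1 (leaf); undefined (`NA`) for an isolated term
#' with neither ancestors nor offspring.
#'
#' @param n_offspring,n_ancestors nonnegative counts (vectorized).
#' @return numeric vector in `[0, 1]`, `NA` where both counts are zero.
#' @examples
#' round(go_proportion(c(0, 1, 5), c(8, 5, 2)), 2)  # 1.00 0.83 0.29
#' @export
go_proportion <- function(n_offspring, n_ancestors) {
  if (any(n_offspring < 0, na.rm = TRUE) || any(n_ancestors < 0, na.rm = TRUE)) {
    bounds_error("counts must be nonnegative")
  }
  tot <- n_offspring + n_ancestors
  out <- ifelse(tot == 0, NA_real_, 1 - n_offspring / tot)
  as.numeric(out)
}

#' Information content of an occurrence probability
#'
#' `IC = -log2(p)`, in bits: 0 when `p = 1` (the root baseline, the least
#' specific function) and increasing as the term gets rarer. Undefined (`NA`)
#' at `p = 0` — a term absent from the data set has no IC.
#'
#' @param p probabilities in `[0, 1]`.
#' @return numeric vector of bits; `NA` where `p` is 0 or `NA`.
#' @examples
#' information_content(4 / 11)  # 1.459...
#' @export
information_content <- function(p) {
  if (!is.numeric(p)) bounds_error("p must be numeric")
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) bounds_error(sprintf("probability %g outside [0, 1]", p[bad][1L]))
  ifelse(is.na(p) | p == 0, NA_real_, -log2(p))
}

#' Occurrence probability of a term in an annotation data set
#'
#' `p(t)` = (number of annotation units assigned to `t` or to any offspring of
#' `t`) / (total units in the data set). With the default
#' `count_mode = "unique"` a unit annotated to several terms in that closure
#' is counted once, which keeps `p <= 1` and `p` monotone along edges;
#' `count_mode = "sum"` reproduces the literal add-the-counts reading, where
#' each term's direct count is summed over the closure.
#'
#' @param dag an `ontology_dag`.
#' @param ann an `annotation_set`.
#' @param t a non-obsolete term id.
#' @param count_mode `"unique"` (default) or `"sum"`.
#' @return a probability (may exceed 1 under `"sum"` when units overlap).
#' @export
term_probability <- function(dag, ann, t, count_mode = c("unique", "sum")) {
  stopifnot(inherits(dag, "ontology_dag"), inherits(ann, "annotation_set"))
  count_mode <- match.arg(count_mode)
  check_known_term(dag, t)
  closure <- c(t, offspring_set(dag, t))
  if (count_mode == "unique") {
    n <- sum(vapply(ann$by_gene, function(terms)
      any(terms %in% closure), FALSE))
  } else {
    n <- sum(vapply(ann$by_gene, function(terms)
      sum(terms %in% closure), 0L))
  }
  n / ann$n_genes
}

#' Metric configuration
#'
#' @param max_offspring the normalization constant `M` for [offsp_n()].
#'   `NULL` (default) derives it from the loaded ontology as the root's
#'   offspring count; override with a printed value (e.g. 8267) to reproduce
#'   published tables.
#' @param count_mode unit counting inside `p(t)`; see [term_probability()].
#' @return a `metric_config` list.
#' @export
metric_config <- function(max_offspring = NULL, count_mode = c("unique", "sum")) {
  count_mode <- match.arg(count_mode)
  if (!is.null(max_offspring)) {
    max_offspring <- as.numeric(max_offspring)
    if (length(max_offspring) != 1L || is.na(max_offspring) || max_offspring < 1) {
      bounds_error("max_offspring must be a single value >= 1")
    }
  }
  structure(list(max_offspring = max_offspring, count_mode = count_mode,
                 log_base_ic = 2), class = "metric_config")
}

#' Compute every specificity metric for every term
#'
#' One record per non-obsolete term: ancestor count, offspring count,
#' `offsp_n`, `go_prop`, and — when an annotation set is supplied — `p` and
#' `ic`. Annotation counts are propagated bottom-up over a topological order
#' (each term's closure unit set is the union of its direct units and its
#' children's closures), so the whole table costs one sweep.
#'
#' @param dag an `ontology_dag`.
#' @param ann optional `annotation_set`; when absent, `p` and `ic` are `NA`.
#' @param cfg a [metric_config()].
#' @return data.frame with columns `term_id`, `name`, `n_ancestors`,
#'   `n_offspring`, `offsp_n`, `go_prop`, `p`, `ic`, one row per term in
#'   topological order.
#' @examples
#' fx <- figure1_fixture()
#' tab <- compute_all(fx$dag, fx$ann)
#' tab[tab$term_id == "GO:Term_3", c("p", "ic")]
#' @export
compute_all <- function(dag, ann = NULL, cfg = metric_config()) {
  stopifnot(inherits(dag, "ontology_dag"), inherits(cfg, "metric_config"))
  reach <- reachability_table(dag)
  ids <- names(reach)
  n_anc <- vapply(reach, function(r) length(r$ancestors), 0L)
  n_off <- vapply(reach, function(r) length(r$offspring), 0L)

  M <- cfg$max_offspring %||% length(reach[[dag$root_id]]$offspring)
  if (any(n_off > M)) {
    bounds_error(sprintf(
      "max_offspring = %g is smaller than the largest offspring count (%d)",
      M, max(n_off)))
  }

  p <- rep(NA_real_, length(ids))
  names(p) <- ids
  if (!is.null(ann)) {
    stopifnot(inherits(ann, "annotation_set"))
    units <- names(ann$by_gene)
    direct <- lapply(stats::setNames(ids, ids), function(i) integer(0))
    for (ui in seq_along(units)) {
      for (t in ann$by_gene[[ui]]) {
        if (!is.null(direct[[t]])) direct[[t]] <- c(direct[[t]], ui)
      }
    }
    if (cfg$count_mode == "unique") {
      closure <- direct
      for (v in rev(dag$topo)) {          # children before parents
        cs <- dag$children[[v]]
        if (length(cs) > 0L) {
          closure[[v]] <- unique(c(closure[[v]],
                                   unlist(closure[cs], use.names = FALSE)))
        }
      }
      p <- vapply(ids, function(v) length(closure[[v]]), 0L) / ann$n_genes
    } else {
      cnt <- vapply(ids, function(v) length(direct[[v]]), 0L)
      p <- vapply(ids, function(v)
        cnt[[v]] + sum(cnt[reach[[v]]$offspring]), 0) / ann$n_genes
    }
  }

  data.frame(
    term_id = ids,
    name = vapply(ids, function(i) dag$terms[[i]]$name %||% NA_character_, ""),
    n_ancestors = as.integer(n_anc),
    n_offspring = as.integer(n_off),
    # M = 0 only for a single-node ontology, where the root is its own leaf
    # and the normalization is degenerately 0
    offsp_n = if (M >= 1) offsp_n(n_off, M) else rep(0, length(ids)),
    go_prop = go_proportion(n_off, n_anc),
    p = as.numeric(p),
    # direct -log2 rather than information_content(): under count_mode="sum"
    # the literal reading can push p above 1, which is reported as-is
    ic = ifelse(is.na(p) | p == 0, NA_real_, -log2(as.numeric(p))),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
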