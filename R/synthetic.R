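#' @title Synthetic ontologies and annotation sets
#' @description Deterministic fixtures — including the frozen toy ontology
#'   behind the worked information-content example — and a seeded generator of
#'   GO-like layered random DAGs with depth-biased annotations, so the whole
#'   test suite runs without any download.
#' @name synthetic
NULL

# run `expr` under a seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' The frozen toy ontology and 11-unit annotation table
#'
#' A small simplified GO-like hierarchy used by the worked IC example:
#' `GO:Term_1` is the root (0 ancestors), `GO:Term_2` and `GO:Term_3` are its
#' children (1 ancestor each), `GO:Term_3` carries one directly annotated
#' unit and its offspring carry three more, and the data set holds 11 distinct
#' units in all — so `p(GO:Term_3) = 4/11` and its IC is 1.5 bits at one
#' decimal. The topology beyond those constraints is arbitrary but frozen, so
#' test expectations never drift.
#'
#' @return `list(dag = ontology_dag, ann = annotation_set)`.
#' @examples
#' fx <- figure1_fixture()
#' term_probability(fx$dag, fx$ann, "GO:Term_3")  # 4/11
#' @export
figure1_fixture <- function() {
  edges <- list(
    c("GO:Term_2", "GO:Term_1"),
    c("GO:Term_3", "GO:Term_1"),
    c("GO:Term_4", "GO:Term_3"),
    c("GO:Term_5", "GO:Term_3"),
    c("GO:Term_6", "GO:Term_2"),
    c("GO:Term_7", "GO:Term_2")
  )
  nm <- c("GO:Term_1" = "root function", "GO:Term_2" = "broad function A",
          "GO:Term_3" = "broad function B", "GO:Term_4" = "narrow function B1",
          "GO:Term_5" = "narrow function B2", "GO:Term_6" = "narrow function A1",
          "GO:Term_7" = "narrow function A2")
  dag <- build_dag(edges, root_id = "GO:Term_1", names = nm,
                   namespace = "molecular_function")
  by_gene <- list(
    P01 = "GO:Term_2",
    P02 = "GO:Term_6", P03 = "GO:Term_6",
    P04 = "GO:Term_3",                        # 1 direct unit on the target
    P05 = "GO:Term_4", P06 = "GO:Term_4",     # 3 units on its offspring
    P07 = "GO:Term_5",
    P08 = "GO:Term_7", P09 = "GO:Term_7", P10 = "GO:Term_7",
    P11 = "GO:Term_1"
  )
  list(dag = dag, ann = annotation_set(by_gene, dag))
}

#' Parameters for the synthetic generator
#'
#' @param n_terms number of terms including the root (`>= 2`).
#' @param max_parents maximum parents per non-root term (`>= 1`).
#' @param n_units number of annotation units (`>= 1`).
#' @param depth_bias `>= 0`; sampling weight for a term at layer `d` is
#'   `(d + 1)^depth_bias`, so larger values push annotations toward deep,
#'   specific terms the way curated data does. 0 is uniform.
#' @param seed integer seed; identical specs give byte-identical output.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_terms = 60L, max_parents = 3L, n_units = 200L,
                           depth_bias = 1, seed = 7L) {
  if (n_terms < 2L) spec_error("n_terms must be >= 2")
  if (max_parents < 1L) spec_error("max_parents must be >= 1")
  if (n_units < 1L) spec_error("n_units must be >= 1")
  if (depth_bias < 0) spec_error("depth_bias must be >= 0")
  structure(list(n_terms = as.integer(n_terms),
                 max_parents = as.integer(max_parents),
                 n_units = as.integer(n_units),
                 depth_bias = depth_bias, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a GO-like random DAG with annotations
#'
#' Terms are arranged in layers (root alone at layer 0); every non-root term
#' draws 1..`max_parents` parents from strictly earlier layers, weighted
#' toward the immediately preceding layer, which mimics the broad-to-narrow
#' shape of real ontologies and guarantees acyclicity and single-rootedness by
#' construction. Each annotation unit is assigned 1 or more terms sampled with
#' the spec's depth bias.
#'
#' @param spec a [synthetic_spec()].
#' @return `list(dag = ontology_dag, ann = annotation_set)`; deterministic
#'   under the spec's seed.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_terms
    ids <- c("GO:S0000001",
             sprintf("GO:S%07d", seq_len(n - 1L) + 1L))
    n_layers <- max(2L, ceiling(log2(n)) + 1L)
    per_layer <- ceiling((n - 1L) / (n_layers - 1L))
    layer <- c(0L, 1L + (seq_len(n - 1L) - 1L) %/% per_layer)
    names(layer) <- ids

    edges <- list()
    for (i in seq(2L, n)) {
      earlier <- ids[layer < layer[[i]]]
      w <- 2^-(layer[[i]] - layer[earlier] - 1L)   # prefer the previous layer
      k <- sample.int(min(spec$max_parents, length(earlier)), 1L)
      ps <- if (length(earlier) == 1L) earlier else
        sample(earlier, k, prob = w)
      for (p in ps) edges[[length(edges) + 1L]] <- c(ids[[i]], p)
    }
    dag <- build_dag(edges, root_id = ids[[1L]],
                     namespace = "molecular_function")

    w_ann <- (layer + 1)^spec$depth_bias
    by_gene <- lapply(seq_len(spec$n_units), function(u) {
      m <- 1L + stats::rpois(1L, 1)
      m <- min(m, n)
      sample(ids, m, prob = w_ann)
    })
    names(by_gene) <- sprintf("U%05d", seq_len(spec$n_units))
    list(dag = dag, ann = annotation_set(by_gene, dag))
  })
}

#' Write a DAG and annotation set as on-disk fixture files
#'
#' Emits `ontology.obo` (OBO 1.2) and `annotations.tsv` (NCBI gene2go
#' dialect) into `directory`; both round-trip through [parse_obo()] and
#' [read_gene2go()] to objects equal to the inputs.
#'
#' @param dag an `ontology_dag`.
#' @param ann an `annotation_set`.
#' @param directory writable output directory (created if missing).
#' @return named character vector of the two file paths.
#' @export
write_fixture <- function(dag, ann, directory) {
  stopifnot(inherits(dag, "ontology_dag"), inherits(ann, "annotation_set"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) spec_error(sprintf("cannot create directory '%s'", directory))
  }
  obo_path <- file.path(directory, "ontology.obo")
  ann_path <- file.path(directory, "annotations.tsv")
  tryCatch({
    write_obo(dag, obo_path)
    write_gene2go(ann, dag, ann_path)
  }, error = function(e) {
    spec_error(sprintf("failed writing fixture under '%s': %s",
                       directory, conditionMessage(e)))
  })
  c(obo = obo_path, annotations = ann_path)
}
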