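# Independent oracles and fixture builders shared across the suite.

# Brute-force reachability by repeated boolean matrix squaring. Entirely
# independent of the package's DFS/topological traversals: closure[u, v] is
# TRUE iff v is an ancestor of u (reachable via child->parent edges).
oracle_ancestor_closure <- function(dag) {
  ids <- names(dag$parents)
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (id in ids) A[id, dag$parents[[id]]] <- TRUE
  R <- A
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) return(R)
    R <- R2
  }
}

withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("gospec-test-")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}

# Small named fixtures
diamond_dag <- function() {
  build_dag(list(c("X", "R"), c("Y", "R"), c("Z", "X"), c("Z", "Y")),
            root_id = "R")
}

chain_dag <- function() {
  build_dag(list(c("A", "R"), c("B", "A")), root_id = "R")
}

# OBO text for the collagen-binding neighborhood:
# GO:0003674 <- GO:0005488 <- GO:0005515 <- GO:0005518 <- GO:0070052
collagen_obo <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: GO:0003674", "name: molecular_function",
    "namespace: molecular_function", "",
    "[Term]", "id: GO:0005488", "name: binding",
    "namespace: molecular_function", "is_a: GO:0003674 ! molecular_function", "",
    "[Term]", "id: GO:0005515", "name: protein binding",
    "namespace: molecular_function", "is_a: GO:0005488 ! binding", "",
    "[Term]", "id: GO:0005518", "name: collagen binding",
    "namespace: molecular_function", "is_a: GO:0005515 ! protein binding", "",
    "[Term]", "id: GO:0070052", "name: collagen V binding",
    "namespace: molecular_function", "is_a: GO:0005518 ! collagen binding", "")
}

# minimal 3-stanza ontology: root; A is_a root; B is_a A
tiny_obo <- function(extra = character(0)) {
  c("format-version: 1.2", "",
    "[Term]", "id: R", "name: root", "namespace: molecular_function", "",
    "[Term]", "id: A", "name: term A", "namespace: molecular_function",
    "is_a: R", "",
    "[Term]", "id: B", "name: term B", "namespace: molecular_function",
    "is_a: A", "",
    extra)
}

gene2go_lines <- function(rows,
                          header = "#tax_id\tGeneID\tGO_ID\tEvidence\tQualifier\tGO_term\tPubMed\tCategory") {
  c(header, rows)
}
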