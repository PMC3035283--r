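#' @title Annotation tables
#' @description Readers for protein/gene-to-term association tables. Both the
#'   NCBI gene2go dialect and GAF 2.x collapse to the same `annotation_set`:
#'   a deduplicated map from annotation unit (gene or protein id, treated
#'   opaquely) to the set of terms it is directly annotated with, plus the
#'   number of distinct units — the denominator of every term probability.
#' @name annotations
NULL

# Category column values in NCBI gene2go, keyed by ontology namespace.
GENE2GO_CATEGORY <- c(molecular_function = "Function",
                      biological_process = "Process",
                      cellular_component = "Component")
GAF_ASPECT <- c(molecular_function = "F",
                biological_process = "P",
                cellular_component = "C")

new_annotation_set <- function(by_gene, namespace, dropped = c(unknown = 0L,
                                                              not = 0L)) {
  by_gene <- by_gene[lengths(by_gene) > 0L]
  if (length(by_gene) == 0L) empty_annotation_error()
  by_gene <- lapply(by_gene, function(x) sort(unique(x)))
  structure(
    list(by_gene = by_gene, n_genes = length(by_gene),
         namespace = namespace, dropped = dropped),
    class = "annotation_set"
  )
}

#' Construct an annotation set from a gene -> terms list
#'
#' Validates every term against the companion DAG (alt ids resolved,
#' unresolvable or obsolete terms dropped with a reported count) and
#' deduplicates.
#'
#' @param by_gene named list: unit id -> character vector of term ids.
#' @param dag the `ontology_dag` the annotations refer to.
#' @return an `annotation_set`.
#' @export
annotation_set <- function(by_gene, dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  n_drop <- 0L
  by_gene <- lapply(by_gene, function(terms) {
    res <- resolve_term_id(dag, terms)
    keep <- !is.na(res) & res %in% names(dag$parents)
    n_drop <<- n_drop + sum(!keep)
    unique(res[keep])
  })
  if (n_drop > 0L) {
    message(sprintf("dropped %d annotation(s) to unknown or obsolete terms",
                    n_drop))
  }
  ns <- dag$terms[[dag$root_id]]$namespace
  new_annotation_set(by_gene, ns, dropped = c(unknown = n_drop, not = 0L))
}

#' Read an NCBI gene2go association table
#'
#' Accepts the full NCBI dialect (`#tax_id`, `GeneID`, `GO_ID`, `Evidence`,
#' `Qualifier`, `GO_term`, `PubMed`, `Category`) and the minimal two-column
#' `GeneID`/`GOTerm` dialect. Rows are filtered to the DAG's namespace (via
#' the `Category` column when present, else by each term's namespace in the
#' DAG), `NOT`-qualified rows are dropped, duplicates collapsed, alternate ids
#' resolved to primaries, and annotations to unknown or obsolete terms dropped
#' with a reported count.
#'
#' @param input path (gzip accepted), connection, or character lines.
#' @param dag the `ontology_dag` the annotations refer to.
#' @param taxon_filter optional taxon id; rows from other taxa are dropped
#'   (requires a tax_id column).
#' @return an `annotation_set`.
#' @export
read_gene2go <- function(input, dag, taxon_filter = NULL) {
  stopifnot(inherits(dag, "ontology_dag"))
  lines <- read_text_lines(input)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) schema_error("empty gene2go input", found = character(0))

  header <- sub("^#", "", lines[[1L]])
  cols <- strsplit(header, "\t", fixed = TRUE)[[1L]]
  gene_col <- match_first(cols, c("GeneID", "geneid"))
  go_col <- match_first(cols, c("GO_ID", "GOTerm", "GO_term_ID"))
  if (is.na(gene_col) || is.na(go_col)) {
    schema_error(sprintf(
      "gene2go input must have GeneID and GO_ID/GOTerm columns; found: %s",
      paste(cols, collapse = ", ")), found = cols)
  }
  tax_col <- match_first(cols, c("tax_id", "taxid"))
  qual_col <- match_first(cols, "Qualifier")
  cat_col <- match_first(cols, "Category")

  body <- lines[-1L]
  body <- body[!grepl("^#", body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  ok_len <- lengths(fields) >= max(gene_col, go_col, tax_col, qual_col,
                                   cat_col, na.rm = TRUE)
  fields <- fields[ok_len]

  get <- function(i) vapply(fields, function(f) f[[i]], "")
  genes <- get(gene_col)
  gos <- get(go_col)
  keep <- rep(TRUE, length(genes))
  n_not <- 0L
  if (!is.na(qual_col)) {
    is_not <- grepl("(^|\\|)NOT($|\\|)", get(qual_col))
    n_not <- sum(is_not)
    keep <- keep & !is_not
  }
  if (!is.null(taxon_filter)) {
    if (is.na(tax_col)) {
      schema_error("taxon_filter given but no tax_id column present",
                   found = cols)
    }
    keep <- keep & get(tax_col) == as.character(taxon_filter)
  }
  ns <- dag$terms[[dag$root_id]]$namespace
  if (!is.na(cat_col) && ns %in% names(GENE2GO_CATEGORY)) {
    keep <- keep & get(cat_col) == GENE2GO_CATEGORY[[ns]]
  }
  build_annotation_set(genes[keep], gos[keep], dag, ns, n_not)
}

#' Read a GAF 2.x association table
#'
#' Comment lines starting with `!` are skipped; `DB_Object_ID` (column 2) is
#' the annotation unit, column 5 the term, the qualifier column drops `NOT`
#' rows, and the aspect column (F/P/C) filters to the DAG's namespace. The
#' same deduplication and unknown-term handling as [read_gene2go()] applies,
#' so identical associations in either format yield identical sets.
#'
#' @inheritParams read_gene2go
#' @return an `annotation_set`.
#' @export
read_gaf <- function(input, dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  lines <- read_text_lines(input)
  lines <- lines[nzchar(lines) & !grepl("^!", lines)]
  if (length(lines) == 0L) empty_annotation_error("GAF input holds no data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 15L | nf > 17L)) {
    schema_error(sprintf(
      "GAF 2.x rows must have 15-17 tab-separated columns; saw %d",
      nf[nf < 15L | nf > 17L][1L]))
  }
  genes <- vapply(fields, `[[`, "", 2L)
  quals <- vapply(fields, `[[`, "", 4L)
  gos <- vapply(fields, `[[`, "", 5L)
  aspects <- vapply(fields, `[[`, "", 9L)
  is_not <- grepl("(^|\\|)NOT($|\\|)", quals)
  ns <- dag$terms[[dag$root_id]]$namespace
  keep <- !is_not
  if (ns %in% names(GAF_ASPECT)) keep <- keep & aspects == GAF_ASPECT[[ns]]
  build_annotation_set(genes[keep], gos[keep], dag, ns, sum(is_not))
}

match_first <- function(cols, candidates) {
  hits <- match(candidates, cols)
  hits <- hits[!is.na(hits)]
  if (length(hits) == 0L) NA_integer_ else hits[[1L]]
}

build_annotation_set <- function(genes, gos, dag, ns, n_not) {
  res <- resolve_term_id(dag, gos)
  res[!res %in% names(dag$parents)] <- NA_character_  # obsolete -> unknown
  # when no Category/aspect filter applied, restrict by the term's namespace
  known <- !is.na(res)
  in_ns <- known & vapply(res, function(id) {
    !is.na(id) && identical(dag$terms[[id]]$namespace, ns)
  }, FALSE)
  n_unknown <- sum(!known)
  if (n_unknown > 0L) {
    message(sprintf("dropped %d annotation(s) to unknown or obsolete terms",
                    n_unknown))
  }
  genes <- genes[in_ns]
  res <- res[in_ns]
  if (length(genes) == 0L) empty_annotation_error()
  by_gene <- split(res, genes)
  new_annotation_set(by_gene, ns,
                     dropped = c(unknown = n_unknown, not = as.integer(n_not)))
}

#' Write an annotation set as a gene2go-dialect TSV
#'
#' Emits the 8-column NCBI dialect with a `#tax_id` header; round-trips
#' through [read_gene2go()] to an equal `annotation_set`.
#'
#' @param ann an `annotation_set`.
#' @param dag the companion `ontology_dag` (for term names and categories).
#' @param path optional output path; lines returned when `NULL`.
#' @param tax_id taxon id written in column 1.
#' @return the TSV lines, invisibly when written to `path`.
#' @export
write_gene2go <- function(ann, dag, path = NULL, tax_id = "9606") {
  stopifnot(inherits(ann, "annotation_set"), inherits(dag, "ontology_dag"))
  cat_val <- GENE2GO_CATEGORY[ann$namespace]
  if (is.na(cat_val)) cat_val <- "Function"
  lines <- "#tax_id\tGeneID\tGO_ID\tEvidence\tQualifier\tGO_term\tPubMed\tCategory"
  for (g in sort(names(ann$by_gene))) {
    for (t in ann$by_gene[[g]]) {
      nm <- dag$terms[[t]]$name %||% t
      lines <- c(lines, paste(tax_id, g, t, "IEA", "-", nm, "-", cat_val,
                              sep = "\t"))
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "annotation_set: %d units, %d associations, namespace %s (dropped: %d unknown, %d NOT)\n",
    x$n_genes, sum(lengths(x$by_gene)), x$namespace,
    x$dropped[["unknown"]], x$dropped[["not"]]))
  invisible(x)
}
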