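# Classed conditions so callers (and the CLI) can distinguish failure modes.
# Every condition also carries class "gospec_error".

gospec_abort <- function(class, msg, ...) {
  cond <- structure(
    class = c(class, "gospec_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}

cyclic_ontology_error <- function(member, msg = NULL) {
  gospec_abort(
    "cyclic_ontology_error",
    msg %||% sprintf("ontology contains a cycle involving term '%s'", member),
    member = member
  )
}

dangling_edge_error <- function(term_id, parent_id = NULL) {
  msg <- if (is.null(parent_id)) {
    sprintf("term '%s' has no declared connection to the root", term_id)
  } else {
    sprintf("term '%s' references undefined parent '%s'", term_id, parent_id)
  }
  gospec_abort("dangling_edge_error", msg, term_id = term_id, parent_id = parent_id)
}

root_resolution_error <- function(candidates) {
  gospec_abort(
    "root_resolution_error",
    sprintf(
      "expected exactly one root term, found %d candidate(s): %s",
      length(candidates), paste(candidates, collapse = ", ")
    ),
    candidates = candidates
  )
}

unknown_term_error <- function(term_id) {
  gospec_abort(
    "unknown_term_error",
    sprintf("term '%s' is not a known (non-obsolete) term in this ontology", term_id),
    term_id = term_id
  )
}

bounds_error <- function(msg) {
  gospec_abort("bounds_error", msg)
}

schema_error <- function(msg, found = NULL) {
  gospec_abort("schema_error", msg, found = found)
}

empty_annotation_error <- function(msg = "no annotation rows survived filtering") {
  gospec_abort("empty_annotation_error", msg)
}

spec_error <- function(msg) {
  gospec_abort("spec_error", msg)
}

namespace_error <- function(namespaces) {
  gospec_abort(
    "namespace_error",
    sprintf(
      "file contains %d namespaces (%s); pass namespace_filter to pick one",
      length(namespaces), paste(namespaces, collapse = ", ")
    ),
    namespaces = namespaces
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
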