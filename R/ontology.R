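#' Build an ontology DAG from a term-parent table
#'
#' Constructs a directed acyclic graph of ontology terms from a table of
#' "is a / part of" relations, the backbone for every information-content
#' computation in the package. Each row states that `term` is a child of
#' `parent`; both relation kinds are treated identically. The graph must be
#' acyclic and must funnel into a single most-general term (the root), so
#' that every term has a directed path to it.
#'
#' Ancestor sets are cached at construction and are *reflexive*: the ancestor
#' set of a term contains the term itself. Every formula in the package that
#' consumes ancestor sets (shared-ancestor intersections, weighted sums)
#' relies on this convention; the strict relation is available through
#' [term_comparable()] combined with an identity check.
#'
#' @param relations A data frame with character columns `term` and `parent`,
#'   one row per direct relation (child first).
#' @return An object of class `ontology_dag`.
#' @examples
#' rel <- tibble::tibble(
#'   term   = c("c1", "c2", "c3", "c4", "c6"),
#'   parent = c("r", "r", "r", "c2", "c3")
#' )
#' ont <- ontology_graph(rel)
#' ancestors(ont, "c4")
#' @seealso [ancestors()], [min_common_ancestors()], [read_obo()]
#' @export
ontology_graph <- function(relations) {
  if (!is.data.frame(relations) || !all(c("term", "parent") %in% names(relations))) {
    abort("`relations` must be a data frame with columns `term` and `parent`.",
          class = "funcoh_error_argument")
  }
  edges <- data.frame(
    from = as.character(relations$term),
    to   = as.character(relations$parent),
    stringsAsFactors = FALSE
  )
  if (nrow(edges) == 0L) {
    abort("`relations` must contain at least one relation.",
          class = "funcoh_error_argument")
  }
  if (anyNA(edges$from) || anyNA(edges$to)) {
    abort("`relations` contains missing term identifiers.",
          class = "funcoh_error_argument")
  }
  g <- igraph::graph_from_data_frame(unique(edges), directed = TRUE)
  if (!igraph::is_dag(g)) {
    abort(paste0("ontology relations contain a cycle: ",
                 paste(find_cycle(g), collapse = " -> ")),
          class = "funcoh_error_cycle")
  }
  sinks <- igraph::V(g)$name[igraph::degree(g, mode = "out") == 0L]
  if (length(sinks) != 1L) {
    abort(sprintf(
      "ontology must have exactly one root (found %d: %s)",
      length(sinks), paste(utils::head(sinks, 5L), collapse = ", ")),
      class = "funcoh_error_structure")
  }
  new_ontology_dag(g, root = sinks)
}

new_ontology_dag <- function(graph, root) {
  terms <- igraph::V(graph)$name
  # reflexive transitive closure upward, cached once; ego() includes the
  # start vertex, which is exactly the convention the measures need
  anc <- igraph::ego(graph, order = igraph::vcount(graph),
                     nodes = terms, mode = "out")
  anc <- lapply(anc, function(v) v$name)
  names(anc) <- terms
  structure(
    list(graph = graph, terms = terms, root = root, anc = anc),
    class = "ontology_dag"
  )
}

# report one directed cycle for the error message
find_cycle <- function(g) {
  comp <- igraph::components(g, mode = "strong")
  big <- which(comp$csize > 1L)[1L]
  v <- which(comp$membership == big)[1L]
  nb <- igraph::neighbors(g, v, mode = "out")
  nb <- nb[comp$membership[nb] == big][1L]
  back <- igraph::shortest_paths(g, from = nb, to = v, mode = "out")$vpath[[1L]]
  c(igraph::V(g)$name[v], igraph::V(g)$name[back])
}

check_terms <- function(ontology, terms) {
  stopifnot(inherits(ontology, "ontology_dag"))
  unknown <- setdiff(terms, ontology$terms)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown ontology term(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "funcoh_error_lookup")
  }
  invisible(terms)
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("<ontology_dag> %d terms, %d relations, root '%s'\n",
              length(x$terms), igraph::ecount(x$graph), x$root))
  invisible(x)
}

#' Ancestors of an ontology term
#'
#' Returns the reflexive upward closure of a term: the term itself plus every
#' term reachable by following is-a/part-of edges, always including the root.
#'
#' @param ontology An [ontology_graph()] object.
#' @param term A single term identifier.
#' @return Character vector of term identifiers.
#' @export
ancestors <- function(ontology, term) {
  if (length(term) != 1L) {
    abort("`term` must be a single term identifier.",
          class = "funcoh_error_argument")
  }
  check_terms(ontology, term)
  ontology$anc[[term]]
}

#' Are two terms comparable?
#'
#' Two terms are comparable when one is an ancestor of the other (identity
#' included); terms on disjoint branches are not.
#'
#' @inheritParams ancestors
#' @param ci,cj Term identifiers.
#' @return `TRUE` or `FALSE`.
#' @export
term_comparable <- function(ontology, ci, cj) {
  check_terms(ontology, c(ci, cj))
  cj %in% ontology$anc[[ci]] || ci %in% ontology$anc[[cj]]
}

#' Directed path length between comparable terms
#'
#' Minimum number of edges along directed ancestor paths between two
#' comparable terms. Defined only when the terms are comparable.
#'
#' @inheritParams term_comparable
#' @return A non-negative integer edge count.
#' @export
term_path_length <- function(ontology, ci, cj) {
  check_terms(ontology, c(ci, cj))
  if (!term_comparable(ontology, ci, cj)) {
    abort(sprintf("terms '%s' and '%s' are not comparable; path length undefined.",
                  ci, cj),
          class = "funcoh_error_domain")
  }
  d1 <- igraph::distances(ontology$graph, v = ci, to = cj, mode = "out")[1L, 1L]
  d2 <- igraph::distances(ontology$graph, v = cj, to = ci, mode = "out")[1L, 1L]
  as.integer(min(d1, d2))
}

#' Minimum common ancestors of a set of terms
#'
#' The most specific terms that are (reflexive) ancestors of every input
#' term. On a DAG the result can contain more than one term; it never
#' contains two comparable terms. With a single input term the result is the
#' term itself.
#'
#' @inheritParams ancestors
#' @param terms Character vector of one or more term identifiers.
#' @return Character vector of term identifiers (non-redundant).
#' @export
min_common_ancestors <- function(ontology, terms) {
  if (length(terms) < 1L) {
    abort("`terms` must contain at least one term.",
          class = "funcoh_error_argument")
  }
  check_terms(ontology, terms)
  common <- Reduce(intersect, ontology$anc[terms])
  reduce_nonredundant(ontology, common)
}

#' Reduce a term set to its most specific members
#'
#' Removes every term that is a strict ancestor of another member, leaving a
#' non-redundant set (no two members comparable). Idempotent and
#' order-independent.
#'
#' @inheritParams ancestors
#' @param terms Character vector of term identifiers.
#' @return Character vector of the most specific members, in input order.
#' @export
reduce_nonredundant <- function(ontology, terms) {
  terms <- unique(as.character(terms))
  check_terms(ontology, terms)
  if (length(terms) <= 1L) {
    return(terms)
  }
  is_strict_anc <- vapply(terms, function(t) {
    any(vapply(setdiff(terms, t),
               function(u) t %in% ontology$anc[[u]],
               logical(1)))
  }, logical(1))
  terms[!is_strict_anc]
}

#' Tabulate ontology relations
#'
#' @param x An `ontology_dag`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `parent`, one row per relation.
#' @export
tidy.ontology_dag <- function(x, ...) {
  e <- igraph::as_data_frame(x$graph, what = "edges")
  tibble::tibble(term = e$from, parent = e$to)
}
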