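#' Build an annotation corpus
#'
#' Associates molecules (proteins, domains, genes) with ontology terms and
#' precomputes the true-path closure index used by every information-content
#' computation. Each molecule's stored term set is reduced to its most
#' specific members (no two comparable terms); the closure index maps each
#' term to the molecules annotated with it *or any of its descendants*, so
#' that `molecules(ci)` is a subset of `molecules(cj)` whenever `cj` is an
#' ancestor of `ci`, and the root maps to every molecule.
#'
#' Annotations that reference terms absent from the ontology are dropped with
#' a warning (annotation data routinely carries obsolete identifiers), as are
#' molecules left with no valid terms.
#'
#' @param ontology An [ontology_graph()] object.
#' @param annotations Either a data frame with character columns `molecule`
#'   and `term`, or a named list mapping molecule identifiers to character
#'   vectors of terms.
#' @return An object of class `annotation_corpus`.
#' @examples
#' fx <- build_figure1()
#' info_content(fx$corpus, "c4")
#' @export
annotation_corpus <- function(ontology, annotations) {
  stopifnot(inherits(ontology, "ontology_dag"))
  if (is.data.frame(annotations)) {
    if (!all(c("molecule", "term") %in% names(annotations))) {
      abort("`annotations` data frame needs columns `molecule` and `term`.",
            class = "funcoh_error_argument")
    }
    ann <- split(as.character(annotations$term),
                 as.character(annotations$molecule))
  } else if (is.list(annotations) && !is.null(names(annotations))) {
    ann <- lapply(annotations, as.character)
  } else {
    abort("`annotations` must be a molecule/term data frame or a named list.",
          class = "funcoh_error_argument")
  }

  dropped <- 0L
  ann <- lapply(ann, function(ts) {
    ts <- unique(ts)
    keep <- ts %in% ontology$terms
    dropped <<- dropped + sum(!keep)
    ts[keep]
  })
  if (dropped > 0L) {
    warn(sprintf("dropped %d annotation(s) to terms absent from the ontology.",
                 dropped))
  }
  empty <- lengths(ann) == 0L
  if (any(empty)) {
    warn(sprintf("dropped %d molecule(s) with no valid annotations.",
                 sum(empty)))
    ann <- ann[!empty]
  }
  if (length(ann) == 0L) {
    abort("corpus is empty: no molecule has a valid annotation.",
          class = "funcoh_error_argument")
  }
  # most specific annotations only, in canonical order so parsed corpora do
  # not depend on input line order
  ann <- lapply(ann, function(ts) sort(reduce_nonredundant(ontology, ts)))
  ann <- ann[order(names(ann))]

  # true-path closure index: term -> molecules annotated at or below it
  closure <- lapply(ann, function(ts) unique(unlist(ontology$anc[ts],
                                                    use.names = FALSE)))
  long_term <- unlist(closure, use.names = FALSE)
  long_mol <- rep(names(closure), lengths(closure))
  index <- split(long_mol, long_term)
  index <- lapply(index, unique)

  structure(
    list(ontology = ontology, annotations = ann, index = index,
         molecules = names(ann)),
    class = "annotation_corpus"
  )
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat(sprintf("<annotation_corpus> %d molecules over %d ontology terms (%d annotated)\n",
              length(x$molecules), length(x$ontology$terms), length(x$index)))
  invisible(x)
}

check_molecules <- function(corpus, molecules) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  unknown <- setdiff(molecules, corpus$molecules)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown or unannotated molecule(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "funcoh_error_lookup")
  }
  invisible(molecules)
}

# molecules supporting every term of a set, via the closure index
supporting_molecules <- function(corpus, terms) {
  sets <- lapply(terms, function(t) corpus$index[[t]] %||% character(0))
  Reduce(intersect, sets)
}

#' Information content of a term or term set
#'
#' For a single term `c`, the information content is
#' `-log2(|G_c| / |G_r|)`, where `G_c` is the set of molecules associated
#' with `c` through the true-path closure and `G_r` is the set of all
#' annotated molecules. For a set of terms it is `-log2` of the fraction of
#' molecules associated with *all* terms in the set. The root has information
#' content 0; descendants never have lower information content than their
#' ancestors. A set supported by no molecule yields `Inf`.
#'
#' @param corpus An [annotation_corpus()].
#' @param terms Character vector of term identifiers, interpreted as a set.
#' @return A single non-negative number, in bits.
#' @examples
#' fx <- build_figure1()
#' info_content(fx$corpus, "c4")          # 1
#' info_content(fx$corpus, c("c4", "c6")) # -log2(1/6)
#' @export
info_content <- function(corpus, terms) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  if (length(terms) < 1L) {
    abort("`terms` must contain at least one term.",
          class = "funcoh_error_argument")
  }
  check_terms(corpus$ontology, terms)
  n <- length(supporting_molecules(corpus, terms))
  if (n == 0L) {
    return(Inf)
  }
  # `+ 0` turns the root's -0 into a plain 0
  -log2(n / length(corpus$molecules)) + 0
}

#' Per-term information content table
#'
#' @param corpus An [annotation_corpus()].
#' @param terms Terms to report; defaults to every ontology term.
#' @return A tibble with columns `term`, `n_molecules` and `ic` (bits);
#'   unannotated terms have `n_molecules = 0` and infinite `ic`.
#' @export
term_info_content <- function(corpus, terms = NULL) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  terms <- terms %||% corpus$ontology$terms
  check_terms(corpus$ontology, terms)
  n <- vapply(terms, function(t) length(corpus$index[[t]] %||% character(0)),
              integer(1))
  tibble::tibble(
    term = terms,
    n_molecules = n,
    ic = ifelse(n == 0L, Inf, -log2(n / length(corpus$molecules)) + 0)
  )
}

#' Stored term set of a molecule
#'
#' @param corpus An [annotation_corpus()].
#' @param molecule A molecule identifier.
#' @return Character vector of the molecule's most specific terms.
#' @export
molecule_terms <- function(corpus, molecule) {
  if (length(molecule) != 1L) {
    abort("`molecule` must be a single identifier.",
          class = "funcoh_error_argument")
  }
  check_molecules(corpus, molecule)
  corpus$annotations[[molecule]]
}

#' Tabulate corpus annotations
#'
#' @param x An `annotation_corpus`.
#' @param ... Unused.
#' @return A tibble with columns `molecule` and `term`, one row per stored
#'   (most specific) annotation.
#' @export
tidy.annotation_corpus <- function(x, ...) {
  tibble::tibble(
    molecule = rep(names(x$annotations), lengths(x$annotations)),
    term = unlist(x$annotations, use.names = FALSE)
  )
}
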