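#' Resnik-style semantic similarity of two terms
#'
#' The information content of the minimum common ancestor of the pair,
#' maximized over the minimum-common-ancestor set when the DAG yields ties.
#' Symmetric; the self-similarity of a term equals its own information
#' content; terms whose only common ancestor is the root score 0.
#'
#' @param corpus An [annotation_corpus()].
#' @param ci,cj Term identifiers.
#' @return A non-negative number, in bits.
#' @examples
#' fx <- build_figure1()
#' delta_i(fx$corpus, "c4", "c6")  # 0: only the root is shared
#' delta_i(fx$corpus, "c4", "c2")  # 1: c2 is the common ancestor
#' @export
delta_i <- function(corpus, ci, cj) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  mca <- min_common_ancestors(corpus$ontology, c(ci, cj))
  max(vapply(mca, function(t) info_content(corpus, t), numeric(1)))
}

#' Self-normalized (Jiang-Conrath style) term similarity
#'
#' Bounded companion of [delta_i()]: the reciprocal of one plus the
#' Jiang-Conrath distance, `1 / (I(ci) + I(cj) - 2 * delta_i(ci, cj) + 1)`.
#' Lies in (0, 1] and equals 1 exactly when the distance is zero (in
#' particular at identity).
#'
#' @inheritParams delta_i
#' @return A number in (0, 1].
#' @export
delta_jc <- function(corpus, ci, cj) {
  d <- info_content(corpus, ci) + info_content(corpus, cj) -
    2 * delta_i(corpus, ci, cj)
  1 / (d + 1)
}

#' Minimum common ancestor set of two term sets
#'
#' Collects the minimum common ancestors of every cross pair of terms and
#' reduces the collection to its most specific members (the generalized
#' union, which preserves non-redundancy).
#'
#' @param corpus An [annotation_corpus()].
#' @param set_i,set_j Character vectors of term identifiers.
#' @return Character vector of terms, non-redundant.
#' @export
lambda_set <- function(corpus, set_i, set_j) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  ont <- corpus$ontology
  check_terms(ont, c(set_i, set_j))
  pool <- unique(unlist(
    lapply(set_i, function(ci)
      lapply(set_j, function(cj) min_common_ancestors(ont, c(ci, cj)))),
    use.names = FALSE))
  reduce_nonredundant(ont, pool)
}

rho_i_impl <- function(corpus, set_i, set_j) {
  info_content(corpus, lambda_set(corpus, set_i, set_j))
}

#' Functional similarity of two annotated term sets
#'
#' Scores the similarity of two molecules' (non-redundant) term sets.
#' Five measures are available:
#' \describe{
#'   \item{`rho_i`}{information content of the minimum-common-ancestor set
#'     [lambda_set()] of the two sets — the set-level generalization of
#'     [delta_i()].}
#'   \item{`rho_jc`}{self-normalized variant,
#'     `1 / (rho_i(Si,Si) + rho_i(Sj,Sj) - 2 rho_i(Si,Sj) + 1)`, in (0, 1]
#'     with `rho_jc(S, S) = 1`.}
#'   \item{`rho_a`}{mean of the term measure over all term pairs.}
#'   \item{`rho_m`}{maximum of the term measure over all term pairs.}
#'   \item{`rho_h`}{average, over both directions, of each term's best match
#'     in the other set (symmetric best-match average).}
#' }
#' All measures are symmetric in their arguments. Input sets are reduced to
#' their most specific members before scoring.
#'
#' @param corpus An [annotation_corpus()].
#' @param set_i,set_j Non-empty character vectors of term identifiers.
#' @param measure One of `"rho_i"`, `"rho_jc"`, `"rho_a"`, `"rho_m"`,
#'   `"rho_h"`.
#' @param term_measure Term-level measure used by the aggregating measures
#'   (`rho_a`, `rho_m`, `rho_h`): `"delta_i"` or `"delta_jc"`.
#' @return A single number.
#' @examples
#' fx <- build_figure1()
#' S1 <- molecule_terms(fx$corpus, "S1")
#' S3 <- molecule_terms(fx$corpus, "S3")
#' pair_similarity(fx$corpus, S1, S3, measure = "rho_a")   # 0.5
#' pair_similarity(fx$corpus, S1, S3, measure = "rho_jc")
#' @export
pair_similarity <- function(corpus, set_i, set_j,
                            measure = c("rho_i", "rho_jc", "rho_a",
                                        "rho_m", "rho_h"),
                            term_measure = c("delta_i", "delta_jc")) {
  measure <- match.arg(measure)
  term_measure <- match.arg(term_measure)
  stopifnot(inherits(corpus, "annotation_corpus"))
  if (length(set_i) == 0L || length(set_j) == 0L) {
    abort("term sets must be non-empty.", class = "funcoh_error_argument")
  }
  ont <- corpus$ontology
  set_i <- reduce_nonredundant(ont, set_i)
  set_j <- reduce_nonredundant(ont, set_j)

  if (measure == "rho_i") {
    return(rho_i_impl(corpus, set_i, set_j))
  }
  if (measure == "rho_jc") {
    d <- rho_i_impl(corpus, set_i, set_i) +
      rho_i_impl(corpus, set_j, set_j) -
      2 * rho_i_impl(corpus, set_i, set_j)
    return(1 / (d + 1))
  }

  tm <- switch(term_measure, delta_i = delta_i, delta_jc = delta_jc)
  m <- outer(seq_along(set_i), seq_along(set_j),
             Vectorize(function(a, b) tm(corpus, set_i[a], set_j[b])))
  switch(measure,
    rho_a = mean(m),
    rho_m = max(m),
    rho_h = (mean(apply(m, 1L, max)) + mean(apply(m, 2L, max))) / 2
  )
}

#' Pairwise similarity of molecules in a corpus
#'
#' Scores every unordered pair of the given molecules with
#' [pair_similarity()] on their stored term sets. For `rho_jc`,
#' self-similarities are computed once per molecule and reused.
#'
#' @param corpus An [annotation_corpus()].
#' @param molecules Molecules to compare; defaults to all annotated
#'   molecules.
#' @inheritParams pair_similarity
#' @return A tibble with columns `mol_i`, `mol_j` and `similarity`, pairs in
#'   lexicographic order.
#' @export
molecule_similarity <- function(corpus, molecules = NULL,
                                measure = c("rho_i", "rho_jc", "rho_a",
                                            "rho_m", "rho_h"),
                                term_measure = c("delta_i", "delta_jc")) {
  measure <- match.arg(measure)
  term_measure <- match.arg(term_measure)
  molecules <- sort(unique(molecules %||% corpus$molecules))
  check_molecules(corpus, molecules)
  if (length(molecules) < 2L) {
    abort("need at least two molecules to compare.",
          class = "funcoh_error_argument")
  }
  sets <- corpus$annotations[molecules]
  self_i <- NULL
  if (measure == "rho_jc") {
    self_i <- vapply(sets, function(s) rho_i_impl(corpus, s, s), numeric(1))
  }
  pairs <- utils::combn(molecules, 2L)
  sim <- vapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]
    b <- pairs[2L, k]
    if (measure == "rho_jc") {
      d <- self_i[[a]] + self_i[[b]] -
        2 * rho_i_impl(corpus, sets[[a]], sets[[b]])
      1 / (d + 1)
    } else {
      pair_similarity(corpus, sets[[a]], sets[[b]],
                      measure = measure, term_measure = term_measure)
    }
  }, numeric(1))
  tibble::tibble(mol_i = pairs[1L, ], mol_j = pairs[2L, ], similarity = sim)
}

#' Combine similarity scores from two sub-ontologies
#'
#' Funsim-style combination of a biological-process and a molecular-function
#' score: half the sum of the squared normalized scores,
#' `((s_bp/max_bp)^2 + (s_mf/max_mf)^2) / 2`. Lies in \[0, 1\] when each
#' score is within its maximum. The maxima default to the corpus-wide
#' observed maxima of the respective score distributions and are explicit
#' arguments so a theoretical maximum can be supplied instead.
#'
#' @param score_bp,score_mf Scores from the two sub-ontologies (vectorized).
#' @param max_bp,max_mf Strictly positive normalizing maxima.
#' @return Combined score(s).
#' @export
combine_subontology <- function(score_bp, score_mf, max_bp, max_mf) {
  check_scalar_number(max_bp, "max_bp", lower = 0, strict_lower = TRUE)
  check_scalar_number(max_mf, "max_mf", lower = 0, strict_lower = TRUE)
  ((score_bp / max_bp)^2 + (score_mf / max_mf)^2) / 2
}
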