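# Module-level coherence measures. A module is a set of annotated molecules;
# each measure scores how functionally homogeneous the set is, using the
# true-path-closed information content machinery of the corpus.

member_term_sets <- function(corpus, molecules) {
  molecules <- as.character(molecules)
  check_molecules(corpus, molecules)
  corpus$annotations[molecules]
}

# union of reflexive ancestor sets of a member's terms (its ancestor DAG)
ancestor_dag <- function(corpus, terms) {
  unique(unlist(corpus$ontology$anc[terms], use.names = FALSE))
}

single_term_ic <- function(corpus, terms) {
  vapply(terms, function(t) info_content(corpus, t), numeric(1))
}

#' Average pairwise coherence of a module
#'
#' Mean of a pairwise similarity measure over all `n(n-1)/2` unordered
#' member pairs. Any [pair_similarity()] measure can be plugged in; the
#' classic choice is the term-level average `rho_a`/`delta_i`, and the
#' set-level `rho_i` is the strongest aggregate in practice.
#'
#' @param corpus An [annotation_corpus()].
#' @param molecules Character vector of two or more module members.
#' @param measure,term_measure Passed to [pair_similarity()].
#' @return A single number.
#' @examples
#' fx <- build_figure1()
#' sigma_a(fx$corpus, c("S1", "S2", "S3", "S4"))  # 3/8
#' sigma_a(fx$corpus, c("S1", "S2", "S3"))        # 2/3
#' @export
sigma_a <- function(corpus, molecules,
                    measure = c("rho_a", "rho_i", "rho_jc", "rho_m", "rho_h"),
                    term_measure = c("delta_i", "delta_jc")) {
  measure <- match.arg(measure)
  term_measure <- match.arg(term_measure)
  sets <- member_term_sets(corpus, molecules)
  n <- length(sets)
  if (n < 2L) {
    abort("sigma_a needs a module of at least two molecules.",
          class = "funcoh_error_argument")
  }
  pairs <- utils::combn(n, 2L)
  mean(vapply(seq_len(ncol(pairs)), function(k) {
    pair_similarity(corpus, sets[[pairs[1L, k]]], sets[[pairs[2L, k]]],
                    measure = measure, term_measure = term_measure)
  }, numeric(1)))
}

#' Generalized information content of a module
#'
#' Information content of the module's joint minimum-common-ancestor set:
#' conceptually, for every tuple drawing one term from each member, take the
#' minimum common ancestors, pool them, and reduce to the most specific
#' terms; the score is the set information content of the result. The
#' enumeration is computed by iterative pairwise folding of [lambda_set()],
#' which is equivalent and avoids the exponential tuple walk. A conservative
#' measure: any member with unrelated functions pulls the ancestor set to
#' the root and the score to 0.
#'
#' @inheritParams sigma_a
#' @param molecules One or more module members; with a single member the
#'   score reduces to the information content of its term set.
#' @return A non-negative number, in bits.
#' @examples
#' fx <- build_figure1()
#' sigma_i(fx$corpus, c("S1", "S2", "S3", "S4"))  # 0
#' sigma_i(fx$corpus, c("S1", "S2", "S3"))        # 1
#' @export
sigma_i <- function(corpus, molecules) {
  sets <- member_term_sets(corpus, molecules)
  lam <- sets[[1L]]
  for (s in sets[-1L]) {
    lam <- lambda_set(corpus, lam, s)
  }
  info_content(corpus, lam)
}

#' Graph information content of a module
#'
#' Ratio of the summed information content of the terms in the intersection
#' of all members' ancestor DAGs to that of the terms in their union.
#' Bounded in \[0, 1\]; 1 when all members induce the same ancestor DAG, 0
#' when they share only the root. When the union carries no information (all
#' members annotated at the root alone) the module is trivially coherent and
#' the score is 1 by convention.
#'
#' @inheritParams sigma_i
#' @return A number in \[0, 1\].
#' @examples
#' fx <- build_figure1()
#' sigma_g(fx$corpus, c("S1", "S2", "S3"))  # 1/2
#' @export
sigma_g <- function(corpus, molecules) {
  sets <- member_term_sets(corpus, molecules)
  dags <- lapply(sets, function(s) ancestor_dag(corpus, s))
  inter <- Reduce(intersect, dags)
  uni <- Reduce(union, dags)
  denom <- sum(single_term_ic(corpus, uni))
  if (denom == 0) {
    return(1)
  }
  sum(single_term_ic(corpus, inter)) / denom
}

#' Weighted information content of a module
#'
#' Rewards functionality shared by *any* sub-group of the module rather than
#' by every member: each term in a member's ancestor DAG is weighted by the
#' number of members `n_t` whose DAG contains it, and the score is the
#' weighted information content of the terms shared by at least two members
#' over that of all terms,
#' `sum(n_t * I(t); n_t >= 2) / sum(n_t * I(t))`. Bounded in \[0, 1\]; the
#' root contributes nothing (zero information content). Designed for
#' bridged complexes built from overlapping sub-complexes, which
#' [sigma_i()] and [sigma_g()] penalize heavily.
#'
#' @inheritParams sigma_a
#' @return A number in \[0, 1\].
#' @examples
#' fx <- build_figure1()
#' sigma_w(fx$corpus, c("S1", "S2", "S3", "S4"))  # ~0.863
#' sigma_w(fx$corpus, c("S1", "S2", "S3"))        # 3/4
#' @export
sigma_w <- function(corpus, molecules) {
  sets <- member_term_sets(corpus, molecules)
  if (length(sets) < 2L) {
    abort("sigma_w needs a module of at least two molecules.",
          class = "funcoh_error_argument")
  }
  dags <- lapply(sets, function(s) ancestor_dag(corpus, s))
  counts <- table(unlist(dags, use.names = FALSE))
  ic <- single_term_ic(corpus, names(counts))
  w <- as.numeric(counts) * ic
  denom <- sum(w)
  if (denom == 0) {
    return(1)
  }
  sum(w[counts >= 2L]) / denom
}

coherence_measure_fn <- function(measure, pair_measure, term_measure) {
  switch(measure,
    sigma_a = function(corpus, mols)
      sigma_a(corpus, mols, measure = pair_measure,
              term_measure = term_measure),
    sigma_i = sigma_i,
    sigma_g = sigma_g,
    sigma_w = sigma_w,
    abort(sprintf("unknown coherence measure '%s'.", measure),
          class = "funcoh_error_argument")
  )
}

#' Score a table of modules
#'
#' Applies the selected coherence measures to every module in a long
#' module/molecule table, optionally subtracting a size-matched random
#' background (see [size_adjust()]). Backgrounds are estimated once per
#' distinct module size and shared across modules of that size.
#'
#' @param modules A data frame with columns `module` and `molecule`, one row
#'   per membership; other columns are ignored.
#' @param corpus An [annotation_corpus()].
#' @param measures Coherence measures to compute, a subset of
#'   `c("sigma_a", "sigma_i", "sigma_g", "sigma_w")`.
#' @param pair_measure,term_measure Pair-level configuration for `sigma_a`.
#' @param adjust If `TRUE`, also report size-adjusted scores
#'   (`<measure>_adj` columns): raw score minus the mean score of
#'   `n_random` uniformly drawn random modules of the same size.
#' @param n_random Number of random background modules per size.
#' @param seed Optional integer seed making the background reproducible.
#' @return A tibble with one row per module: `module`, `size`, one column
#'   per measure, and `<measure>_adj` columns when `adjust = TRUE`.
#'   Modules are ordered lexicographically.
#' @examples
#' fx <- build_figure1()
#' mods <- tibble::tibble(
#'   module = rep(c("R1", "R2"), c(4, 3)),
#'   molecule = c("S1", "S2", "S3", "S4", "S1", "S2", "S3")
#' )
#' score_modules(mods, fx$corpus)
#' @export
score_modules <- function(modules, corpus,
                          measures = c("sigma_a", "sigma_i", "sigma_g",
                                       "sigma_w"),
                          pair_measure = "rho_a", term_measure = "delta_i",
                          adjust = FALSE, n_random = 100L, seed = NULL) {
  if (!is.data.frame(modules) ||
      !all(c("module", "molecule") %in% names(modules))) {
    abort("`modules` must be a data frame with columns `module` and `molecule`.",
          class = "funcoh_error_argument")
  }
  if (nrow(modules) == 0L) {
    abort("`modules` is empty.", class = "funcoh_error_argument")
  }
  measures <- match.arg(measures, several.ok = TRUE)
  fns <- lapply(measures, coherence_measure_fn,
                pair_measure = pair_measure, term_measure = term_measure)
  names(fns) <- measures

  member_list <- split(as.character(modules$molecule),
                       as.character(modules$module))
  member_list <- lapply(member_list, unique)

  out <- purrr::map_dfr(names(member_list), function(id) {
    mols <- member_list[[id]]
    row <- tibble::tibble(module = id, size = length(mols))
    for (m in measures) {
      row[[m]] <- fns[[m]](corpus, mols)
    }
    row
  })

  if (adjust) {
    bg <- background_means(corpus, sizes = unique(out$size), fns = fns,
                           n_random = n_random, seed = seed)
    for (m in measures) {
      out[[paste0(m, "_adj")]] <-
        out[[m]] - bg[[m]][match(out$size, bg$size)]
    }
  }
  dplyr::arrange(out, .data$module)
}

# mean background score per module size, one tibble row per size
background_means <- function(corpus, sizes, fns, n_random, seed) {
  with_seed(seed, {
    rows <- lapply(sort(sizes), function(k) {
      draws <- replicate(n_random,
                         sample(corpus$molecules, k, replace = FALSE),
                         simplify = FALSE)
      means <- vapply(fns, function(f) {
        mean(vapply(draws, function(mols) f(corpus, mols), numeric(1)))
      }, numeric(1))
      tibble::tibble(size = k, !!!as.list(means))
    })
    dplyr::bind_rows(rows)
  })
}

#' Size-adjusted coherence score
#'
#' Coherence scores drift with module size, so raw scores of modules of
#' different sizes are not comparable. This subtracts the mean score of
#' `n_random` random modules of the same size, drawn by uniform molecule
#' sampling without replacement from the annotated corpus: the result is
#' zero-centered under the null at every size. Deterministic for a fixed
#' seed.
#'
#' @param corpus An [annotation_corpus()].
#' @param score Raw coherence score of the module under `score_fn`.
#' @param size Module size (number of molecules).
#' @param score_fn A function `(corpus, molecules) -> number`, e.g.
#'   `sigma_w`.
#' @param n_random Number of random modules (at least 30).
#' @param seed Optional integer seed.
#' @return `score` minus the random-background mean.
#' @export
size_adjust <- function(corpus, score, size, score_fn, n_random = 1000L,
                        seed = NULL) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  check_scalar_number(n_random, "n_random", lower = 30)
  check_scalar_number(size, "size", lower = 1)
  if (size > length(corpus$molecules)) {
    abort("module size exceeds the number of annotated molecules.",
          class = "funcoh_error_argument")
  }
  with_seed(seed, {
    bg <- replicate(n_random, {
      score_fn(corpus, sample(corpus$molecules, size, replace = FALSE))
    })
    score - mean(bg)
  })
}
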