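#' The six-molecule worked-example fixture
#'
#' Builds the small ontology and annotation corpus used throughout the
#' documentation and tests: six terms (`r`, `c1`, `c2`, `c3`, `c4`, `c6`)
#' with relations `c1 -> r`, `c2 -> r`, `c3 -> r`, `c4 -> c2`, `c6 -> c3`,
#' and six molecules annotated as `S1 = {c4}`, `S2 = {c4}`, `S3 = {c4, c6}`,
#' `S4 = {c1, c6}`, `S5 = {c1}`, `S6 = {c6}`. The module
#' `{S1, S2, S3, S4}` behaves as a bridged complex of two sub-complexes
#' `{S1, S2, S3}` (shared `c4`) and `{S3, S4}` (shared `c6`), making the
#' contrast between the coherence measures visible at a glance.
#'
#' Construction asserts the resulting information contents:
#' `I(c4) = I(c6) = I(c2) = I(c3) = 1`, `I(c1) = log2(3)`, `I(r) = 0`.
#'
#' @return A list with elements `ontology` ([ontology_graph()]) and
#'   `corpus` ([annotation_corpus()]).
#' @examples
#' fx <- build_figure1()
#' sigma_w(fx$corpus, c("S1", "S2", "S3", "S4"))
#' @export
build_figure1 <- function() {
  ont <- ontology_graph(tibble::tibble(
    term   = c("c1", "c2", "c3", "c4", "c6"),
    parent = c("r", "r", "r", "c2", "c3")
  ))
  corpus <- annotation_corpus(ont, list(
    S1 = "c4",
    S2 = "c4",
    S3 = c("c4", "c6"),
    S4 = c("c1", "c6"),
    S5 = "c1",
    S6 = "c6"
  ))
  ic <- vapply(c("c1", "c2", "c3", "c4", "c6", "r"),
               function(t) info_content(corpus, t), numeric(1))
  stopifnot(
    isTRUE(all.equal(unname(ic[c("c2", "c3", "c4", "c6")]), rep(1, 4))),
    isTRUE(all.equal(unname(ic["c1"]), log2(3))),
    ic["r"] == 0,
    length(corpus$molecules) == 6L
  )
  list(ontology = ont, corpus = corpus)
}

#' Generate a random rooted ontology DAG
#'
#' Terms are created in order; each non-root term draws between one and
#' `max_parents` parents uniformly among the earlier terms, which guarantees
#' acyclicity and a single root by construction. Deterministic for a fixed
#' seed.
#'
#' @param n_terms Total number of terms including the root (at least 2).
#' @param max_parents Maximum parents per term.
#' @param seed Optional integer seed.
#' @return An [ontology_graph()] object; the root is named `"r"`, other
#'   terms `"t002"`, `"t003"`, ...
#' @export
simulate_ontology <- function(n_terms, max_parents = 2L, seed = NULL) {
  check_scalar_number(n_terms, "n_terms", lower = 2)
  check_scalar_number(max_parents, "max_parents", lower = 1)
  with_seed(seed, {
    terms <- c("r", sprintf("t%03d", seq_len(n_terms - 1L) + 1L))
    rel <- purrr::map_dfr(seq_along(terms)[-1L], function(i) {
      k <- sample.int(min(max_parents, i - 1L), 1L)
      tibble::tibble(term = terms[i],
                     parent = sample(terms[seq_len(i - 1L)], k))
    })
    ontology_graph(rel)
  })
}

#' Generate a random annotation corpus
#'
#' Annotates each molecule with a leaf-biased random draw of terms (leaves
#' are three times as likely as internal terms, mimicking the
#' most-specific-annotation convention of curated corpora), reduced to a
#' non-redundant set. Deterministic for a fixed seed.
#'
#' @param ontology An [ontology_graph()] object.
#' @param n_molecules Number of molecules.
#' @param terms_per_molecule Terms drawn per molecule before non-redundancy
#'   reduction.
#' @param seed Optional integer seed.
#' @return An [annotation_corpus()]; molecules are named `"m0001"`, ...
#' @export
simulate_corpus <- function(ontology, n_molecules, terms_per_molecule = 2L,
                            seed = NULL) {
  stopifnot(inherits(ontology, "ontology_dag"))
  check_scalar_number(n_molecules, "n_molecules", lower = 1)
  check_scalar_number(terms_per_molecule, "terms_per_molecule", lower = 1)
  with_seed(seed, {
    pool <- setdiff(ontology$terms, ontology$root)
    is_leaf <- igraph::degree(ontology$graph, v = pool, mode = "in") == 0L
    w <- ifelse(is_leaf, 3, 1)
    ann <- lapply(seq_len(n_molecules), function(i) {
      k <- min(terms_per_molecule, length(pool))
      sample(pool, k, prob = w)
    })
    names(ann) <- sprintf("m%04d", seq_len(n_molecules))
    annotation_corpus(ontology, ann)
  })
}

# depth of each term: shortest directed distance to the root
term_depths <- function(ontology) {
  d <- igraph::distances(ontology$graph, to = ontology$root,
                         mode = "out")[, 1L]
  d[ontology$terms]
}

# terms suitable for planting a functional family: mid-depth (>= 2 edges
# from the root) with at least `min_family` molecules annotated at or below
planted_candidates <- function(corpus, min_family) {
  depth <- term_depths(corpus$ontology)
  fam <- vapply(corpus$ontology$terms,
                function(t) length(corpus$index[[t]] %||% character(0)),
                integer(1))
  corpus$ontology$terms[depth >= 2 & fam >= min_family]
}

#' Generate planted test modules and random control modules
#'
#' Emulates a known-complex benchmark: for each requested size, `n_per_size`
#' "test" modules whose members are drawn from planted functional families,
#' and `n_per_size` "control" modules drawn uniformly from the corpus.
#'
#' A functional family is the set of molecules annotated at or below a
#' mid-depth ontology term. Test modules larger than `subcomplex_size` are
#' partitioned into sub-blocks of roughly that size, each with its own
#' planted term — large complexes are assemblies of functionally specific
#' sub-complexes, so whole-module agreement dilutes with size while
#' sub-group-level sharing persists. Each member is drawn from its block's
#' family with probability `coherence_bias` and uniformly otherwise;
#' `coherence_bias = 0` makes test and control statistically
#' indistinguishable.
#'
#' @param corpus An [annotation_corpus()].
#' @param sizes Module sizes to generate.
#' @param n_per_size Number of test and of control modules per size.
#' @param coherence_bias Probability in \[0, 1\] that a test-module member
#'   comes from its block's planted family.
#' @param subcomplex_size Target sub-block size for test modules.
#' @param seed Optional integer seed.
#' @return A tibble with columns `module`, `molecule`, `group`
#'   (`"test"`/`"control"`) and `size`.
#' @export
simulate_test_control_modules <- function(corpus, sizes = 4:11,
                                          n_per_size = 25L,
                                          coherence_bias = 0.9,
                                          subcomplex_size = 4L,
                                          seed = NULL) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  check_scalar_number(coherence_bias, "coherence_bias", lower = 0, upper = 1)
  mols <- corpus$molecules
  if (max(sizes) > length(mols)) {
    abort("corpus too small for the largest requested module size.",
          class = "funcoh_error_argument")
  }
  cands <- planted_candidates(corpus, min_family = 2L)
  if (length(cands) < 2L) {
    abort("corpus has too few mid-depth terms with annotated families.",
          class = "funcoh_error_argument")
  }
  with_seed(seed, {
    rows <- list()
    for (k in sizes) {
      for (j in seq_len(n_per_size)) {
        # control: uniform draw
        rows[[length(rows) + 1L]] <- tibble::tibble(
          module = sprintf("ctrl_s%02d_%03d", k, j),
          molecule = sample(mols, k),
          group = "control", size = k
        )
        # test: planted sub-blocks
        n_blocks <- max(1L, round(k / subcomplex_size))
        block_of <- sort(rep_len(seq_len(n_blocks), k))
        terms <- sample(cands, n_blocks,
                        replace = length(cands) < n_blocks)
        chosen <- character(0)
        for (b in seq_len(n_blocks)) {
          fam <- setdiff(corpus$index[[terms[b]]], chosen)
          for (s in seq_len(sum(block_of == b))) {
            from_fam <- length(fam) > 0L &&
              stats::runif(1) < coherence_bias
            pick <- if (from_fam) {
              sample(fam, 1L)
            } else {
              sample(setdiff(mols, chosen), 1L)
            }
            chosen <- c(chosen, pick)
            fam <- setdiff(fam, pick)
          }
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          module = sprintf("test_s%02d_%03d", k, j),
          molecule = chosen, group = "test", size = k
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Generate a planted-partition interaction network over functional families
#'
#' Builds a synthetic network whose topological modules coincide with
#' functional families of the corpus: `n_blocks` disjoint blocks of
#' `block_size` molecules, each block drawn from the family of a distinct
#' mid-depth planted term; within-block edges appear with probability
#' `p_in`, between-block edges with probability `p_out < p_in`. With
#' `p_out = 0` the connected components are exactly the planted blocks.
#'
#' @param corpus An [annotation_corpus()].
#' @param n_blocks Number of planted blocks.
#' @param block_size Molecules per block.
#' @param p_in,p_out Within- and between-block edge probabilities
#'   (`p_in > p_out`).
#' @param seed Optional integer seed.
#' @return An [interaction_graph()] with a `blocks` attribute: a tibble
#'   with columns `node`, `block`, `planted_term`.
#' @export
simulate_modular_network <- function(corpus, n_blocks = 6L, block_size = 8L,
                                     p_in = 0.8, p_out = 0.05, seed = NULL) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  check_scalar_number(p_in, "p_in", lower = 0, upper = 1)
  check_scalar_number(p_out, "p_out", lower = 0, upper = 1)
  if (p_in <= p_out) {
    abort("`p_in` must exceed `p_out`.", class = "funcoh_error_argument")
  }
  with_seed(seed, {
    cands <- sample(planted_candidates(corpus, min_family = block_size))
    used <- character(0)
    blocks <- list()
    for (t in cands) {
      if (length(blocks) == n_blocks) break
      fam <- setdiff(corpus$index[[t]], used)
      if (length(fam) >= block_size) {
        members <- sample(fam, block_size)
        used <- c(used, members)
        blocks[[length(blocks) + 1L]] <- tibble::tibble(
          node = members, block = length(blocks) + 1L, planted_term = t)
      }
    }
    if (length(blocks) < n_blocks) {
      abort("corpus does not contain enough disjoint planted families.",
            class = "funcoh_error_argument")
    }
    membership <- dplyr::bind_rows(blocks)
    nodes <- membership$node
    blk <- membership$block
    n <- length(nodes)
    pairs <- utils::combn(n, 2L)
    p <- ifelse(blk[pairs[1L, ]] == blk[pairs[2L, ]], p_in, p_out)
    keep <- stats::runif(ncol(pairs)) < p
    edges <- tibble::tibble(from = nodes[pairs[1L, keep]],
                            to = nodes[pairs[2L, keep]])
    g <- interaction_graph(edges, nodes = nodes)
    attr(g, "blocks") <- membership
    g
  })
}
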