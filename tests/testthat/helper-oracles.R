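# Brute-force oracles, independent of the package's cached-closure and
# folding implementations. They work directly from a relations table
# (columns term, parent) and a raw molecule -> term-set annotation list.

`%||%` <- function(x, y) if (is.null(x)) y else x

# reflexive ancestor set by iterated parent expansion
bf_ancestors <- function(rel, term) {
  out <- term
  repeat {
    nxt <- unique(c(out, rel$parent[rel$term %in% out]))
    if (length(nxt) == length(out)) {
      return(sort(out))
    }
    out <- nxt
  }
}

# drop members that are strict ancestors of another member
bf_reduce <- function(rel, terms) {
  terms <- unique(terms)
  keep <- vapply(terms, function(t) {
    !any(vapply(setdiff(terms, t),
                function(u) t %in% bf_ancestors(rel, u), logical(1)))
  }, logical(1))
  sort(terms[keep])
}

# exhaustive minimum common ancestors of a tuple of terms
bf_mca <- function(rel, terms) {
  common <- Reduce(intersect, lapply(terms, bf_ancestors, rel = rel))
  bf_reduce(rel, common)
}

# set information content by direct molecule counting
bf_set_ic <- function(rel, ann, terms) {
  closure <- lapply(ann, function(ts) {
    unique(unlist(lapply(ts, bf_ancestors, rel = rel)))
  })
  supp <- sum(vapply(closure, function(cl) all(terms %in% cl), logical(1)))
  if (supp == 0L) Inf else -log2(supp / length(ann))
}

# minimum-common-ancestor set of two term sets via full pair enumeration
bf_lambda <- function(rel, set_i, set_j) {
  pool <- unique(unlist(
    lapply(set_i, function(a)
      lapply(set_j, function(b) bf_mca(rel, c(a, b))))))
  bf_reduce(rel, pool)
}

bf_rho_i <- function(rel, ann, set_i, set_j) {
  bf_set_ic(rel, ann, bf_lambda(rel, set_i, set_j))
}

# exhaustive tuple enumeration behind the generalized information content
bf_sigma_i <- function(rel, ann, sets) {
  grid <- expand.grid(sets, stringsAsFactors = FALSE)
  pool <- unique(unlist(
    lapply(seq_len(nrow(grid)),
           function(k) bf_mca(rel, as.character(unlist(grid[k, ]))))))
  bf_set_ic(rel, ann, bf_reduce(rel, pool))
}

# shared/unique classification of each member's ancestor DAG
bf_sigma_w <- function(rel, ann, mols) {
  dags <- lapply(ann[mols], function(ts) {
    unique(unlist(lapply(ts, bf_ancestors, rel = rel)))
  })
  all_terms <- unique(unlist(dags))
  n_t <- vapply(all_terms, function(t)
    sum(vapply(dags, function(d) t %in% d, logical(1))), numeric(1))
  ic <- vapply(all_terms, function(t) bf_set_ic(rel, ann, t), numeric(1))
  denom <- sum(n_t * ic)
  if (denom == 0) 1 else sum((n_t * ic)[n_t >= 2]) / denom
}

# closed-form random walk with restart via a linear solve, rows = sources
bf_rwr <- function(A, restart) {
  deg <- rowSums(A)
  W <- A / ifelse(deg > 0, deg, 1)
  for (i in which(deg == 0)) W[i, i] <- 1
  n <- nrow(A)
  P <- vapply(seq_len(n), function(i) {
    e <- numeric(n)
    e[i] <- restart
    solve(diag(n) - (1 - restart) * t(W), e)
  }, numeric(n))
  t(P)
}

# area under the binormal ROC curve by quadrature over thresholds
bf_binormal_auc <- function(mean_t, sd_t, mean_c, sd_c) {
  stats::integrate(function(x) {
    (1 - stats::pnorm((x - mean_t) / sd_t)) *
      stats::dnorm((x - mean_c) / sd_c) / sd_c
  }, lower = -Inf, upper = Inf)$value
}

# shared random fixture: small ontology + corpus, deterministic
random_fixture <- function(seed, n_terms = 25, n_molecules = 40,
                           terms_per_molecule = 2) {
  ont <- simulate_ontology(n_terms, max_parents = 2, seed = seed)
  corpus <- simulate_corpus(ont, n_molecules,
                            terms_per_molecule = terms_per_molecule,
                            seed = seed + 1000L)
  list(ontology = ont, corpus = corpus, relations = tidy(ont))
}
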