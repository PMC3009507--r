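two_node <- interaction_graph(tibble::tibble(from = "a", to = "b"))

test_that("interaction graphs merge duplicates and reject bad edges", {
  g <- interaction_graph(tibble::tibble(
    from = c("a", "b", "a"), to = c("b", "a", "c"),
    weight = c(1, 2, 1)))
  e <- tidy(g)
  expect_identical(nrow(e), 2L)
  expect_equal(e$weight[e$from == "a" & e$to == "b"], 3)
  expect_warning(interaction_graph(tibble::tibble(from = c("a", "a"),
                                                  to = c("a", "b"))),
                 "self-loop")
  expect_error(interaction_graph(tibble::tibble(from = "a", to = "b",
                                                weight = -1)),
               class = "funcoh_error_argument")
})

test_that("two-node walk matches the analytic fixed point", {
  for (cc in c(0.1, 0.3, 0.65, 0.9)) {
    pm <- rwr_proximity(two_node, restart = cc)
    expect_equal(pm$presym["a", "b"], (1 - cc) / (2 - cc), tolerance = 1e-9)
    expect_equal(pm$presym["a", "a"], 1 / (2 - cc), tolerance = 1e-9)
    expect_equal(pm$scores["a", "b"], (1 - cc) / (2 - cc), tolerance = 1e-9)
  }
  # restart = 1 never leaves the source
  pm1 <- rwr_proximity(two_node, restart = 1)
  expect_equal(unname(pm1$presym), diag(2))
  expect_error(rwr_proximity(two_node, restart = 0),
               class = "funcoh_error_argument")
  expect_error(rwr_proximity(two_node, restart = 0.3, max_iter = 1),
               class = "funcoh_error_convergence")
})

test_that("iterative walk matches the closed-form linear solve", {
  for (seed in c(1, 5)) {
    set.seed(seed)
    n <- sample(10:50, 1)
    g_ig <- igraph::sample_gnp(n, 0.15)
    edges <- igraph::as_data_frame(g_ig, what = "edges")
    if (nrow(edges) == 0) next
    g <- interaction_graph(tibble::tibble(
      from = paste0("n", edges$from), to = paste0("n", edges$to)),
      nodes = paste0("n", seq_len(n)))
    A <- igraph::as_adjacency_matrix(g$graph, attr = "weight",
                                     sparse = FALSE)[g$nodes, g$nodes]
    for (cc in c(0.3, 0.7)) {
      pm <- rwr_proximity(g, restart = cc, tolerance = 1e-12)
      expect_lt(max(abs(pm$presym - bf_rwr(A, cc))), 1e-8)
      # probability conservation per source
      expect_equal(unname(rowSums(pm$presym)), rep(1, n), tolerance = 1e-8)
      # symmetrization averages the two orientations
      expect_equal(pm$scores, (pm$presym + t(pm$presym)) / 2)
      expect_true(isSymmetric(pm$scores))
    }
  }
})

test_that("faster restarts shorten the walk's reach on a star graph", {
  star <- interaction_graph(tibble::tibble(
    from = "hub", to = paste0("leaf", 1:4)))
  leaf_prox <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(cc) {
    rwr_proximity(star, restart = cc)$presym["leaf1", "leaf2"]
  }, numeric(1))
  expect_true(all(diff(leaf_prox) < 0))
})

test_that("shortest-path matrix is breadth-first with an Inf sentinel", {
  path <- interaction_graph(tibble::tibble(
    from = c("a", "b"), to = c("b", "c")), nodes = c("a", "b", "c", "d"))
  pm <- shortest_path_matrix(path)
  expect_equal(pm$scores["a", "b"], 1)
  expect_equal(pm$scores["a", "c"], 2)
  expect_identical(pm$scores["a", "d"], Inf)
  pairs <- proximity_pairs(pm)
  expect_identical(pairs$proximity[pairs$from == "a" & pairs$to == "d"], Inf)
})

test_that("z-normalization centres and scales", {
  expect_equal(znormalize(c(1, 2, 3)),
               c(-1, 0, 1) * sqrt(3 / 2))
  expect_equal(znormalize(c(1, 2, 3), type = "sample"), c(-1, 0, 1))
  z <- znormalize(c(4, 8, 15, 16, 23, 42))
  expect_equal(znormalize(z), z)
  expect_error(znormalize(c(2, 2, 2)), class = "funcoh_error_argument")
})

test_that("equal-count binning balances bins and tracks monotone signals", {
  pairs <- tibble::tibble(
    from = letters[1:10], to = LETTERS[1:10],
    proximity = 1:10, similarity = (1:10)^2)
  b <- bin_similarity(pairs, n_bins = 5)
  expect_identical(b$n_pairs, rep(2L, 5))
  expect_true(all(diff(b$mean_z_similarity) > 0))
  expect_error(bin_similarity(pairs, n_bins = 11),
               class = "funcoh_error_argument")

  # independent proximity and similarity: bin means hover near zero
  set.seed(99)
  n <- 400
  rnd <- tibble::tibble(
    from = sprintf("x%03d", 1:n), to = sprintf("y%03d", 1:n),
    proximity = stats::runif(n), similarity = stats::rnorm(n))
  br <- bin_similarity(rnd, n_bins = 8)
  se <- 1 / sqrt(n / 8)
  expect_true(all(abs(br$mean_z_similarity) < 3 * se))
})

test_that("correlation aligns proximity and similarity over node pairs", {
  fx <- build_figure1()
  sim <- molecule_similarity(fx$corpus, measure = "rho_jc")
  nodes <- sort(fx$corpus$molecules)
  m <- matrix(0, 6, 6, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(sim))) {
    m[sim$mol_i[k], sim$mol_j[k]] <- sim$similarity[k]
    m[sim$mol_j[k], sim$mol_i[k]] <- sim$similarity[k]
  }
  pm <- structure(list(scores = m, kind = "rwr", nodes = nodes,
                       restart = 0.3, presym = NULL),
                  class = "proximity_matrix")
  expect_equal(proximity_similarity_correlation(pm, fx$corpus,
                                                measure = "rho_jc"), 1)
  neg <- pm
  neg$scores <- -m
  expect_equal(proximity_similarity_correlation(neg, fx$corpus,
                                                measure = "rho_jc"), -1)
})

test_that("restart sweep emits one correlation per restart value", {
  f <- random_fixture(2, n_terms = 40, n_molecules = 120,
                      terms_per_molecule = 2)
  net <- simulate_modular_network(f$corpus, n_blocks = 3, block_size = 5,
                                  p_in = 0.9, p_out = 0.05, seed = 3)
  sw <- restart_sweep(net, f$corpus, restarts = c(0.2, 0.5, 0.8))
  expect_identical(nrow(sw), 3L)
  expect_true(all(is.finite(sw$correlation)))
})
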