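test_that("worked-example fixture carries the stated information contents", {
  fx <- build_figure1()
  expect_identical(length(fx$corpus$molecules), 6L)
  ic <- term_info_content(fx$corpus)
  ics <- stats::setNames(ic$ic, ic$term)
  expect_equal(unname(ics[c("c2", "c3", "c4", "c6")]), rep(1, 4))
  expect_equal(unname(ics["c1"]), log2(3))
  expect_equal(unname(ics["r"]), 0)
  expect_setequal(molecule_terms(fx$corpus, "S4"), c("c1", "c6"))
})

test_that("random ontologies are rooted DAGs, reproducible by seed", {
  tiny <- simulate_ontology(2, max_parents = 1, seed = 5)
  expect_identical(sort(tiny$terms), c("r", "t002"))
  expect_identical(tiny$root, "r")
  for (seed in 1:10) {
    ont <- simulate_ontology(30, max_parents = 3, seed = seed)
    expect_true(igraph::is_dag(ont$graph))
    expect_true(all(vapply(ont$terms, function(t)
      "r" %in% ancestors(ont, t), logical(1))))
  }
  a <- simulate_ontology(25, seed = 42)
  b <- simulate_ontology(25, seed = 42)
  expect_identical(tidy(a), tidy(b))
})

test_that("random corpora are non-redundant and true-path consistent", {
  ont <- simulate_ontology(40, seed = 8)
  corpus <- simulate_corpus(ont, 60, terms_per_molecule = 3, seed = 9)
  for (m in corpus$molecules) {
    ts <- molecule_terms(corpus, m)
    expect_setequal(reduce_nonredundant(ont, ts), ts)
  }
  rel <- tidy(ont)
  ic <- term_info_content(corpus)
  ics <- stats::setNames(ic$ic, ic$term)
  expect_true(all(ics[rel$parent] <= ics[rel$term]))
  again <- simulate_corpus(ont, 60, terms_per_molecule = 3, seed = 9)
  expect_identical(again$annotations, corpus$annotations)
})

test_that("module generator honours counts and plants detectable coherence", {
  f <- random_fixture(11, n_terms = 60, n_molecules = 250)
  mods <- simulate_test_control_modules(f$corpus, sizes = c(4, 6),
                                        n_per_size = 10, seed = 2)
  counts <- dplyr::count(dplyr::distinct(mods, .data$module, .data$group,
                                         .data$size),
                         .data$group, .data$size)
  expect_identical(counts$n, rep(10L, 4))
  sizes <- dplyr::count(mods, .data$module)
  expect_setequal(sizes$n, c(4L, 6L))

  score_groups <- function(bias, seed) {
    m <- simulate_test_control_modules(f$corpus, sizes = 4,
                                       n_per_size = 200,
                                       coherence_bias = bias, seed = seed)
    members <- split(m$molecule, m$module)
    grp <- vapply(split(m$group, m$module), `[[`, character(1), 1L)
    s <- vapply(members, function(mol) sigma_w(f$corpus, mol), numeric(1))
    glance(detectability(s[grp == "test"], s[grp == "control"]))$d
  }
  # fully planted modules separate clearly; unplanted ones do not
  expect_gt(score_groups(bias = 1, seed = 21), 1)
  expect_lt(abs(score_groups(bias = 0, seed = 22)), 0.3)
})

test_that("planted-partition networks mirror their functional blocks", {
  f <- random_fixture(13, n_terms = 60, n_molecules = 300)
  net0 <- simulate_modular_network(f$corpus, n_blocks = 4, block_size = 6,
                                   p_in = 0.9, p_out = 0, seed = 5)
  blocks <- attr(net0, "blocks")
  comp <- igraph::components(net0$graph)$membership
  for (b in unique(blocks$block)) {
    nodes <- blocks$node[blocks$block == b]
    expect_identical(length(unique(comp[nodes])), 1L)
  }

  p_in <- 0.6
  net <- simulate_modular_network(f$corpus, n_blocks = 5, block_size = 8,
                                  p_in = p_in, p_out = 0.02, seed = 6)
  blocks <- attr(net, "blocks")
  e <- tidy(net)
  blk <- stats::setNames(blocks$block, blocks$node)
  within <- sum(blk[e$from] == blk[e$to])
  n_within_pairs <- 5 * choose(8, 2)
  se <- sqrt(n_within_pairs * p_in * (1 - p_in))
  expect_lt(abs(within - p_in * n_within_pairs), 3 * se)

  again <- simulate_modular_network(f$corpus, n_blocks = 5, block_size = 8,
                                    p_in = p_in, p_out = 0.02, seed = 6)
  expect_identical(tidy(again), e)
  expect_error(simulate_modular_network(f$corpus, p_in = 0.1, p_out = 0.2),
               class = "funcoh_error_argument")
})
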