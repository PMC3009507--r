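fx <- build_figure1()
corpus <- fx$corpus
R1 <- c("S1", "S2", "S3", "S4")
R2 <- c("S1", "S2", "S3")

test_that("coherence measures reproduce the worked example", {
  expect_equal(sigma_a(corpus, R1), 3 / 8)
  expect_equal(sigma_a(corpus, R2), 2 / 3)
  expect_equal(sigma_a(corpus, c("S1", "S2")), 1)
  expect_equal(sigma_i(corpus, R1), 0)
  expect_equal(sigma_i(corpus, R2), 1)
  expect_equal(sigma_i(corpus, "S3"), log2(6))
  expect_equal(sigma_g(corpus, R1), 0)
  expect_equal(sigma_g(corpus, R2), 1 / 2)
  expect_equal(sigma_g(corpus, c("S1", "S2")), 1)
  expect_equal(sigma_w(corpus, R1), 10 / (10 + log2(3)))
  expect_equal(round(sigma_w(corpus, R1), 2), 0.86)
  expect_equal(sigma_w(corpus, R2), 3 / 4)
  expect_equal(sigma_w(corpus, c("S1", "S2")), 1)
  expect_error(sigma_a(corpus, "S1"), class = "funcoh_error_argument")
  expect_error(sigma_w(corpus, "S1"), class = "funcoh_error_argument")
})

test_that("generalized information content fold matches tuple brute force", {
  # worked-example modules first, then random ones up to four members
  expect_equal(sigma_i(corpus, R1),
               bf_sigma_i(tidy(fx$ontology), corpus$annotations,
                          corpus$annotations[R1]))
  for (seed in c(2, 6, 9)) {
    f <- random_fixture(seed, n_terms = 16, n_molecules = 20,
                        terms_per_molecule = 2)
    set.seed(seed)
    for (n in 2:4) {
      mols <- sample(f$corpus$molecules, n)
      expect_equal(sigma_i(f$corpus, mols),
                   bf_sigma_i(f$relations, f$corpus$annotations,
                              f$corpus$annotations[mols]),
                   info = sprintf("seed %d n %d", seed, n))
    }
  }
})

test_that("weighted information content matches shared/unique brute force", {
  expect_equal(sigma_w(corpus, R1),
               bf_sigma_w(tidy(fx$ontology), corpus$annotations, R1))
  for (seed in c(3, 8)) {
    f <- random_fixture(seed, n_terms = 18, n_molecules = 24)
    set.seed(seed)
    mols <- sample(f$corpus$molecules, 5)
    expect_equal(sigma_w(f$corpus, mols),
                 bf_sigma_w(f$relations, f$corpus$annotations, mols))
  }
})

test_that("coherence measures respect bounds, ordering and duplication", {
  for (seed in c(1, 4)) {
    f <- random_fixture(seed)
    set.seed(seed)
    mols <- sample(f$corpus$molecules, 4)
    sg <- sigma_g(f$corpus, mols)
    sw <- sigma_w(f$corpus, mols)
    expect_gte(sg, 0); expect_lte(sg, 1)
    expect_gte(sw, 0); expect_lte(sw, 1)
    expect_gte(sigma_i(f$corpus, mols), 0)
    # member ordering is irrelevant
    expect_equal(sigma_i(f$corpus, rev(mols)), sigma_i(f$corpus, mols))
    expect_equal(sigma_g(f$corpus, rev(mols)), sg)
    expect_equal(sigma_a(f$corpus, rev(mols)), sigma_a(f$corpus, mols))
    # joint information bounded by every member's self-information
    selfs <- vapply(mols, function(m) {
      s <- molecule_terms(f$corpus, m)
      pair_similarity(f$corpus, s, s, "rho_i")
    }, numeric(1))
    expect_lte(sigma_i(f$corpus, mols), min(selfs))
    # duplicating a member never decreases sigma_g or sigma_w
    dup <- c(mols, mols[1])
    expect_gte(sigma_g(f$corpus, dup), sg - 1e-12)
    expect_gte(sigma_w(f$corpus, dup), sw - 1e-12)
  }
})

test_that("size adjustment centres scores against an exhaustive background", {
  subsets <- utils::combn(corpus$molecules, 3)
  exhaustive_mean <- mean(vapply(seq_len(ncol(subsets)), function(k) {
    sigma_w(corpus, subsets[, k])
  }, numeric(1)))
  raw <- sigma_w(corpus, R2)
  adj <- size_adjust(corpus, raw, 3, sigma_w, n_random = 3000, seed = 1)
  expect_equal(adj, raw - exhaustive_mean, tolerance = 0.02)
  expect_gt(adj, 0)  # a coherent module beats the random background
  expect_identical(adj,
                   size_adjust(corpus, raw, 3, sigma_w,
                               n_random = 3000, seed = 1))
  expect_error(size_adjust(corpus, raw, 99, sigma_w, seed = 1),
               class = "funcoh_error_argument")
  expect_error(size_adjust(corpus, raw, 3, sigma_w, n_random = 10, seed = 1),
               class = "funcoh_error_argument")
})

test_that("module score tables match direct measure calls", {
  mods <- tibble::tibble(
    module = rep(c("R1", "R2"), c(4, 3)),
    molecule = c(R1, R2)
  )
  tab <- score_modules(mods, corpus)
  expect_identical(tab$module, c("R1", "R2"))
  expect_identical(tab$size, c(4L, 3L))
  expect_equal(tab$sigma_w, c(sigma_w(corpus, R1), sigma_w(corpus, R2)))
  expect_equal(tab$sigma_a, c(3 / 8, 2 / 3))

  adj1 <- score_modules(mods, corpus, adjust = TRUE, n_random = 50, seed = 7)
  adj2 <- score_modules(mods, corpus, adjust = TRUE, n_random = 50, seed = 7)
  expect_identical(adj1, adj2)
  expect_true(all(c("sigma_w_adj", "sigma_g_adj") %in% names(adj1)))
  expect_error(score_modules(mods[0, ], corpus),
               class = "funcoh_error_argument")
})

test_that("detectability is the binormal separation of two score sets", {
  x <- c(0.2, 0.5, 0.9, 0.4)
  expect_equal(glance(detectability(x, x))$d, 0)
  rep <- detectability(c(2, 4), c(0, 2))
  expect_equal(glance(rep)$d, 1)  # means 3 vs 1, sample variances 2 + 2
  expect_equal(glance(rep)$threshold, stats::qnorm(0.95))
  # zero pooled variance: equal means give 0, unequal a signed infinity
  expect_equal(glance(detectability(c(1, 1), c(1, 1)))$d, 0)
  expect_identical(glance(detectability(c(2, 2), c(1, 1)))$d, Inf)
  expect_error(detectability(1, c(1, 2)), class = "funcoh_error_argument")

  # the reported AUC equals the quadrature integral of the binormal ROC
  set.seed(42)
  t_scores <- stats::rnorm(40, 1.2, 0.8)
  c_scores <- stats::rnorm(55, 0.3, 1.1)
  g <- glance(detectability(t_scores, c_scores))
  expect_equal(g$auc,
               bf_binormal_auc(g$mean_test, sqrt(g$var_test),
                               g$mean_control, sqrt(g$var_control)),
               tolerance = 1e-6)
})
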