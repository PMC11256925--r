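test_that("exhaustive search solves hand-checkable instances", {
  # one gene, two cells, one sample: keep the positive cell only
  m <- matrix(c(2, -1), nrow = 1)
  sm <- sample_map(c("a", "a"))
  bc <- exhaustive_search(m, sm, sccross_params(kappa = 1, mu = 0))
  expect_equal(bc$cells, 1L)
  expect_equal(bc$genes, 1L)
  expect_equal(bc$objective, 2)

  # nothing positive: empty bicluster
  bc0 <- exhaustive_search(matrix(-1, 2, 3), sample_map(rep("a", 3)),
                           sccross_params(kappa = 1))
  expect_length(bc0$cells, 0)
  expect_equal(bc0$objective, 0)

  expect_error(exhaustive_search(matrix(1, 1, 20), sample_map(rep("a", 20)),
                                 tiny_params()), "beam_search")
})

test_that("exhaustive search agrees with full brute-force enumeration", {
  for (s in 1:3) {
    inst <- rand_instance(s, n_genes = 3, n_cells = 6)
    p <- tiny_params()
    got <- exhaustive_search(inst$m, inst$sm, p)
    want <- oracle_best_bicluster(inst$m, inst$sm, p)
    expect_equal(got$objective, want$objective, tolerance = 1e-9)
  }
})

test_that("beam search is bounded by the exhaustive optimum", {
  p <- tiny_params()
  attained <- 0
  for (s in 1:10) {
    inst <- rand_instance(s)
    ex <- exhaustive_search(inst$m, inst$sm, p)
    bm <- beam_search(inst$m, inst$sm, p)
    expect_lte(bm$objective, ex$objective + 1e-9)
    if (abs(bm$objective - ex$objective) < 1e-9) attained <- attained + 1
  }
  expect_gte(attained, 8)
})

test_that("beam search is deterministic", {
  sim <- generate_mixture(n_cells = 300, n_rare = 10, n_genes = 400,
                          n_marker_genes = 25, seed = 8)
  m <- filter_genes(log_transform(cpm_normalize(sim$counts)))
  a <- beam_search(m, sim$sample_map)
  b <- beam_search(m, sim$sample_map)
  expect_identical(a$bicluster$cells, b$bicluster$cells)
  expect_identical(a$bicluster$genes, b$bicluster$genes)
  expect_identical(a$trace, b$trace)
  expect_identical(a$n_evaluations, b$n_evaluations)
})

test_that("evaluation effort grows linearly with the number of cells", {
  evals <- vapply(c(250L, 500L), function(n) {
    sim <- generate_mixture(n_cells = n, n_rare = 12, n_genes = 400,
                            n_marker_genes = 30, seed = 21)
    m <- filter_genes(log_transform(cpm_normalize(sim$counts)))
    fit <- beam_search(m, sim$sample_map)
    # analytic per-step bound: active states x candidate pool
    n_states <- length(fit$seed_cells) * 2  # lineage width 2
    expect_lte(fit$n_evaluations,
               (length(fit$trace) + 1) * n_states * n)
    fit$n_evaluations / length(fit$trace)
  }, numeric(1))
  # doubling the cells at fixed width at most ~doubles per-step effort
  expect_lte(evals[2] / evals[1], 2.6)
})

test_that("excluded cells still incur the out-of-cluster penalty", {
  m <- matrix(-1, 2, 8)
  m[1, 1:3] <- 2           # pattern over cells 1-3
  sm <- sample_map(rep(c("s1", "s2"), each = 4))
  p <- sccross_params(kappa = 1, mu = 0)

  run <- beam_search(m, sm, p, excluded = 3L)
  expect_false(3L %in% run$bicluster$cells)
  # the selection over {1,2} is penalized for cell 3's expression ...
  with_pen <- select_genes(m, 1:2, sm, p)
  # ... compared to the same data with cell 3 truly absent
  without <- select_genes(m[, -3, drop = FALSE],
                          1:2, sample_map(rep(c("s1", "s2"), c(3, 4))), p)
  expect_lt(with_pen$objective, without$objective)
  expect_equal(run$bicluster$objective, with_pen$objective)
})

test_that("successive runs exclude cells and return disjoint clusters", {
  sim <- generate_mixture(n_cells = 500, n_rare = 12, n_genes = 600,
                          n_marker_genes = 40, marker_rate = 6, seed = 31)
  fit <- sccross(sim$counts, sim$sample_map, normalize = "cpm", runs = 2)
  expect_gte(length(fit$runs), 1)
  # first run identical to a single beam search on the same matrix
  single <- beam_search(fit$m, fit$sample_map, fit$params)
  expect_identical(fit$biclusters[[1]]$cells, single$bicluster$cells)
  expect_equal(fit$biclusters[[1]]$objective, single$objective)
  if (length(fit$runs) == 2) {
    expect_length(intersect(fit$biclusters[[1]]$cells,
                            fit$biclusters[[2]]$cells), 0)
    # the only planted pattern is consumed by run 1
    expect_lt(fit$biclusters[[2]]$objective, fit$biclusters[[1]]$objective)
  }
})

test_that("gene exclusion mode removes earlier genes instead of cells", {
  sim <- generate_mixture(n_cells = 300, n_rare = 10, n_genes = 400,
                          n_marker_genes = 25, seed = 13)
  fit <- sccross(sim$counts, sim$sample_map, normalize = "cpm", runs = 2,
                 exclude = "genes")
  if (length(fit$runs) == 2) {
    expect_length(intersect(fit$biclusters[[1]]$genes,
                            fit$biclusters[[2]]$genes), 0)
  }
  expect_true(length(fit$runs) >= 1)
})
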