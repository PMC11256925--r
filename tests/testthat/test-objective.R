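test_that("per-sample specificity matches direct evaluation", {
  m <- matrix(c(2, 1.5, 0.5, -1), nrow = 1)
  expect_equal(omega_score(m, 1, 1:4, 1:2, kappa = 0.1), 3.45)

  # J disjoint from the sample, no positive out-of-cluster expression
  m2 <- matrix(c(-1, -0.5, 3), nrow = 1)
  expect_equal(omega_score(m2, 1, 1:2, J = 3, kappa = 5), 0)

  # symmetric cancellation
  m3 <- matrix(c(1, 1), nrow = 1)
  expect_equal(omega_score(m3, 1, 1:2, J = 1, kappa = 1), 0)

  # random cases against the loop oracle
  for (s in 1:10) {
    inst <- rand_instance(s)
    J <- sort(sample(10, 4))
    g <- sample(8, 1)
    cs <- inst$sm$cells_of[[1]]
    expect_equal(omega_score(inst$m, g, cs, J, 0.3),
                 oracle_omega(inst$m, g, cs, J, 0.3))
  }
})

test_that("consistency weight is the clipped geometric/arithmetic ratio", {
  expect_equal(delta_consistency(c(3, 3, 3)), 1)
  expect_equal(delta_consistency(c(4, 0.1)), sqrt(0.4) / 2.05)
  # negative values are clipped at epsilon before both means
  expect_equal(delta_consistency(c(-2, 5)), sqrt(0.5) / 2.55)
  expect_error(delta_consistency(numeric(0)), "per sample")

  # AM-GM: always in (0, 1], equality iff all clipped values are equal
  set.seed(42)
  for (i in 1:200) {
    om <- runif(sample(2:6, 1), -2, 6)
    d <- delta_consistency(om, 0.1)
    expect_gt(d, 0)
    expect_lte(d, 1)
    cl <- pmax(om, 0.1)
    if (diff(range(cl)) < 1e-12) expect_equal(d, 1)
    if (abs(d - 1) < 1e-12) expect_lt(diff(range(cl)), 1e-9)
  }
  # all values below the clip are equal after clipping
  expect_equal(delta_consistency(c(-5, -1, 0), 0.1), 1)
})

test_that("gene contribution combines the weight and the unclipped sum", {
  # one gene expressed only in the first of three samples
  m <- matrix(c(10, 0, -1, 0, -1, 0), nrow = 1)
  sm <- sample_map(rep(c("a", "b", "c"), each = 2))
  gc <- gene_contribution(m, 1, J = c(1, 3, 5), sm, sccross_params(kappa = 1))
  expect_equal(unname(gc$omega_per_sample), c(10, -1, -1))
  d <- (0.1 * 0.1 * 10)^(1 / 3) / (10.2 / 3)
  expect_equal(gc$delta, d)
  expect_equal(gc$contribution, d * 8)

  # single sample: weight identically 1, contribution = whole-data omega
  sm1 <- sample_map(rep("x", 6))
  gc1 <- gene_contribution(m, 1, J = c(1, 3, 5), sm1, sccross_params(kappa = 1))
  expect_equal(gc1$delta, 1)
  expect_equal(gc1$contribution, omega_score(m, 1, 1:6, c(1, 3, 5), 1))
})

test_that("gene statistics satisfy their structural invariants", {
  inst <- rand_instance(3)
  J <- c(1, 2, 6, 7)
  st <- gene_stats(inst$m, J, inst$sm, tiny_params())
  om <- as.matrix(st[, c("omega.s1", "omega.s2")])
  expect_equal(st$contribution, st$delta * rowSums(om))
  expect_true(all(st$delta > 0 & st$delta <= 1))
  expect_true(all(st$neg_count <= length(J)))
  # contribution is positive iff the unclipped score-sum is positive
  expect_equal(st$contribution > 0, rowSums(om) > 0)
})

test_that("negative fraction counts strictly negative entries", {
  m <- matrix(c(1, 1, 1, -1, 1, 1), nrow = 2)
  expect_equal(negative_fraction(m, 1:2, 1:3), 1 / 6)
  expect_equal(negative_fraction(abs(m), 1:2, 1:3), 0)
  expect_equal(negative_fraction(-abs(m), 1:2, 1:3), 1)
  expect_error(negative_fraction(m, integer(0), 1:3), "non-empty")
})

test_that("fewer genes stay profitable as kappa grows", {
  inst <- rand_instance(11, n_genes = 12, n_cells = 12)
  J <- c(1, 2, 7, 8)
  counts <- vapply(c(0.05, 0.2, 0.5, 1, 2, 5), function(k) {
    st <- gene_stats(inst$m, J, inst$sm, sccross_params(kappa = k))
    sum(st$contribution > 0)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("objective values are invariant under relabeling", {
  inst <- rand_instance(5)
  p <- tiny_params()
  base <- select_genes(inst$m, c(1, 2, 6), inst$sm, p)

  # permute cells within each sample
  perm <- c(sample(1:5), sample(6:10))
  m2 <- inst$m[, perm]
  J2 <- match(c(1, 2, 6), perm)
  expect_equal(select_genes(m2, J2, inst$sm, p)$objective, base$objective)

  # reorder the samples (swap the two halves)
  m3 <- inst$m[, c(6:10, 1:5)]
  sm3 <- sample_map(rep(c("s2", "s1"), each = 5))
  J3 <- match(c(1, 2, 6), c(6:10, 1:5))
  expect_equal(select_genes(m3, J3, sm3, p)$objective, base$objective)
})

test_that("summing per-sample scores equals the single-sample score", {
  inst <- rand_instance(9)
  J <- c(2, 3, 8)
  for (g in 1:4) {
    per_sample <- sum(vapply(inst$sm$samples, function(s) {
      omega_score(inst$m, g, inst$sm$cells_of[[s]], J, 0.4)
    }, numeric(1)))
    expect_equal(per_sample, omega_score(inst$m, g, 1:10, J, 0.4))
  }
})
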