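test_that("generated mixtures have the declared shape and rare split", {
  sim <- generate_mixture(n_cells = 200, n_rare = 12, n_genes = 300,
                          n_marker_genes = 20, seed = 1)
  expect_equal(dim(sim$counts), c(300L, 200L))
  expect_length(sim$rare_cells, 12)
  expect_length(sim$marker_genes, 20)
  sizes <- vapply(sim$sample_map$cells_of, length, integer(1))
  expect_equal(unname(sizes), c(100L, 100L))
  # rare cells split evenly across the two samples
  in_s1 <- sum(sim$rare_cells %in% sim$sample_map$cells_of$s1)
  expect_equal(in_s1, 6L)

  # odd rare count: the extra cell goes to sample 1
  sim7 <- generate_mixture(n_cells = 200, n_rare = 7, n_genes = 300,
                           n_marker_genes = 20, seed = 2)
  expect_equal(sum(sim7$rare_cells %in% sim7$sample_map$cells_of$s1), 4L)

  expect_error(generate_mixture(n_cells = 201), "even")
  expect_error(generate_mixture(n_marker_genes = 5000), "n_marker_genes")
  expect_error(generate_mixture(n_cells = 100, n_rare = 100), "n_rare")
})

test_that("marker genes separate rare cells from the background", {
  sim <- generate_mixture(n_cells = 400, n_rare = 16, n_genes = 500,
                          n_marker_genes = 30, seed = 5)
  mk <- sim$counts[sim$marker_genes, , drop = FALSE]
  rare_mean <- mean(mk[, sim$rare_cells])
  bg_mean <- mean(mk[, -sim$rare_cells])
  expect_gt(rare_mean, 5 * (bg_mean + 0.01))
})

test_that("a zero marker rate leaves rare and background exchangeable", {
  sim <- generate_mixture(n_cells = 400, n_rare = 16, n_genes = 500,
                          n_marker_genes = 30, marker_rate = 0, seed = 6)
  load <- colSums(sim$counts[sim$marker_genes, , drop = FALSE])
  p <- stats::t.test(load[sim$rare_cells], load[-sim$rare_cells])$p.value
  expect_gt(p, 0.05)
})

test_that("batch scenarios perturb only the second sample as specified", {
  sim <- generate_mixture(n_cells = 200, n_rare = 8, n_genes = 2000,
                          n_marker_genes = 20, seed = 3)
  cn <- cpm_normalize(sim$counts)
  s1 <- sim$sample_map$cells_of$s1
  s2 <- sim$sample_map$cells_of$s2

  expect_identical(apply_batch_effect(cn, sim$sample_map, "none"), cn)

  for (sc in c("global", "gene_specific", "value_specific")) {
    out <- apply_batch_effect(cn, sim$sample_map, sc, seed = 9)
    expect_identical(out[, s1], cn[, s1])          # sample 1 untouched
    out2 <- apply_batch_effect(cn, sim$sample_map, sc, seed = 9)
    expect_identical(out, out2)                     # deterministic
  }

  # global: one Gaussian factor per gene, mean 0.5, sd 0.02
  g <- apply_batch_effect(cn, sim$sample_map, "global", seed = 4)
  ratio <- g[, s2] / cn[, s2]
  fac <- vapply(seq_len(nrow(cn)), function(i) {
    r <- ratio[i, is.finite(ratio[i, ])]
    if (length(r)) r[1] else NA_real_
  }, numeric(1))
  per_gene_spread <- vapply(seq_len(nrow(cn)), function(i) {
    r <- ratio[i, is.finite(ratio[i, ])]
    if (length(r) > 1) diff(range(r)) else 0
  }, numeric(1))
  expect_lt(max(per_gene_spread), 1e-8)             # constant within gene
  fac <- fac[is.finite(fac)]
  expect_lt(abs(mean(fac) - 0.5), 3 * 0.02 / sqrt(length(fac)))

  # gene-specific: constant per gene, inside [0.2, 1.8]
  gs <- apply_batch_effect(cn, sim$sample_map, "gene_specific", seed = 4)
  rgs <- gs[, s2] / cn[, s2]
  rgs_ok <- rgs[is.finite(rgs)]
  expect_true(all(rgs_ok >= 0.2 - 1e-12 & rgs_ok <= 1.8 + 1e-12))

  # value-specific: every entry scaled independently inside [0.5, 1.5]
  vs <- apply_batch_effect(cn, sim$sample_map, "value_specific", seed = 4)
  rvs <- vs[, s2] / cn[, s2]
  rvs_ok <- rvs[is.finite(rvs)]
  expect_true(all(rvs_ok >= 0.5 - 1e-12 & rvs_ok <= 1.5 + 1e-12))

  expect_error(apply_batch_effect(cn, sim$sample_map, "spurious"))
})

test_that("f1 combines precision and recall as their harmonic mean", {
  expect_equal(f1_score(1:10, 1:10), list(precision = 1, recall = 1, f1 = 1))
  expect_equal(f1_score(1:5, 1:10)$f1, 2 / 3)
  expect_equal(f1_score(11:20, 1:10), list(precision = 0, recall = 0, f1 = 0))
  expect_equal(f1_score(integer(0), 1:10)$f1, 0)
  expect_error(f1_score(1:3, integer(0)), "non-empty")
})

test_that("recovery is perfect in the separable regime and fades with it", {
  f_strong <- vapply(1:3, function(s) small_run_f1(s), numeric(1))
  expect_equal(mean(f_strong), 1.0)

  f_mid <- vapply(1:3, function(s) small_run_f1(s, marker_rate = 1.2),
                  numeric(1))
  f_weak <- vapply(1:3, function(s) small_run_f1(s, marker_rate = 0.3),
                   numeric(1))
  expect_gte(mean(f_strong), mean(f_mid))
  expect_gte(mean(f_mid), mean(f_weak))
})

test_that("the benchmark table is complete and reproducible", {
  a <- run_benchmark(n_rare = 12L, scenarios = c("none", "global"),
                     n_reps = 2L, n_cells = 500L, n_genes = 600L,
                     n_marker_genes = 40L, marker_rate = 6, seed = 77)
  expect_equal(nrow(a$runs), 4L)
  expect_equal(nrow(a$summary), 2L)
  expect_true(all(a$runs$f1 >= 0 & a$runs$f1 <= 1))
  expect_true(all(a$runs$precision >= 0 & a$runs$precision <= 1))
  expect_equal(nrow(a$spread), 1L)

  b <- run_benchmark(n_rare = 12L, scenarios = c("none", "global"),
                     n_reps = 2L, n_cells = 500L, n_genes = 600L,
                     n_marker_genes = 40L, marker_rate = 6, seed = 77)
  expect_identical(a$runs, b$runs)
  expect_identical(a$summary, b$summary)
})
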