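# Shared fixtures and independent (naive, loop-based) oracles. The oracles
# deliberately re-derive every quantity from the definitions, without using
# the package's vectorized implementations, so they can serve as a second
# route in equivalence tests.

tiny_params <- function() sccross_params(kappa = 0.5, mu = 0.1)

# Random small instance: sparse positive values on a -1 background,
# two equal samples.
rand_instance <- function(seed, n_genes = 8, n_cells = 10, p_pos = 0.35) {
  set.seed(seed)
  m <- matrix(ifelse(runif(n_genes * n_cells) < p_pos,
                     runif(n_genes * n_cells, 0.5, 2.5), -1),
              n_genes, n_cells)
  sm <- sample_map(rep(c("s1", "s2"), each = n_cells / 2))
  list(m = m, sm = sm)
}

oracle_omega <- function(m, gene, sample_cells, J, kappa) {
  tot <- 0
  for (j in sample_cells) {
    if (j %in% J) tot <- tot + m[gene, j]
    else if (m[gene, j] > 0) tot <- tot - kappa * m[gene, j]
  }
  tot
}

oracle_delta <- function(omegas, epsilon) {
  cl <- ifelse(omegas < epsilon, epsilon, omegas)
  prod(cl)^(1 / length(cl)) / mean(cl)
}

# Per-gene table (contribution, negative count) from the definitions.
oracle_gene_table <- function(m, J, smap, params) {
  t(vapply(seq_len(nrow(m)), function(g) {
    om <- vapply(smap$samples, function(s) {
      oracle_omega(m, g, smap$cells_of[[s]], J, params$kappa)
    }, numeric(1))
    delta <- if (length(om) == 1L) 1 else oracle_delta(om, params$epsilon)
    c(contribution = delta * sum(om), neg = sum(m[g, J] < 0))
  }, numeric(2)))
}

# Brute-force optimal gene subset (enumeration over all subsets of the
# positive-contribution genes) under the negative-fraction cap.
oracle_select <- function(m, J, smap, params) {
  st <- oracle_gene_table(m, J, smap, params)
  cand <- which(st[, "contribution"] > 0)
  best <- 0
  bestI <- integer(0)
  if (length(cand)) {
    bits <- 2^(seq_along(cand) - 1)
    for (mask in seq_len(2^length(cand) - 1)) {
      I <- cand[bitwAnd(mask, bits) != 0]
      if (sum(st[I, "neg"]) <=
            params$mu * length(I) * length(J) + 1e-9) {
        v <- sum(st[I, "contribution"])
        if (v > best + 1e-12) {
          best <- v
          bestI <- I
        }
      }
    }
  }
  list(objective = best, genes = sort(bestI))
}

# Brute-force optimal bicluster (enumeration over cell subsets too).
oracle_best_bicluster <- function(m, smap, params) {
  n <- ncol(m)
  bits <- 2^(seq_len(n) - 1)
  best <- 0
  bestJ <- integer(0)
  for (mask in seq_len(2^n - 1)) {
    J <- which(bitwAnd(mask, bits) != 0)
    v <- oracle_select(m, J, smap, params)$objective
    if (v > best + 1e-12) {
      best <- v
      bestJ <- J
    }
  }
  list(objective = best, cells = bestJ)
}

# Planted-block instance: a block confined to the third sample (higher
# plain-sum value) and a weaker block spread over all three samples.
make_planted_blocks <- function() {
  m <- matrix(-1, 8, 12)
  m[1:3, 9:12] <- 2
  m[4:6, c(2, 3, 6, 7, 10, 11)] <- 1.2
  list(m = m,
       sm3 = sample_map(rep(c("s1", "s2", "s3"), each = 4)),
       sm1 = sample_map(rep("all", 12)),
       confined = 9:12, confined_genes = 1:3,
       spread = c(2, 3, 6, 7, 10, 11), spread_genes = 4:6,
       params = sccross_params(kappa = 1, mu = 0.1))
}

# Benchmark-scale instance with two disjoint planted subpopulations.
make_two_pop <- function(seed = 42L) {
  sim <- generate_mixture(n_cells = 1000, n_rare = 20, n_genes = 1000,
                          n_marker_genes = 50, seed = seed)
  set.seed(seed + 100L)
  free_cells <- setdiff(seq_len(1000), sim$rare_cells)
  s1 <- intersect(free_cells, sim$sample_map$cells_of$s1)
  s2 <- intersect(free_cells, sim$sample_map$cells_of$s2)
  pop2 <- sort(c(sample(s1, 7), sample(s2, 7)))
  mk2 <- sort(sample(setdiff(seq_len(1000), sim$marker_genes), 35))
  counts <- sim$counts
  counts[mk2, pop2] <- counts[mk2, pop2] +
    matrix(rnbinom(length(mk2) * length(pop2), mu = 5, size = 2),
           length(mk2))
  list(counts = counts, smap = sim$sample_map,
       pop1 = sim$rare_cells, pop2 = pop2,
       markers1 = sim$marker_genes, markers2 = mk2)
}

# Standard small-scale pipeline: simulate, normalize, perturb, transform,
# filter, search; returns the F1 of the recovered cells.
small_run_f1 <- function(seed, scenario = "none", n_cells = 500,
                         n_genes = 600, n_rare = 12, n_marker_genes = 40,
                         marker_rate = 6) {
  sim <- generate_mixture(n_cells = n_cells, n_rare = n_rare,
                          n_genes = n_genes,
                          n_marker_genes = n_marker_genes,
                          marker_rate = marker_rate, seed = seed)
  cn <- cpm_normalize(sim$counts)
  cb <- apply_batch_effect(cn, sim$sample_map, scenario, seed = seed + 1L)
  m <- filter_genes(log_transform(cb))
  fit <- beam_search(m, sim$sample_map)
  f1_score(fit$bicluster$cells, sim$rare_cells)$f1
}
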