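#' Per-sample specificity score of a gene
#'
#' For one sample with cells `sample_cells` and a candidate cell set `J`, the
#' score sums the expression of the gene over the selected cells of the
#' sample and subtracts `kappa` times the positive expression of the gene in
#' the remaining cells of that sample:
#' `sum(m[gene, intersect(sample_cells, J)]) -
#'  kappa * sum(pmax(0, m[gene, setdiff(sample_cells, J)]))`.
#' A gene is specific to `J` within the sample when the selected cells
#' express it highly and the other cells of the sample barely express it.
#'
#' @param m log-scale expression matrix (genes x cells).
#' @param gene single row index.
#' @param sample_cells integer column indices of one sample.
#' @param J integer column indices of the candidate cell set.
#' @param kappa out-of-cluster penalty weight (> 0).
#' @return A single number; 0 when both the intersection and the
#'   out-of-cluster positive expression are empty.
#' @export
omega_score <- function(m, gene, sample_cells, J, kappa) {
  v <- m[gene, sample_cells]
  in_j <- sample_cells %in% J
  sum(v[in_j]) - kappa * sum(pmax(0, v[!in_j]))
}

#' Cross-sample consistency weight
#'
#' Ratio of the geometric to the arithmetic mean of the per-sample
#' specificity scores, each clipped from below at `epsilon` to stay in the
#' real domain. The ratio lies in `(0, 1]`; it equals 1 exactly when all
#' clipped scores are equal (the gene behaves identically across samples)
#' and drops towards 0 for genes whose score is concentrated in few samples.
#'
#' @param omegas numeric vector, one specificity score per sample.
#' @param epsilon positive clipping floor; default 0.1.
#' @return A single number in `(0, 1]`.
#' @examples
#' delta_consistency(c(3, 3, 3))          # 1
#' delta_consistency(c(4, 0.1))           # sqrt(0.4) / 2.05
#' @export
delta_consistency <- function(omegas, epsilon = 0.1) {
  if (length(omegas) == 0L) stop("'omegas' must contain one value per sample")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop("'epsilon' must be a single positive number")
  }
  cl <- pmax(epsilon, omegas)
  min(1, exp(mean(log(cl))) / mean(cl))
}

#' Per-gene statistics for a fixed cell set
#'
#' Computes, for every gene, the per-sample specificity scores, the
#' consistency weight, the objective contribution
#' `delta * sum(per-sample scores)` (the per-sample scores enter the sum
#' unclipped), and the number of negative entries within `J`.
#'
#' @param m log-scale expression matrix.
#' @param J non-empty integer vector of selected cell column indices.
#' @param smap a [sample_map()] covering the columns of `m`.
#' @param params a [sccross_params()] object (`kappa` must be numeric or
#'   `"auto"`, resolved against `ncol(m)`).
#' @return A data frame with one row per gene: `gene` (row index), `gene_id`,
#'   one `omega.<sample>` column per sample, `delta`, `contribution`,
#'   `neg_count`.
#' @export
gene_stats <- function(m, J, smap, params = sccross_params()) {
  check_sample_map(smap, ncol(m))
  J <- check_cell_set(J, ncol(m), "J")
  params <- resolve_params(params, ncol(m))
  om <- omega_matrix(m, J, smap, params$kappa)
  cl <- pmax(om, params$epsilon)
  delta <- if (ncol(om) == 1L) rep(1, nrow(om)) else
    pmin(1, exp(rowMeans(log(cl))) / rowMeans(cl))
  contribution <- delta * rowSums(om)
  neg_count <- rowSums(m[, J, drop = FALSE] < 0)
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  out <- data.frame(gene = seq_len(nrow(m)), gene_id = ids,
                    stringsAsFactors = FALSE)
  omd <- as.data.frame(om)
  names(omd) <- paste0("omega.", smap$samples)
  out <- cbind(out, omd)
  out$delta <- delta
  out$contribution <- contribution
  out$neg_count <- as.integer(neg_count)
  rownames(out) <- NULL
  out
}

#' Statistics for a single gene
#'
#' Convenience wrapper around [gene_stats()] for one gene; returns the
#' per-sample scores, the consistency weight, the contribution and the
#' negative count as a list.
#'
#' @inheritParams gene_stats
#' @param gene single row index.
#' @return A list with `gene`, `omega_per_sample` (named numeric), `delta`,
#'   `contribution` and `neg_count`.
#' @export
gene_contribution <- function(m, gene, J, smap, params = sccross_params()) {
  check_sample_map(smap, ncol(m))
  J <- check_cell_set(J, ncol(m), "J")
  params <- resolve_params(params, ncol(m))
  omegas <- vapply(smap$samples, function(s) {
    omega_score(m, gene, smap$cells_of[[s]], J, params$kappa)
  }, numeric(1))
  delta <- if (length(omegas) == 1L) 1 else
    delta_consistency(omegas, params$epsilon)
  list(gene = gene,
       omega_per_sample = omegas,
       delta = delta,
       contribution = delta * sum(omegas),
       neg_count = sum(m[gene, J] < 0))
}

#' Fraction of negative entries in a submatrix
#'
#' The left-hand side of the negative-entries constraint: the proportion of
#' strictly negative entries in the `I` x `J` submatrix. Selected genes must
#' be expressed often enough across the selected cells, so this fraction is
#' capped at `mu` in all returned biclusters.
#'
#' @param m log-scale expression matrix.
#' @param I non-empty integer vector of gene row indices.
#' @param J non-empty integer vector of cell column indices.
#' @return A number in `[0, 1]`.
#' @export
negative_fraction <- function(m, I, J) {
  if (length(I) == 0L) stop("'I' must be non-empty")
  J <- check_cell_set(J, ncol(m), "J")
  I <- check_cell_set(I, nrow(m), "I")
  mean(m[I, J, drop = FALSE] < 0)
}

#' Optimal gene set for a fixed cell set
#'
#' Among genes with strictly positive contribution, selects the subset `I`
#' maximizing the summed contributions subject to the cap `mu` on the
#' fraction of negative entries in the `I` x `J` submatrix. Writing
#' `t = mu * |J|`, every candidate gene has weight `neg_count - t`: genes
#' with non-positive weight only add slack and are always included; the
#' remaining knapsack over positive-weight genes is solved exactly by
#' dynamic programming when there are at most `exact_limit` of them, and by
#' a greedy pass in decreasing contribution order otherwise.
#'
#' @inheritParams gene_stats
#' @param exact_limit maximum number of positive-weight candidate genes for
#'   which the exact dynamic program is used; above it, the greedy fallback.
#'   Default 25.
#' @return An object of class `sccross_bicluster` (possibly with an empty
#'   gene set and objective 0 when no gene has positive contribution).
#' @export
select_genes <- function(m, J, smap, params = sccross_params(),
                         exact_limit = 25L) {
  check_sample_map(smap, ncol(m))
  J <- check_cell_set(J, ncol(m), "J")
  params <- resolve_params(params, ncol(m))
  st <- gene_stats(m, J, smap, params)
  pick <- select_from_stats(st$contribution, st$neg_count, params$mu,
                            length(J), exact_limit)
  build_bicluster(m, pick, J, st, smap, params)
}

#' Score a user-supplied bicluster
#'
#' Assembles the per-gene statistics, the objective value and the
#' negative-entry fraction for a given gene set and cell set, without any
#' optimization. The reported `constraint_ok` flag says whether the supplied
#' bicluster satisfies the negative-fraction cap.
#'
#' @inheritParams gene_stats
#' @param I non-empty integer vector of gene row indices (or gene ids
#'   matching `rownames(m)`).
#' @param J non-empty integer vector of cell column indices (or cell ids
#'   matching `colnames(m)`).
#' @return An object of class `sccross_bicluster`.
#' @export
evaluate_bicluster <- function(m, I, J, smap, params = sccross_params()) {
  check_sample_map(smap, ncol(m))
  I <- match_indices(I, rownames(m), nrow(m), "I")
  J <- match_indices(J, colnames(m), ncol(m), "J")
  params <- resolve_params(params, ncol(m))
  st <- gene_stats(m, J, smap, params)
  build_bicluster(m, sort(I), J, st, smap, params, check_constraint = FALSE)
}

# ---- internals --------------------------------------------------------------

# All omega scores at once: genes x samples matrix.
omega_matrix <- function(m, J, smap, kappa) {
  S <- length(smap$samples)
  om <- matrix(0, nrow(m), S)
  in_j <- logical(ncol(m))
  in_j[J] <- TRUE
  for (s in seq_len(S)) {
    cs <- smap$cells_of[[s]]
    ins <- cs[in_j[cs]]
    outs <- cs[!in_j[cs]]
    a <- if (length(ins)) rowSums(m[, ins, drop = FALSE]) else numeric(nrow(m))
    b <- if (length(outs)) rowSums(pmax(m[, outs, drop = FALSE], 0)) else
      numeric(nrow(m))
    om[, s] <- a - kappa * b
  }
  colnames(om) <- smap$samples
  om
}

# Choose the gene subset maximizing total contribution under the
# negative-fraction cap. Returns sorted integer indices.
select_from_stats <- function(contribution, neg_count, mu, j_size,
                              exact_limit = 25L) {
  t_allow <- mu * j_size
  cand <- which(contribution > 0)
  if (length(cand) == 0L) return(integer(0))
  free <- cand[neg_count[cand] <= t_allow]
  heavy <- cand[neg_count[cand] > t_allow]
  slack <- sum(t_allow - neg_count[free])
  if (length(heavy) == 0L) return(sort(free))
  chosen <- if (length(heavy) <= exact_limit) {
    knapsack_exact(contribution[heavy], neg_count[heavy], t_allow, slack)
  } else {
    knapsack_greedy(contribution[heavy], neg_count[heavy], t_allow, slack)
  }
  sort(c(free, heavy[chosen]))
}

# Greedy: heaviest contributions first, keep a gene if the accumulated
# slack still covers its excess negatives. Ties by lower index.
knapsack_greedy <- function(cont, negs, t_allow, slack, tol = 1e-9) {
  ord <- order(-cont, seq_along(cont))
  keep <- integer(0)
  for (i in ord) {
    w <- negs[i] - t_allow
    if (w <= slack + tol) {
      keep <- c(keep, i)
      slack <- slack - w
    }
  }
  sort(keep)
}

# Exact 0/1 selection over positive-weight genes. State: (#chosen, total
# negatives among chosen); a state is feasible iff
# total_neg - p * t_allow <= slack. Chosen sets tracked as bitmasks in
# doubles (exact for < 2^53, and the caller caps the item count).
knapsack_exact <- function(cont, negs, t_allow, slack, tol = 1e-9) {
  P <- length(cont)
  N <- sum(negs)
  val <- matrix(-Inf, P + 1L, N + 1L)
  set <- matrix(0, P + 1L, N + 1L)
  val[1L, 1L] <- 0
  for (i in seq_len(P)) {
    wi <- negs[i]
    for (p in rev(seq_len(i))) {
      src <- seq_len(N - wi + 1L)
      dst <- src + wi
      candv <- val[p, src] + cont[i]
      upd <- candv > val[p + 1L, dst] + tol
      if (any(upd)) {
        val[p + 1L, dst[upd]] <- candv[upd]
        set[p + 1L, dst[upd]] <- set[p, src[upd]] + 2^(i - 1)
      }
    }
  }
  best_v <- 0
  best_set <- 0
  for (p in seq_len(P)) {
    n_idx <- which(is.finite(val[p + 1L, ]))
    if (length(n_idx) == 0L) next
    feas <- n_idx[(n_idx - 1L) - p * t_allow <= slack + tol]
    if (length(feas) == 0L) next
    v <- val[p + 1L, feas]
    k <- which.max(v)
    if (v[k] > best_v + tol) {
      best_v <- v[k]
      best_set <- set[p + 1L, feas[k]]
    }
  }
  if (best_set == 0) return(integer(0))
  which(bitwAnd_double(best_set, 2^(seq_len(P) - 1)) > 0)
}

# Bitwise AND for set masks stored in doubles (P <= 52).
bitwAnd_double <- function(mask, bits) {
  vapply(bits, function(b) (mask %/% b) %% 2, numeric(1)) * bits
}

check_cell_set <- function(x, n, what) {
  x <- as.integer(x)
  if (length(x) == 0L) stop(sprintf("'%s' must be non-empty", what))
  if (anyNA(x) || any(x < 1L) || any(x > n)) {
    stop(sprintf("'%s' contains indices outside 1..%d", what, n))
  }
  if (anyDuplicated(x)) stop(sprintf("'%s' contains duplicated indices", what))
  sort(x)
}

match_indices <- function(x, ids, n, what) {
  if (is.character(x)) {
    if (is.null(ids)) stop(sprintf("'%s' given as ids but the matrix has none",
                                   what))
    idx <- match(x, ids)
    if (anyNA(idx)) {
      stop(sprintf("unknown %s id(s): %s", what,
                   paste(utils::head(x[is.na(idx)], 5L), collapse = ", ")))
    }
    x <- idx
  }
  check_cell_set(x, n, what)
}
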