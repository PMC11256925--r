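# Search over cell subsets: an exhaustive oracle for tiny instances and a
# deterministic beam search with sample-stratified seeding for real ones.

#' Exhaustive bicluster search (oracle for small instances)
#'
#' Enumerates every non-empty subset of the candidate cells, applies the
#' exact gene selection to each, and returns the best bicluster. The
#' optimization problem is NP-hard, so this is only feasible for a handful
#' of cells; it serves as the ground-truth oracle against which the beam
#' search is validated.
#'
#' @inheritParams gene_stats
#' @param max_cells refuse to enumerate more than this many candidate cells
#'   (default 15; the cost is `2^n` gene selections).
#' @param pool integer vector of candidate cell columns (default: all).
#' @return The optimal `sccross_bicluster` (empty, with objective 0, when no
#'   subset attains a positive objective). Ties are broken towards the
#'   lexicographically smallest sorted cell set.
#' @export
exhaustive_search <- function(m, smap, params = sccross_params(),
                              max_cells = 15L, pool = NULL) {
  check_sample_map(smap, ncol(m))
  params <- resolve_params(params, ncol(m))
  if (is.null(pool)) pool <- seq_len(ncol(m))
  pool <- check_cell_set(pool, ncol(m), "pool")
  n <- length(pool)
  if (n > max_cells) {
    stop(sprintf("%d candidate cells exceed max_cells = %d; use beam_search()",
                 n, max_cells))
  }
  bits <- 2^(seq_len(n) - 1)
  best_obj <- 0
  best_J <- NULL
  best_key <- NULL
  for (mask in seq_len(2^n - 1)) {
    J <- pool[bitwAnd(mask, bits) != 0]
    val <- objective_of(m, J, smap, params)$objective
    if (val > best_obj + 1e-9 ||
        (val > best_obj - 1e-9 && !is.null(best_key) &&
         cell_set_key(J) < best_key)) {
      best_obj <- val
      best_J <- J
      best_key <- cell_set_key(J)
    }
  }
  if (is.null(best_J) || best_obj <= 0) {
    return(empty_bicluster(m, smap, params))
  }
  select_genes(m, best_J, smap, params)
}

#' Beam search for the best bicluster
#'
#' Multi-start beam search with sample-stratified seeding. Every sample
#' contributes `beam_width` seed cells under each of two complementary
#' criteria: the cells with the highest one-cell objective (cells carrying
#' an already-specific expression pattern) and the cells with the highest
#' total positive expression over the sparse gene universe (cells of a rare
#' type express many genes that are rare in the dataset, even though their
#' one-cell objective is dragged down by the out-of-cluster penalty of
#' their still-unselected peers). Each seed then grows its own search
#' lineage: at every step the lineage is extended by the candidate cell —
#' from any sample — that most improves its score, so no seed can be
#' evicted by another seed's stronger early pattern. States are scored by
#' the greedy gene-selection objective; on the zero-objective plateau the
#' score falls back to the best single-gene contribution, which lets a
#' lineage climb towards profitability before any gene is selectable. A
#' lineage stops when no extension improves its score; the search stops
#' when all lineages have stopped. The best cell set ever encountered is
#' re-scored with the exact gene selection and returned. Fully
#' deterministic: ties are broken towards the higher score, then the
#' lexicographically smallest sorted cell set.
#'
#' @inheritParams exhaustive_search
#' @param beam_width number of seed lineages per sample and per seeding
#'   criterion (default 10).
#' @param lineage_width number of states each seed lineage keeps per step
#'   (a small per-seed beam; default 2). Width 1 is plain greedy growth;
#'   larger widths trade runtime for a better chance of escaping early
#'   missteps.
#' @param excluded integer vector of cell columns that may not enter the
#'   cell set but still count towards the out-of-cluster penalties (used by
#'   the iterative multi-bicluster protocol).
#' @param max_cluster_size optional cap on the number of selected cells.
#' @param exact_limit passed to the final [select_genes()] call.
#' @return An object of class `sccross_run`: a list with the `bicluster`,
#'   the per-step `trace` of best scores, and `n_evaluations` (number of
#'   candidate extensions scored).
#' @export
beam_search <- function(m, smap, params = sccross_params(), beam_width = 10L,
                        lineage_width = 2L, pool = NULL, excluded = NULL,
                        max_cluster_size = Inf, exact_limit = 25L) {
  check_sample_map(smap, ncol(m))
  params <- resolve_params(params, ncol(m))
  n <- ncol(m)
  G <- nrow(m)
  S <- length(smap$samples)
  beam_width <- as.integer(beam_width)
  if (beam_width < 1L) stop("'beam_width' must be >= 1")
  excluded <- if (length(excluded)) check_cell_set(excluded, n, "excluded")
              else integer(0)
  if (is.null(pool)) {
    pool <- setdiff(seq_len(n), excluded)
  } else {
    pool <- check_cell_set(pool, n, "pool")
    if (length(intersect(pool, excluded))) {
      stop("'pool' and 'excluded' must be disjoint")
    }
  }
  if (length(pool) == 0L) stop("empty candidate pool")

  storage.mode(m) <- "double"
  mpos <- pmax(m, 0)
  samp_idx <- match(smap$assignment, smap$samples)
  totpos <- vapply(smap$samples,
                   function(s) rowSums(mpos[, smap$cells_of[[s]],
                                            drop = FALSE]),
                   numeric(G))
  if (!is.matrix(totpos)) totpos <- matrix(totpos, nrow = G)

  omega_of <- function(st) st$inclsum - params$kappa * (totpos - st$inclpos)
  # per-gene upper bound, over the pool, of the score-sum change when a
  # candidate joins (used to skip genes that cannot become profitable)
  gain_max <- {
    gm <- m[, pool, drop = FALSE] + params$kappa * mpos[, pool, drop = FALSE]
    out <- gm[, 1L]
    for (k in seq_len(ncol(gm))[-1L]) out <- pmax(out, gm[, k])
    out
  }
  score_ext <- function(st, cand) {
    .score_extensions(m, mpos, omega_of(st), as.integer(st$neg),
                      as.integer(cand - 1L),
                      as.integer(samp_idx[cand] - 1L), gain_max,
                      length(st$J), params$kappa, params$mu, params$epsilon)
  }
  extend_state <- function(st, j) {
    s <- samp_idx[j]
    st$inclsum[, s] <- st$inclsum[, s] + m[, j]
    st$inclpos[, s] <- st$inclpos[, s] + mpos[, j]
    st$neg <- st$neg + as.integer(m[, j] < 0)
    st$J <- sort(c(st$J, j))
    st
  }
  root <- list(J = integer(0), inclsum = matrix(0, G, S),
               inclpos = matrix(0, G, S), neg = integer(G))

  n_eval <- 0L
  seed_scores <- score_ext(root, pool)
  n_eval <- n_eval + length(pool)
  load <- colSums(mpos)[pool]

  seed_cells <- integer(0)
  for (b in seq_len(S)) {
    in_b <- which(samp_idx[pool] == b)
    if (length(in_b) == 0L) next
    cand_b <- pool[in_b]
    by_score <- cand_b[utils::head(order(-seed_scores[in_b], cand_b),
                                   beam_width)]
    by_load <- cand_b[utils::head(order(-load[in_b], cand_b), beam_width)]
    seed_cells <- c(seed_cells, union(by_score, by_load))
  }
  seed_cells <- sort(unique(seed_cells))
  lineage_width <- max(1L, as.integer(lineage_width))
  # one lineage per seed: a list of up to lineage_width states plus the best
  # score seen by the lineage so far
  chains <- lapply(seed_cells, function(j) {
    st <- extend_state(root, j)
    list(states = list(st), best = seed_scores[match(j, pool)],
         active = TRUE)
  })
  inc_score <- 0
  inc_J <- integer(0)
  inc_key <- ""
  for (ch in chains) {
    if (ch$best > inc_score + 1e-9) {
      inc_score <- ch$best
      inc_J <- ch$states[[1L]]$J
      inc_key <- cell_set_key(inc_J)
    }
  }

  trace <- if (length(chains)) max(vapply(chains, `[[`, numeric(1), "best"))
           else 0
  # transposition table: lineages converging onto a cell set already held by
  # an earlier lineage would repeat its trajectory, so such states are dropped
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  for (j in seed_cells) assign(cell_set_key(j), TRUE, envir = seen)
  step <- 0L
  while (any(vapply(chains, `[[`, logical(1), "active")) &&
         step < length(pool)) {
    step <- step + 1L
    step_best <- -Inf
    for (ci in seq_along(chains)) {
      ch <- chains[[ci]]
      if (!ch$active) next
      # dominance pruning: a lineage strictly inside the incumbent cell set
      # with a lower score is re-climbing the incumbent's own path
      if (ch$best < inc_score - 1e-9 &&
          all(vapply(ch$states,
                     function(st) all(st$J %in% inc_J), logical(1)))) {
        chains[[ci]]$active <- FALSE
        next
      }
      p_score <- numeric(0)
      p_state <- integer(0)
      p_cand <- integer(0)
      for (si in seq_along(ch$states)) {
        st <- ch$states[[si]]
        if (length(st$J) >= max_cluster_size) next
        cand <- pool[!(pool %in% st$J)]
        if (length(cand) == 0L) next
        sc <- score_ext(st, cand)
        n_eval <- n_eval + length(cand)
        p_score <- c(p_score, sc)
        p_state <- c(p_state, rep(si, length(cand)))
        p_cand <- c(p_cand, cand)
      }
      if (length(p_score) == 0L || max(p_score) <= ch$best + 1e-9) {
        chains[[ci]]$active <- FALSE
        next
      }
      # lexicographic tie-breaking needs set keys, which are expensive to
      # format; compute them only for the contending top-score group
      k_target <- min(length(p_score), lineage_width)
      ord1 <- order(-p_score, p_state, p_cand)
      thr <- p_score[ord1[k_target]]
      tie <- which(p_score >= thr - 1e-9)
      cap <- 50L * lineage_width
      if (length(tie) > cap) {
        tie <- tie[order(-p_score[tie], p_state[tie],
                         p_cand[tie])][seq_len(cap)]
      }
      keys <- vapply(tie, function(i) {
        cell_set_key(c(ch$states[[p_state[i]]]$J, p_cand[i]))
      }, character(1))
      ord <- tie[order(-p_score[tie], keys)]
      keys <- keys[order(-p_score[tie], keys)]
      kept <- integer(0)
      kept_keys <- character(0)
      for (ii in seq_along(ord)) {
        i <- ord[ii]
        if (exists(keys[ii], envir = seen, inherits = FALSE)) next
        kept <- c(kept, i)
        kept_keys <- c(kept_keys, keys[ii])
        assign(keys[ii], TRUE, envir = seen)
        if (length(kept) >= lineage_width) break
      }
      if (length(kept) == 0L) {
        chains[[ci]]$active <- FALSE
        next
      }
      ch$states <- lapply(kept, function(i) {
        extend_state(ch$states[[p_state[i]]], p_cand[i])
      })
      ch$best <- p_score[kept[1L]]
      chains[[ci]] <- ch
      step_best <- max(step_best, ch$best)
      k1 <- kept[1L]
      if (p_score[k1] > inc_score + 1e-9 ||
          (p_score[k1] > inc_score - 1e-9 && nchar(inc_key) &&
           kept_keys[1L] < inc_key)) {
        inc_score <- p_score[k1]
        inc_J <- ch$states[[1L]]$J
        inc_key <- kept_keys[1L]
      }
    }
    trace <- c(trace, if (is.finite(step_best)) step_best else trace[step])
  }

  bc <- if (length(inc_J) && inc_score > 0) {
    select_genes(m, inc_J, smap, params, exact_limit)
  } else {
    empty_bicluster(m, smap, params)
  }
  structure(list(bicluster = bc, objective = bc$objective,
                 trace = trace, n_evaluations = n_eval,
                 seed_cells = sort(seed_cells), beam_width = beam_width,
                 excluded = excluded, params = params),
            class = "sccross_run")
}

#' @export
print.sccross_run <- function(x, ...) {
  cat(sprintf("Beam-search run (width %d, %d extensions scored)\n",
              x$beam_width, x$n_evaluations))
  print(x$bicluster)
  invisible(x)
}

# ---- internals --------------------------------------------------------------

# Objective (and selected gene set) of a fixed cell set, without the
# data-frame plumbing of select_genes(); used in tight enumeration loops.
objective_of <- function(m, J, smap, params, exact_limit = 25L) {
  om <- omega_matrix(m, J, smap, params$kappa)
  cl <- pmax(om, params$epsilon)
  delta <- if (ncol(om) == 1L) rep(1, nrow(om)) else
    pmin(1, exp(rowMeans(log(cl))) / rowMeans(cl))
  contribution <- delta * rowSums(om)
  neg <- rowSums(m[, J, drop = FALSE] < 0)
  I <- select_from_stats(contribution, neg, params$mu, length(J), exact_limit)
  list(I = I, objective = if (length(I)) sum(contribution[I]) else 0)
}

# Canonical sort key of a cell set: lexicographic on the sorted indices.
cell_set_key <- function(J) {
  paste(sprintf("%06d", sort(J)), collapse = "")
}
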