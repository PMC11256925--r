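# Controlled two-cell-type mixtures with planted rare cells, parametric
# batch-effect scenarios, and F1 scoring of the recovered cell set.

#' Simulate a two-type mixture with a planted rare subpopulation
#'
#' Emulates a controlled experiment in which a handful of cells of a second,
#' transcriptionally distinct cell type are spiked into an abundant
#' background population and the cells are split into two equally sized
#' samples, each holding half of the rare cells. Background counts are
#' per-gene negative binomial with long-tailed (log-normal) means, giving a
#' sparse gene universe. The marker genes of the rare type are near-silent
#' in the background type (`marker_bg_rate`), as lineage markers of a
#' distinct cell line are, and are expressed in the rare cells with
#' overdispersed counts of mean `marker_rate` on top of the background.
#'
#' @param n_cells total number of cells (even; default 1000).
#' @param n_rare number of planted rare cells (default 20; split as evenly
#'   as possible across the two samples, the extra cell to sample 1).
#' @param n_genes number of genes (default 2000).
#' @param n_marker_genes number of marker genes of the rare type (default 50).
#' @param marker_rate mean marker count in rare cells (default 5).
#' @param marker_bg_rate mean marker count in background cells (default 0.01).
#' @param bg_meanlog,bg_sdlog log-normal parameters of the per-gene
#'   background means (defaults -1.2 and 1.5).
#' @param bg_size,marker_size negative-binomial size (inverse dispersion) of
#'   background and marker counts (defaults 0.3 and 2).
#' @param seed integer seed; the dataset is a deterministic function of the
#'   arguments.
#' @return A list of class `sccross_sim`: `counts` (genes x cells),
#'   `sample_map` (two samples `s1`, `s2`), `rare_cells` and `marker_genes`
#'   (sorted integer index vectors, the ground truth), and `config`.
#' @export
generate_mixture <- function(n_cells = 1000L, n_rare = 20L, n_genes = 2000L,
                             n_marker_genes = 50L, marker_rate = 5,
                             marker_bg_rate = 0.01, bg_meanlog = -1.2,
                             bg_sdlog = 1.5, bg_size = 0.3, marker_size = 2,
                             seed = 1L) {
  if (n_marker_genes > n_genes) {
    stop("'n_marker_genes' cannot exceed 'n_genes'")
  }
  if (n_rare >= n_cells) stop("'n_rare' must be smaller than 'n_cells'")
  if (n_cells %% 2L != 0L) stop("'n_cells' must be even (two equal samples)")
  set.seed(seed)

  lambda <- rlnorm(n_genes, bg_meanlog, bg_sdlog)
  marker_genes <- sort(sample.int(n_genes, n_marker_genes))
  lambda[marker_genes] <- marker_bg_rate
  counts <- matrix(rnbinom(n_genes * n_cells, mu = rep(lambda, n_cells),
                           size = bg_size),
                   nrow = n_genes, ncol = n_cells)

  rare <- sort(sample.int(n_cells, n_rare))
  if (n_rare > 0L && marker_rate > 0) {
    counts[marker_genes, rare] <- counts[marker_genes, rare] +
      matrix(rnbinom(n_marker_genes * n_rare, mu = marker_rate,
                     size = marker_size),
             nrow = n_marker_genes)
  }

  # split into two samples of n_cells / 2, rare cells as evenly as possible
  # (odd remainder to sample 1)
  n_half <- n_cells %/% 2L
  n_rare_s1 <- ceiling(n_rare / 2)
  rare_s1 <- if (n_rare > 0L) sort(sample(rare, n_rare_s1)) else integer(0)
  other <- setdiff(seq_len(n_cells), rare)
  other_s1 <- sort(sample(other, n_half - n_rare_s1))
  assignment <- rep("s2", n_cells)
  assignment[c(rare_s1, other_s1)] <- "s1"
  # order samples s1 then s2 regardless of cell positions
  assignment <- factor(assignment, levels = c("s1", "s2"))

  dimnames(counts) <- list(sprintf("g%05d", seq_len(n_genes)),
                           sprintf("c%05d", seq_len(n_cells)))
  smap <- sample_map(assignment, cell_ids = colnames(counts))
  structure(list(
    counts = counts, sample_map = smap,
    rare_cells = rare, marker_genes = marker_genes,
    config = list(n_cells = n_cells, n_rare = n_rare, n_genes = n_genes,
                  n_marker_genes = n_marker_genes, marker_rate = marker_rate,
                  marker_bg_rate = marker_bg_rate, bg_meanlog = bg_meanlog,
                  bg_sdlog = bg_sdlog, bg_size = bg_size,
                  marker_size = marker_size, seed = seed)
  ), class = "sccross_sim")
}

#' @export
print.sccross_sim <- function(x, ...) {
  cat(sprintf("Simulated mixture: %d genes x %d cells, %d rare cells, %d marker genes\n",
              nrow(x$counts), ncol(x$counts), length(x$rare_cells),
              length(x$marker_genes)))
  print(x$sample_map)
  invisible(x)
}

#' Apply an artificial batch effect to the second sample
#'
#' Leaves the first sample untouched and multiplies the expression values of
#' the second sample according to one of three scenarios: `"global"` — every
#' gene is multiplied by one Gaussian factor of mean 0.5 and sd 0.02
#' (roughly halving the sample, factors truncated at 0); `"gene_specific"`
#' — every gene is multiplied by its own uniform factor in `[0.2, 1.8]`;
#' `"value_specific"` — every entry is multiplied by an independent uniform
#' factor in `[0.5, 1.5]`. `"none"` returns the input unchanged.
#'
#' @param counts genes x cells matrix of (raw or normalized) count values.
#' @param smap a [sample_map()] with exactly two samples.
#' @param scenario one of `"none"`, `"global"`, `"gene_specific"`,
#'   `"value_specific"`.
#' @param seed integer seed for the perturbation factors.
#' @return The perturbed matrix (same shape, dimnames preserved).
#' @export
apply_batch_effect <- function(counts, smap,
                               scenario = c("none", "global",
                                            "gene_specific",
                                            "value_specific"),
                               seed = 1L) {
  scenario <- match.arg(scenario)
  counts <- check_counts(counts)
  check_sample_map(smap, ncol(counts))
  if (length(smap$samples) != 2L) {
    stop("batch-effect scenarios are defined for exactly two samples")
  }
  if (scenario == "none") return(counts)
  set.seed(seed)
  s2 <- smap$cells_of[[2L]]
  n_genes <- nrow(counts)
  fac <- switch(scenario,
    global = matrix(pmax(0, rnorm(n_genes, mean = 0.5, sd = 0.02)),
                    nrow = n_genes, ncol = length(s2)),
    gene_specific = matrix(runif(n_genes, 0.2, 1.8),
                           nrow = n_genes, ncol = length(s2)),
    value_specific = matrix(runif(n_genes * length(s2), 0.5, 1.5),
                            nrow = n_genes, ncol = length(s2))
  )
  counts[, s2] <- counts[, s2] * fac
  counts
}

#' Precision, recall and F1 of a recovered cell set
#'
#' Precision is the proportion of true rare cells within the selection (0
#' for an empty selection), recall the proportion of the true rare cells
#' recovered, and F1 their harmonic mean (0 when both are 0).
#'
#' @param selected integer (or id) vector of selected cells.
#' @param truth non-empty integer (or id) vector of planted rare cells.
#' @return A list with `precision`, `recall` and `f1`.
#' @examples
#' f1_score(1:5, 1:10)  # precision 1, recall 0.5, f1 2/3
#' @export
f1_score <- function(selected, truth) {
  if (length(truth) == 0L) stop("'truth' must be non-empty")
  tp <- length(intersect(selected, truth))
  precision <- if (length(selected) == 0L) 0 else tp / length(selected)
  recall <- tp / length(truth)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Run the controlled batch-effect benchmark
#'
#' For every combination of rare-population size, batch scenario and
#' replicate: simulate a mixture, CPM-normalize, perturb the second sample,
#' log-transform, filter generic genes, run the beam search with default
#' parameters (`kappa = 100 / n_cells`), and score the recovered cell set
#' against the planted rare cells. A failed run is recorded with F1 = 0 and
#' the failure message, not raised. The whole benchmark is a deterministic
#' function of its arguments.
#'
#' @param n_rare integer vector of rare-population sizes (default 20).
#' @param scenarios character vector of batch scenarios (default the three
#'   perturbations).
#' @param n_reps replicates per combination (default 10).
#' @param n_cells,n_genes,n_marker_genes,marker_rate passed to
#'   [generate_mixture()].
#' @param params objective parameters; default [sccross_params()] with
#'   automatic kappa.
#' @param beam_width beam width of the solver runs.
#' @param method optional adapter: a `function(m, smap)` returning the
#'   selected cell column indices, so external methods can be scored on the
#'   same simulations; default the internal beam search.
#' @param seed master seed; per-run seeds are derived from it.
#' @param verbose print one line per run.
#' @return An object of class `sccross_benchmark`: `runs` (one row per run
#'   with precision/recall/F1), `summary` (mean F1 per size x scenario) and
#'   `spread` (per size, the largest difference between scenario mean F1).
#' @export
run_benchmark <- function(n_rare = 20L,
                          scenarios = c("global", "gene_specific",
                                        "value_specific"),
                          n_reps = 10L, n_cells = 1000L, n_genes = 2000L,
                          n_marker_genes = 50L, marker_rate = 5,
                          params = sccross_params(), beam_width = 10L,
                          method = NULL, seed = 1L, verbose = FALSE) {
  stopifnot(n_reps >= 1L)
  set.seed(seed)
  n_runs <- length(n_rare) * length(scenarios) * n_reps
  run_seeds <- matrix(sample.int(2^30, 2L * n_runs), ncol = 2L)
  if (is.null(method)) {
    method <- function(m, smap) {
      beam_search(m, smap, params, beam_width = beam_width)$bicluster$cells
    }
  }
  rows <- vector("list", n_runs)
  idx <- 0L
  for (nr in n_rare) {
    for (sc in scenarios) {
      for (rep_i in seq_len(n_reps)) {
        idx <- idx + 1L
        s_gen <- run_seeds[idx, 1L]
        s_batch <- run_seeds[idx, 2L]
        res <- tryCatch({
          sim <- generate_mixture(n_cells = n_cells, n_rare = nr,
                                  n_genes = n_genes,
                                  n_marker_genes = n_marker_genes,
                                  marker_rate = marker_rate, seed = s_gen)
          cn <- cpm_normalize(sim$counts)
          cb <- apply_batch_effect(cn, sim$sample_map, sc, seed = s_batch)
          m <- filter_genes(log_transform(cb))
          sel <- method(m, sim$sample_map)
          sc3 <- f1_score(sel, sim$rare_cells)
          c(sc3, list(n_selected = length(sel), note = ""))
        }, error = function(e) {
          list(precision = 0, recall = 0, f1 = 0, n_selected = 0L,
               note = conditionMessage(e))
        })
        if (verbose) {
          message(sprintf("n_rare=%d %-14s rep %2d: F1 = %.3f",
                          nr, sc, rep_i, res$f1))
        }
        rows[[idx]] <- data.frame(n_rare = nr, scenario = sc, rep = rep_i,
                                  seed_gen = s_gen, seed_batch = s_batch,
                                  precision = res$precision,
                                  recall = res$recall, f1 = res$f1,
                                  n_selected = res$n_selected,
                                  note = res$note,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  runs <- do.call(rbind, rows)
  summ <- aggregate(f1 ~ n_rare + scenario, data = runs, FUN = mean)
  names(summ)[names(summ) == "f1"] <- "mean_f1"
  summ <- summ[order(summ$n_rare, match(summ$scenario, scenarios)), ]
  rownames(summ) <- NULL
  spread <- aggregate(mean_f1 ~ n_rare, data = summ,
                      FUN = function(v) max(v) - min(v))
  names(spread)[names(spread) == "mean_f1"] <- "spread"
  structure(list(runs = runs, summary = summ, spread = spread, seed = seed),
            class = "sccross_benchmark")
}

#' @export
print.sccross_benchmark <- function(x, ...) {
  cat("Controlled batch-effect benchmark (mean F1 over",
      max(x$runs$rep), "replicates)\n")
  print(x$summary, row.names = FALSE)
  cat("Largest cross-scenario spread of mean F1:\n")
  print(x$spread, row.names = FALSE)
  invisible(x)
}
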