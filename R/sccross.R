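#' Find rare cell subpopulations shared across samples
#'
#' Main entry point. Preprocesses a genes x cells count matrix (optional
#' counts-per-million normalization, signed `log10(x + pseudocount)`
#' transform, removal of genes expressed in more than a set fraction of the
#' cells), then runs the beam search one or more times. Each additional run
#' excludes the previously selected cells from the candidate pool — their
#' expression still contributes to the out-of-cluster penalties — so
#' successive runs return disjoint subpopulations. Alternatively,
#' `exclude = "genes"` removes the previously selected genes instead, which
#' can expose hierarchical structure by allowing cells to be clustered again.
#'
#' @param x numeric genes x cells matrix. Raw or normalized counts by
#'   default; set `log = FALSE` if `x` is already on the signed log scale.
#' @param samples a [sample_map()], or a character/factor vector with one
#'   sample label per column of `x`.
#' @param kappa,mu,epsilon objective parameters, see [sccross_params()].
#'   `kappa = "auto"` resolves to `100 / ncol(x)`.
#' @param normalize `"none"` (default) or `"cpm"`. CPM is the usual choice
#'   for full-length (Smart-seq2) counts; pre-normalized input should use
#'   `"none"`.
#' @param log apply the signed log transform (default `TRUE`).
#' @param pseudocount pseudocount of the log transform; default 0.1.
#' @param filter drop generic genes expressed in more than
#'   `max_expr_fraction` of the cells (default `TRUE`).
#' @param max_expr_fraction expression-fraction cap of the gene filter.
#' @param beam_width beam width of the search; default 10.
#' @param runs number of successive biclusters to search for; default 1.
#' @param exclude what successive runs exclude: previously selected
#'   `"cells"` (default) or `"genes"`.
#' @param max_cluster_size optional cap on the number of cells per bicluster.
#' @return An object of class `sccross` with `print`, `summary`, `coef` and
#'   `plot` methods. Element `runs` is the list of per-run results; element
#'   `biclusters` the list of `sccross_bicluster` objects (gene and cell
#'   indices refer to the stored, preprocessed matrix `m`).
#' @examples
#' sim <- generate_mixture(n_cells = 120, n_rare = 8, n_genes = 300,
#'                         n_marker_genes = 25, seed = 7)
#' fit <- sccross(sim$counts, sim$sample_map, normalize = "cpm")
#' fit
#' @export
sccross <- function(x, samples, kappa = "auto", mu = 0.1, epsilon = 0.1,
                    normalize = c("none", "cpm"), log = TRUE,
                    pseudocount = 0.1, filter = TRUE,
                    max_expr_fraction = 0.25, beam_width = 10L, runs = 1L,
                    exclude = c("cells", "genes"), max_cluster_size = Inf) {
  cl <- match.call()
  normalize <- match.arg(normalize)
  exclude <- match.arg(exclude)
  if (inherits(x, "Matrix")) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("'x' must be a numeric genes x cells matrix")
  }
  if (is.null(rownames(x))) {
    rownames(x) <- sprintf("gene%05d", seq_len(nrow(x)))
  }
  if (is.null(colnames(x))) {
    colnames(x) <- sprintf("cell%05d", seq_len(ncol(x)))
  }
  if (!inherits(samples, "sample_map")) {
    samples <- sample_map(samples, cell_ids = colnames(x))
  }
  check_sample_map(samples, ncol(x))
  params <- sccross_params(kappa, mu, epsilon)  # validate before any work

  m <- x
  if (normalize == "cpm") m <- cpm_normalize(m)
  if (log) m <- log_transform(m, pseudocount)
  kept <- seq_len(nrow(m))
  if (filter) {
    m <- filter_genes(m, max_expr_fraction)
    kept <- attr(m, "kept_genes")
  }
  params <- resolve_params(params, ncol(m))

  run_list <- list()
  excluded_cells <- integer(0)
  gene_mask <- rep(TRUE, nrow(m))
  for (r in seq_len(runs)) {
    mr <- m[gene_mask, , drop = FALSE]
    if (nrow(mr) == 0L) {
      message("run ", r, ": no genes left after exclusion; stopping")
      break
    }
    if (length(excluded_cells) >= ncol(m)) {
      message("run ", r, ": no cells left in the candidate pool; stopping")
      break
    }
    res <- beam_search(mr, samples, params, beam_width = beam_width,
                       excluded = excluded_cells,
                       max_cluster_size = max_cluster_size)
    # map gene indices back to rows of the full (filtered) matrix
    gmap <- which(gene_mask)
    res$bicluster$genes <- gmap[res$bicluster$genes]
    res$bicluster$gene_stats$gene <- gmap[res$bicluster$gene_stats$gene]
    res$run_index <- r
    if (length(res$bicluster$cells) == 0L) {
      message("run ", r, " returned an empty bicluster; stopping")
      break
    }
    run_list[[r]] <- res
    if (exclude == "cells") {
      excluded_cells <- sort(union(excluded_cells, res$bicluster$cells))
    } else {
      gene_mask[res$bicluster$genes] <- FALSE
    }
  }

  structure(list(
    runs = run_list,
    biclusters = lapply(run_list, `[[`, "bicluster"),
    m = m,
    params = params,
    sample_map = samples,
    preprocess = list(normalize = normalize, log = log,
                      pseudocount = if (log) pseudocount else NULL,
                      filter = filter,
                      max_expr_fraction = if (filter) max_expr_fraction
                        else NULL,
                      kept_genes = kept,
                      n_genes_input = nrow(x), n_genes_used = nrow(m)),
    exclude = exclude,
    beam_width = beam_width,
    call = cl
  ), class = "sccross")
}

#' @export
print.sccross <- function(x, ...) {
  cat("Cross-sample rare-subpopulation biclustering\n")
  cat(sprintf("  %d cells in %d sample(s); %d of %d genes used (<= %s%% expressed)\n",
              ncol(x$m), length(x$sample_map$samples),
              x$preprocess$n_genes_used, x$preprocess$n_genes_input,
              if (x$preprocess$filter)
                format(100 * x$preprocess$max_expr_fraction) else "100"))
  cat(sprintf("  kappa = %.6g, mu = %g, epsilon = %g\n",
              x$params$kappa, x$params$mu, x$params$epsilon))
  if (length(x$runs) == 0L) {
    cat("  no bicluster found\n")
    return(invisible(x))
  }
  cat(sprintf("  %d run(s):\n", length(x$runs)))
  for (r in seq_along(x$runs)) {
    bc <- x$runs[[r]]$bicluster
    cat(sprintf("  run %d: %3d cells x %4d genes, objective %10.3f, neg. fraction %.3f\n",
                r, length(bc$cells), length(bc$genes), bc$objective,
                bc$neg_fraction))
  }
  invisible(x)
}

#' @export
summary.sccross <- function(object, n_genes = 10L, ...) {
  structure(list(fit = object, n_genes = n_genes),
            class = "summary.sccross")
}

#' @export
print.summary.sccross <- function(x, ...) {
  print(x$fit)
  for (r in seq_along(x$fit$runs)) {
    cat(sprintf("\n-- run %d --\n", r))
    print(x$fit$runs[[r]]$bicluster, n_genes = x$n_genes)
  }
  invisible(x)
}

#' Per-gene contributions of a fitted bicluster
#'
#' @param object an `sccross` fit.
#' @param run which run's bicluster (default 1).
#' @param ... unused.
#' @return Named numeric vector of objective contributions of the selected
#'   genes, decreasing.
#' @export
coef.sccross <- function(object, run = 1L, ...) {
  if (run > length(object$runs)) stop("no run ", run, " in this fit")
  st <- object$runs[[run]]$bicluster$gene_stats
  out <- setNames(st$contribution, st$gene_id)
  sort(out, decreasing = TRUE)
}

#' Heatmap of a fitted bicluster
#'
#' Displays the selected genes (rows, by decreasing contribution) over all
#' cells, selected cells first, then the remaining cells grouped by sample.
#'
#' @param x an `sccross` fit.
#' @param run which run's bicluster (default 1).
#' @param max_out maximum number of out-of-cluster cells drawn (default 200).
#' @param ... passed to [graphics::image()].
#' @return Invisibly, the plotted submatrix.
#' @export
plot.sccross <- function(x, run = 1L, max_out = 200L, ...) {
  if (run > length(x$runs)) stop("no run ", run, " in this fit")
  bc <- x$runs[[run]]$bicluster
  if (length(bc$genes) == 0L) stop("run ", run, " has an empty bicluster")
  genes <- bc$genes[order(-bc$gene_stats$contribution)]
  out_cells <- setdiff(seq_len(ncol(x$m)), bc$cells)
  out_cells <- out_cells[order(match(x$sample_map$assignment[out_cells],
                                     x$sample_map$samples))]
  if (length(out_cells) > max_out) {
    out_cells <- out_cells[seq_len(max_out)]
  }
  cols <- c(bc$cells, out_cells)
  sub <- x$m[genes, cols, drop = FALSE]
  pal <- grDevices::hcl.colors(51, "Blue-Red 3")
  graphics::image(z = t(sub)[, rev(seq_len(nrow(sub))), drop = FALSE],
                  col = pal, axes = FALSE,
                  xlab = sprintf("cells (first %d = bicluster)",
                                 length(bc$cells)),
                  ylab = "selected genes", ...)
  graphics::abline(v = (length(bc$cells) - 0.5) / (length(cols) - 1))
  invisible(sub)
}
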