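# Bicluster container: the joint selection of a gene set I and a cell set J
# together with the per-gene statistics and the objective value.

build_bicluster <- function(m, I, J, st, smap, params,
                            check_constraint = TRUE) {
  I <- as.integer(I)
  J <- as.integer(J)
  if (length(I)) {
    stats_sel <- st[I, , drop = FALSE]
    objective <- sum(stats_sel$contribution)
    neg_fraction <- sum(stats_sel$neg_count) / (length(I) * length(J))
  } else {
    stats_sel <- st[0, , drop = FALSE]
    objective <- 0
    neg_fraction <- 0
  }
  constraint_ok <- neg_fraction <= params$mu + 1e-9
  if (check_constraint && !constraint_ok) {
    stop("internal error: selected gene set violates the negative-fraction cap")
  }
  gene_ids <- rownames(m)
  cell_ids <- colnames(m)
  structure(list(
    genes = I,
    cells = J,
    gene_ids = if (is.null(gene_ids)) as.character(I) else gene_ids[I],
    cell_ids = if (is.null(cell_ids)) as.character(J) else cell_ids[J],
    gene_stats = stats_sel,
    objective = objective,
    neg_fraction = neg_fraction,
    constraint_ok = constraint_ok,
    params = params,
    samples = table(factor(smap$assignment[J], levels = smap$samples))
  ), class = "sccross_bicluster")
}

empty_bicluster <- function(m, smap, params) {
  st <- data.frame(gene = integer(0), gene_id = character(0))
  structure(list(
    genes = integer(0), cells = integer(0),
    gene_ids = character(0), cell_ids = character(0),
    gene_stats = st, objective = 0, neg_fraction = 0,
    constraint_ok = TRUE, params = params,
    samples = table(factor(character(0), levels = smap$samples))
  ), class = "sccross_bicluster")
}

#' @export
print.sccross_bicluster <- function(x, n_genes = 10L, ...) {
  cat(sprintf("Bicluster: %d cell(s) x %d gene(s), objective %.4f\n",
              length(x$cells), length(x$genes), x$objective))
  if (length(x$cells) == 0L) {
    cat("  (empty)\n")
    return(invisible(x))
  }
  cat(sprintf("  negative fraction: %.3f (cap mu = %g)\n",
              x$neg_fraction, x$params$mu))
  comp <- paste(sprintf("%s: %d", names(x$samples), as.integer(x$samples)),
                collapse = ", ")
  cat("  cells per sample: ", comp, "\n", sep = "")
  if (length(x$genes)) {
    top <- x$gene_stats[order(-x$gene_stats$contribution), , drop = FALSE]
    top <- utils::head(top, n_genes)
    cat(sprintf("  top genes (of %d):\n", length(x$genes)))
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %-12s contribution %8.3f  delta %.3f\n",
                  top$gene_id[i], top$contribution[i], top$delta[i]))
    }
  }
  invisible(x)
}
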