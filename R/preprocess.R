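#' Counts-per-million normalization
#'
#' Scales every cell (column) so its counts sum to one million. Intended for
#' full-length protocols (e.g. Smart-seq2); UMI data that is already
#' depth-normalized can skip this step.
#'
#' @param counts numeric genes x cells matrix of non-negative counts.
#' @return A matrix of the same shape whose columns each sum to `1e6`.
#' @examples
#' m <- matrix(c(1, 3, 2, 2), nrow = 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
#' cpm_normalize(m)
#' @export
cpm_normalize <- function(counts) {
  counts <- check_counts(counts)
  libs <- colSums(counts)
  if (any(libs == 0)) {
    bad <- colnames(counts)[libs == 0]
    if (is.null(bad)) bad <- which(libs == 0)
    stop("cell(s) with all-zero counts cannot be normalized: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  out <- sweep(counts, 2L, libs, "/") * 1e6
  add_provenance(out, counts, "cpm")
}

#' Signed log transform of expression values
#'
#' Applies `log10(x + pseudocount)` elementwise. With the default pseudocount
#' of 0.1, zero counts map exactly to -1 and values >= 0.9 stay non-negative,
#' so the sign of an entry encodes whether the cell expresses the gene
#' (strictly positive = expressed).
#'
#' @param counts numeric genes x cells matrix of non-negative values (raw or
#'   normalized counts).
#' @param pseudocount positive offset added before taking `log10`; default 0.1.
#' @return The log-scale expression matrix, with attributes `pseudocount` and
#'   `provenance` recording the transform.
#' @examples
#' log_transform(matrix(c(0, 0.9, 9.9), ncol = 1))  # -1, 0, 1
#' @export
log_transform <- function(counts, pseudocount = 0.1) {
  counts <- check_counts(counts)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      !is.finite(pseudocount) || pseudocount <= 0) {
    stop("'pseudocount' must be a single positive number")
  }
  out <- log10(counts + pseudocount)
  out <- add_provenance(out, counts,
                        sprintf("log10(x + %g)", pseudocount))
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Restrict the gene universe to sparsely expressed genes
#'
#' Keeps exactly the genes whose number of strictly positive (expressed)
#' entries is at most `max_expr_fraction` of the cells; genes expressed in
#' strictly more of the cells are generic high-expression markers rather
#' than rare patterns, and are discarded. Operates on the signed log-scale
#' matrix, where an entry is "expressed" iff it is strictly positive.
#'
#' @param m log-scale expression matrix (see [log_transform()]).
#' @param max_expr_fraction maximum fraction of cells a kept gene may be
#'   expressed in, in `(0, 1]`. Default 0.25.
#' @return The row-subset matrix; attribute `kept_genes` holds the integer
#'   indices of the kept rows relative to the input.
#' @examples
#' m <- log_transform(matrix(c(5, 0, 5, 5, 0, 0), nrow = 3))
#' filter_genes(m, max_expr_fraction = 0.5)
#' @export
filter_genes <- function(m, max_expr_fraction = 0.25) {
  if (!is.matrix(m) || !is.numeric(m)) stop("'m' must be a numeric matrix")
  if (!is.numeric(max_expr_fraction) || length(max_expr_fraction) != 1L ||
      is.na(max_expr_fraction) || max_expr_fraction <= 0 ||
      max_expr_fraction > 1) {
    stop("'max_expr_fraction' must be in (0, 1]")
  }
  n_pos <- rowSums(m > 0)
  keep <- which(n_pos <= max_expr_fraction * ncol(m))
  if (length(keep) == 0L) {
    stop("no gene is expressed in at most ",
         format(100 * max_expr_fraction),
         "% of the cells; raise 'max_expr_fraction'")
  }
  out <- m[keep, , drop = FALSE]
  out <- add_provenance(out, m,
                        sprintf("filter_genes(<= %g of cells)",
                                max_expr_fraction))
  attr(out, "pseudocount") <- attr(m, "pseudocount")
  attr(out, "kept_genes") <- keep
  out
}

# ---- internal helpers -------------------------------------------------------

check_counts <- function(x) {
  if (inherits(x, "Matrix")) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expected a numeric genes x cells matrix")
  }
  if (anyNA(x)) stop("the matrix contains missing values")
  if (any(x < 0)) stop("the matrix contains negative values")
  x
}

add_provenance <- function(out, input, step) {
  prov <- attr(input, "provenance")
  attr(out, "provenance") <- c(prov, step)
  out
}
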