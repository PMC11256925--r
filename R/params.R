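#' Optimization parameters
#'
#' Bundle of the three tuning parameters of the bicluster objective.
#'
#' @param kappa penalty weight on out-of-cluster positive expression. The
#'   higher the value, the fewer genes obtain a positive specificity score.
#'   `"auto"` (the default) resolves to `100 / n_cells` when a data matrix is
#'   available.
#' @param mu maximum allowed fraction of negative (non-expressed) entries in
#'   the selected genes-by-cells submatrix, in `[0, 1]`. Default 0.1.
#' @param epsilon clipping floor applied to per-sample specificity scores
#'   before the geometric/arithmetic mean ratio is taken, so the ratio stays
#'   in the real domain. Must be positive. Default 0.1.
#'
#' @return An object of class `sccross_params`.
#' @examples
#' sccross_params(kappa = 0.004, mu = 0.1)
#' @export
sccross_params <- function(kappa = "auto", mu = 0.1, epsilon = 0.1) {
  if (!identical(kappa, "auto")) {
    if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) ||
        kappa <= 0) {
      stop("'kappa' must be a single positive number or \"auto\"")
    }
  }
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0 || mu > 1) {
    stop("'mu' must be a single number in [0, 1]")
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 0) {
    stop("'epsilon' must be a single positive number")
  }
  structure(list(kappa = kappa, mu = mu, epsilon = epsilon),
            class = "sccross_params")
}

#' @export
print.sccross_params <- function(x, ...) {
  kap <- if (identical(x$kappa, "auto")) "auto (100 / n_cells)" else
    format(x$kappa)
  cat("Bicluster objective parameters:\n")
  cat("  kappa   :", kap, "\n")
  cat("  mu      :", format(x$mu), "\n")
  cat("  epsilon :", format(x$epsilon), "\n")
  invisible(x)
}

# Resolve kappa = "auto" against the number of cells of the data at hand.
resolve_params <- function(params, n_cells) {
  if (!inherits(params, "sccross_params")) {
    stop("'params' must be created by sccross_params()")
  }
  if (identical(params$kappa, "auto")) params$kappa <- 100 / n_cells
  params
}
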