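#' Partition of cells into samples
#'
#' Builds the sample map used throughout the package: an assignment of every
#' cell (column of the expression matrix) to one named sample. Samples are
#' ordered by first appearance; every sample must be non-empty and the
#' samples partition the full set of cells.
#'
#' @param samples character or factor vector with one sample label per cell,
#'   in column order of the matrix it describes.
#' @param cell_ids optional character vector of cell identifiers (same
#'   length); stored for reporting.
#'
#' @return An object of class `sample_map` with elements `assignment`
#'   (character vector), `samples` (sample ids in order of first appearance),
#'   `cells_of` (named list of integer column index vectors) and `cell_ids`.
#' @examples
#' sm <- sample_map(c("d1", "d1", "d2", "d2"))
#' sm$cells_of
#' @export
sample_map <- function(samples, cell_ids = NULL) {
  if (length(samples) == 0L) stop("'samples' must be non-empty")
  lev <- if (is.factor(samples)) as.character(unique(levels(samples)[
    levels(samples) %in% as.character(samples)])) else NULL
  samples <- as.character(samples)
  if (anyNA(samples)) stop("'samples' contains missing values")
  if (!is.null(cell_ids)) {
    cell_ids <- as.character(cell_ids)
    if (length(cell_ids) != length(samples)) {
      stop("'cell_ids' must have one entry per cell")
    }
    if (anyDuplicated(cell_ids)) stop("duplicated cell ids in 'cell_ids'")
  }
  ids <- if (is.null(lev)) unique(samples) else lev
  cells_of <- lapply(ids, function(s) which(samples == s))
  names(cells_of) <- ids
  structure(list(assignment = samples, samples = ids, cells_of = cells_of,
                 cell_ids = cell_ids),
            class = "sample_map")
}

#' @export
print.sample_map <- function(x, ...) {
  cat(sprintf("Sample map: %d cells in %d sample(s)\n",
              length(x$assignment), length(x$samples)))
  sizes <- vapply(x$cells_of, length, integer(1))
  for (s in x$samples) cat(sprintf("  %s: %d cells\n", s, sizes[[s]]))
  invisible(x)
}

# Internal: check a sample map against a matrix with n columns.
check_sample_map <- function(smap, n_cells) {
  if (!inherits(smap, "sample_map")) {
    stop("'samples' must be a sample_map (see sample_map())")
  }
  if (length(smap$assignment) != n_cells) {
    stop(sprintf("sample map covers %d cells but the matrix has %d columns",
                 length(smap$assignment), n_cells))
  }
  invisible(smap)
}
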