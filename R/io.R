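# Readers and writers: MatrixMarket triplets with 10x-style sidecars, dense
# CSV/TSV, sample maps, and the JSON + TSV run report.

#' Read a genes x cells count matrix
#'
#' Supports the 10x-style MatrixMarket triplet layout (`matrix.mtx` with
#' `features.tsv`/`genes.tsv` and `barcodes.tsv` sidecars; the feature file
#' may carry extra columns, the first is used as the id) and dense CSV/TSV
#' with gene ids in the first column and cell ids in the header row.
#'
#' @param path for `layout = "mtx"`, the `.mtx` file or its directory; for
#'   dense layouts, the delimited file.
#' @param layout `"mtx"`, `"csv"` or `"tsv"`.
#' @param transposed set `TRUE` if the stored matrix is cells x genes; it is
#'   transposed to genes x cells after reading.
#' @param features,barcodes optional explicit sidecar paths (mtx layout).
#' @return A numeric genes x cells matrix with unique dimnames.
#' @export
read_count_matrix <- function(path, layout = c("mtx", "csv", "tsv"),
                              transposed = FALSE, features = NULL,
                              barcodes = NULL) {
  layout <- match.arg(layout)
  if (layout == "mtx") {
    if (dir.exists(path)) {
      mtx <- file.path(path, "matrix.mtx")
      dir <- path
    } else {
      mtx <- path
      dir <- dirname(path)
    }
    if (!file.exists(mtx)) stop("matrix file not found: ", mtx)
    if (is.null(features)) {
      features <- file.path(dir, c("features.tsv", "genes.tsv"))
      features <- features[file.exists(features)][1]
      if (is.na(features)) stop("no features.tsv/genes.tsv next to ", mtx)
    }
    if (is.null(barcodes)) {
      barcodes <- file.path(dir, "barcodes.tsv")
      if (!file.exists(barcodes)) stop("no barcodes.tsv next to ", mtx)
    }
    x <- as.matrix(Matrix::readMM(mtx))
    feat <- read.delim(features, header = FALSE, stringsAsFactors = FALSE)
    bars <- read.delim(barcodes, header = FALSE, stringsAsFactors = FALSE)
    row_ids <- as.character(feat[[1L]])
    col_ids <- as.character(bars[[1L]])
    if (transposed) x <- t(x)
    if (nrow(x) != length(row_ids)) {
      stop(sprintf("feature file has %d ids but the matrix has %d rows",
                   length(row_ids), nrow(x)))
    }
    if (ncol(x) != length(col_ids)) {
      stop(sprintf("barcode file has %d ids but the matrix has %d columns",
                   length(col_ids), ncol(x)))
    }
    dimnames(x) <- list(row_ids, col_ids)
  } else {
    sep <- if (layout == "csv") "," else "\t"
    df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    ids <- as.character(df[[1L]])
    x <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(x)) stop("non-numeric entries in ", path)
    rownames(x) <- ids
    if (transposed) x <- t(x)
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicated gene ids in ", path)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicated cell ids in ", path)
  }
  check_counts(x)
  x
}

#' Read a cell-to-sample assignment
#'
#' Reads a two-column TSV (`cell_id`, `sample_id`; a header row with those
#' names is tolerated) and returns the [sample_map()] aligned with the given
#' cell order. Every cell of the matrix must be assigned exactly once;
#' samples are ordered by first appearance in the file.
#'
#' @param path path to the TSV file.
#' @param cell_ids character vector of cell ids in matrix column order.
#' @return A [sample_map()].
#' @export
read_sample_map <- function(path, cell_ids) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected two columns (cell_id, sample_id) in ",
                          path)
  if (identical(tolower(as.character(df[1L, 1:2])),
                c("cell_id", "sample_id"))) {
    df <- df[-1L, , drop = FALSE]
  }
  ids <- as.character(df[[1L]])
  labs <- as.character(df[[2L]])
  if (anyDuplicated(ids)) {
    stop("cell id(s) assigned more than once: ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5L),
               collapse = ", "))
  }
  hit <- match(cell_ids, ids)
  if (anyNA(hit)) {
    stop("cell id(s) missing from ", path, ": ",
         paste(utils::head(cell_ids[is.na(hit)], 5L), collapse = ", "))
  }
  extra <- setdiff(ids, cell_ids)
  if (length(extra)) {
    stop("cell id(s) absent from the matrix: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  }
  # sample order by first appearance in the file, assignment in matrix order
  labs_matrix_order <- labs[hit]
  first_seen <- unique(labs)
  smap <- sample_map(factor(labs_matrix_order, levels = first_seen),
                     cell_ids = cell_ids)
  smap
}

#' Write a count matrix in the MatrixMarket triplet layout
#'
#' Emits `matrix.mtx`, `features.tsv` and `barcodes.tsv` into a directory.
#'
#' @param counts genes x cells matrix with dimnames.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_count_matrix <- function(counts, dir) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("'counts' must have gene and cell ids as dimnames")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), mtx)
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(c(mtx, file.path(dir, c("features.tsv", "barcodes.tsv"))))
}

#' Write a simulated dataset with its ground truth
#'
#' Writes the counts in MatrixMarket layout plus `samples.tsv` (cell id,
#' sample id) and `truth.json` (rare cell ids, marker gene ids, generator
#' configuration).
#'
#' @param sim a [generate_mixture()] result.
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  if (!inherits(sim, "sccross_sim")) stop("'sim' must be a sccross_sim")
  write_count_matrix(sim$counts, dir)
  write.table(data.frame(cell_id = colnames(sim$counts),
                         sample_id = sim$sample_map$assignment),
              file.path(dir, "samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(
    rare_cells = colnames(sim$counts)[sim$rare_cells],
    marker_genes = rownames(sim$counts)[sim$marker_genes],
    config = sim$config
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
  invisible(dir)
}

#' Write a reproducible run report
#'
#' Writes `report.json` — parameters, preprocessing provenance, input file
#' checksums when available, and every run's bicluster (gene ids, cell ids,
#' per-gene consistency weight, per-sample specificity scores, contribution,
#' objective, negative fraction) — plus one `bicluster_<r>.tsv` per run with
#' the per-gene table and a footer line listing the selected cell ids. Field
#' order is fixed, so identical fits produce identical reports.
#'
#' @param fit an [sccross()] result.
#' @param dir output directory (created if needed).
#' @param input optional named character vector of input file paths; their
#'   md5 checksums are recorded.
#' @return Invisibly, the path of `report.json`.
#' @export
write_report <- function(fit, dir, input = NULL) {
  if (!inherits(fit, "sccross")) stop("'fit' must be an sccross fit")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- NULL
  if (!is.null(input)) {
    sums <- tools::md5sum(input)
    prov <- lapply(seq_along(input), function(i) {
      list(file = unname(input[i]), md5 = unname(sums[i]))
    })
    names(prov) <- if (is.null(names(input))) basename(input) else
      names(input)
  }
  runs <- lapply(seq_along(fit$runs), function(r) {
    bc <- fit$runs[[r]]$bicluster
    st <- bc$gene_stats
    list(run = r,
         n_cells = length(bc$cells),
         n_genes = length(bc$genes),
         objective = bc$objective,
         neg_fraction = bc$neg_fraction,
         cell_ids = bc$cell_ids,
         gene_table = st[, setdiff(names(st), "gene"), drop = FALSE])
  })
  report <- list(
    tool = "scCross",
    version = as.character(utils::packageVersion("scCross")),
    parameters = list(kappa = fit$params$kappa, mu = fit$params$mu,
                      epsilon = fit$params$epsilon,
                      beam_width = fit$beam_width,
                      exclude = fit$exclude),
    preprocess = fit$preprocess[c("normalize", "log", "pseudocount",
                                  "filter", "max_expr_fraction",
                                  "n_genes_input", "n_genes_used")],
    samples = fit$sample_map$samples,
    input = prov,
    runs = runs
  )
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows", null = "null")
  for (r in seq_along(fit$runs)) {
    bc <- fit$runs[[r]]$bicluster
    tsv <- file.path(dir, sprintf("bicluster_%d.tsv", r))
    st <- bc$gene_stats[order(-bc$gene_stats$contribution), , drop = FALSE]
    st$gene <- NULL
    con <- file(tsv, "w")
    write.table(st, con, sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(paste0("# cells: ", paste(bc$cell_ids, collapse = "\t")), con)
    close(con)
  }
  invisible(json_path)
}
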