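#' Construct a layered single-cell expression bundle
#'
#' A bundle mirrors the layered single-cell container used across the
#' scverse ecosystem: an `X` matrix of cells x genes plus aligned annotation
#' layers. `obs` carries one row per cell (first column `cell_id`), `var`
#' one row per gene (first column `gene`), `obsm`/`varm` hold per-cell and
#' per-gene matrices, `obsp` cell-pairwise (sparse) matrices, and `uns`
#' arbitrary unstructured metadata.
#'
#' @param X numeric matrix (cells x genes), a `Matrix` sparse matrix, or a
#'   matrix accessor created by [matrix_accessor()] (e.g. a backed H5AD
#'   matrix). Dense values must be non-negative for count workflows, but the
#'   container itself accepts any numeric values.
#' @param obs data frame of per-cell annotations. A `cell_id` column is used
#'   as the cell barcode; if absent, row names of `X` are used, and failing
#'   that ids `cell_1 ... cell_n` are generated.
#' @param var data frame of per-gene annotations. A `gene` column is used as
#'   the gene name; if absent, column names of `X` are used, then `g1 ... gp`.
#' @param obsm,varm named lists of numeric matrices with as many rows as
#'   cells (`obsm`) or genes (`varm`).
#' @param obsp named list of square cell-by-cell matrices (dense or sparse).
#' @param uns named list of unstructured metadata (scalars, arrays, nested
#'   named lists).
#' @return An object of class `sc_bundle`.
#' @examples
#' b <- sc_bundle(matrix(rpois(6, 5), 2, 3))
#' dim(b)
#' @export
sc_bundle <- function(X, obs = NULL, var = NULL, obsm = list(), varm = list(),
                      obsp = list(), uns = list()) {
  acc <- if (inherits(X, "sc_matrix_accessor")) X else matrix_accessor(X)
  n <- acc$n_cells
  p <- acc$n_genes

  cell_ids <- NULL
  if (!is.null(obs) && "cell_id" %in% names(obs)) cell_ids <- as.character(obs$cell_id)
  if (is.null(cell_ids) && !is.null(acc$row_names)) cell_ids <- acc$row_names
  if (is.null(cell_ids)) cell_ids <- make_ids("cell_", n)
  if (anyDuplicated(cell_ids)) {
    abort_scsql("cell ids must be unique", "inconsistent_bundle")
  }

  gene_ids <- NULL
  if (!is.null(var) && "gene" %in% names(var)) gene_ids <- as.character(var$gene)
  if (is.null(gene_ids) && !is.null(acc$col_names)) gene_ids <- acc$col_names
  if (is.null(gene_ids)) gene_ids <- make_ids("g", p)

  obs <- if (is.null(obs)) tibble::tibble(cell_id = cell_ids) else {
    obs <- tibble::as_tibble(obs)
    obs$cell_id <- cell_ids
    dplyr::relocate(obs, "cell_id")
  }
  var <- if (is.null(var)) tibble::tibble(gene = gene_ids) else {
    var <- tibble::as_tibble(var)
    var$gene <- gene_ids
    dplyr::relocate(var, "gene")
  }

  if (nrow(obs) != n) abort_scsql("obs rows must equal X rows", "inconsistent_bundle")
  if (nrow(var) != p) abort_scsql("var rows must equal X columns", "inconsistent_bundle")
  for (nm in names(obsm)) {
    if (NROW(obsm[[nm]]) != n) {
      abort_scsql(paste0("obsm[['", nm, "']] must have one row per cell"), "inconsistent_bundle")
    }
  }
  for (nm in names(varm)) {
    if (NROW(varm[[nm]]) != p) {
      abort_scsql(paste0("varm[['", nm, "']] must have one row per gene"), "inconsistent_bundle")
    }
  }
  for (nm in names(obsp)) {
    if (!all(dim(obsp[[nm]]) == c(n, n))) {
      abort_scsql(paste0("obsp[['", nm, "']] must be cells x cells"), "inconsistent_bundle")
    }
  }

  structure(
    list(X = acc, obs = obs, var = var, obsm = obsm, varm = varm,
         obsp = obsp, uns = uns),
    class = "sc_bundle"
  )
}

#' @export
dim.sc_bundle <- function(x) c(x$X$n_cells, x$X$n_genes)

#' @export
print.sc_bundle <- function(x, ...) {
  d <- dim(x)
  cat("<sc_bundle> ", d[1], " cells x ", d[2], " genes (",
      if (x$X$backed) "backed" else "in-memory", " X)\n", sep = "")
  cat("  obs: ", paste(names(x$obs), collapse = ", "), "\n", sep = "")
  cat("  var: ", paste(names(x$var), collapse = ", "), "\n", sep = "")
  if (length(x$obsm)) cat("  obsm:", paste(names(x$obsm), collapse = ", "), "\n")
  if (length(x$varm)) cat("  varm:", paste(names(x$varm), collapse = ", "), "\n")
  if (length(x$obsp)) cat("  obsp:", paste(names(x$obsp), collapse = ", "), "\n")
  if (length(x$uns))  cat("  uns: ", paste(names(x$uns), collapse = ", "), "\n")
  invisible(x)
}

#' Materialize a bundle's X as a dense matrix
#'
#' Fetches the full expression matrix through the bundle's accessor. For a
#' backed bundle this reads the whole matrix into memory; prefer chunked
#' operations for large data.
#' @param bundle an [sc_bundle()].
#' @return dense numeric matrix, cells x genes, with cell ids as row names
#'   and gene names as column names.
#' @export
bundle_matrix <- function(bundle) {
  m <- bundle$X$fetch(seq_len(bundle$X$n_cells))
  rownames(m) <- bundle$obs$cell_id
  colnames(m) <- bundle$var$gene
  m
}

#' Wrap a matrix (or matrix-like source) as a chunkable accessor
#'
#' Accessors decouple ingestion from storage: an accessor knows its shape and
#' can fetch an arbitrary set of rows (cells) as a dense block. In-memory
#' dense and sparse matrices are wrapped directly; H5AD-backed accessors are
#' produced by [read_h5ad()] with `backed = TRUE`.
#'
#' @param x numeric matrix or a `Matrix` sparse matrix (cells x genes).
#' @return an object of class `sc_matrix_accessor` with fields `n_cells`,
#'   `n_genes`, `backed`, and `fetch(rows)` returning a dense base matrix.
#' @export
matrix_accessor <- function(x) {
  if (inherits(x, "sc_matrix_accessor")) return(x)
  if (!(is.matrix(x) || inherits(x, "Matrix"))) {
    abort_scsql("X must be a matrix, Matrix, or matrix accessor", "inconsistent_bundle")
  }
  structure(
    list(
      n_cells = nrow(x),
      n_genes = ncol(x),
      backed = FALSE,
      row_names = rownames(x),
      col_names = colnames(x),
      fetch = function(rows) {
        block <- x[rows, , drop = FALSE]
        if (inherits(block, "Matrix")) block <- as.matrix(block)
        storage.mode(block) <- "double"
        block
      }
    ),
    class = "sc_matrix_accessor"
  )
}

#' Instrument an accessor to record its largest row request
#'
#' Used to verify the out-of-core contract: during a chunked ingestion no
#' single fetch should ever request more rows than the chunk size.
#' @param accessor an `sc_matrix_accessor`.
#' @return an accessor whose `max_rows_requested()` reports the largest
#'   number of rows fetched in one call so far.
#' @export
instrument_accessor <- function(accessor) {
  state <- new.env(parent = emptyenv())
  state$max_rows <- 0L
  inner <- accessor$fetch
  out <- accessor
  out$fetch <- function(rows) {
    state$max_rows <- max(state$max_rows, length(rows))
    inner(rows)
  }
  out$max_rows_requested <- function() state$max_rows
  class(out) <- class(accessor)
  out
}
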