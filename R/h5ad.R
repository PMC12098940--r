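# H5AD input/output built on rhdf5. The on-disk convention is the layered
# single-cell H5 format: X as a dense dataset or a CSR/CSC group
# (data/indices/indptr + shape), obs/var as dataframe groups keyed by an
# "_index" attribute, obsm/varm as groups of 2-D arrays, obsp as sparse
# groups, uns as nested groups. HDF5 is row-major while R is column-major,
# so every 2-D object is transposed at the boundary.

#' Read an H5AD file
#'
#' @param path path to an `.h5ad` file.
#' @param backed if `TRUE`, the expression matrix is not loaded; the
#'   returned bundle's `X` is an accessor that streams blocks of cells from
#'   disk on demand (dense and CSR layouts; a CSC matrix cannot be row-sliced
#'   efficiently and is loaded in full with a warning).
#' @return an [sc_bundle()].
#' @export
read_h5ad <- function(path, backed = FALSE) {
  if (!file.exists(path)) abort_scsql(paste0("file not found: ", path), "not_found")
  contents <- rhdf5::h5ls(path)
  top <- contents$name[contents$group == "/"]

  x_acc <- read_h5ad_x(path, backed)
  obs <- if ("obs" %in% top) read_h5_dataframe(path, "obs") else NULL
  var <- if ("var" %in% top) read_h5_dataframe(path, "var") else NULL
  if (!is.null(obs)) names(obs)[1] <- "cell_id"
  if (!is.null(var)) names(var)[1] <- "gene"

  read_mats <- function(layer) {
    if (!layer %in% top) return(list())
    nms <- contents$name[contents$group == paste0("/", layer)]
    rlang::set_names(lapply(nms, function(nm) {
      t(rhdf5::h5read(path, paste0(layer, "/", nm)))
    }), nms)
  }
  obsm <- read_mats("obsm")
  varm <- read_mats("varm")
  obsp <- list()
  if ("obsp" %in% top) {
    nms <- contents$name[contents$group == "/obsp"]
    obsp <- rlang::set_names(lapply(nms, function(nm) {
      read_h5_sparse(path, paste0("obsp/", nm))
    }), nms)
  }
  uns <- if ("uns" %in% top) read_h5_uns(path, "uns") else list()

  rhdf5::h5closeAll()
  sc_bundle(x_acc, obs = obs, var = var, obsm = obsm, varm = varm,
            obsp = obsp, uns = uns)
}

read_h5ad_x <- function(path, backed) {
  is_group <- rhdf5::h5ls(path, recursive = FALSE)
  x_kind <- is_group$otype[is_group$name == "X"]
  if (length(x_kind) == 0) abort_scsql("no X entry in file", "io")

  if (x_kind == "H5I_DATASET") {
    # dense: file shape (n_obs, n_vars) appears in R as (n_vars, n_obs)
    info <- rhdf5::h5ls(path)
    dims <- as.integer(strsplit(info$dim[info$group == "/" & info$name == "X"], " x ")[[1]])
    n_vars <- dims[1]; n_obs <- dims[2]
    if (!backed) {
      m <- t(rhdf5::h5read(path, "X"))
      storage.mode(m) <- "double"
      return(matrix_accessor(m))
    }
    return(structure(list(
      n_cells = n_obs, n_genes = n_vars, backed = TRUE,
      row_names = NULL, col_names = NULL,
      fetch = function(rows) {
        block <- t(rhdf5::h5read(path, "X", index = list(NULL, rows)))
        storage.mode(block) <- "double"
        block
      }
    ), class = "sc_matrix_accessor"))
  }

  att <- rhdf5::h5readAttributes(path, "X")
  enc <- att[["encoding-type"]] %||% if (!is.null(att[["shape"]])) "csr_matrix" else NULL
  shape <- as.integer(att[["shape"]])  # (n_obs, n_vars)
  if (is.null(enc) || !enc %in% c("csr_matrix", "csc_matrix")) {
    abort_scsql("unsupported X encoding (expected dense, csr_matrix or csc_matrix)", "io")
  }
  n_obs <- shape[1]; n_vars <- shape[2]
  if (enc == "csr_matrix" && backed) {
    indptr <- as.numeric(rhdf5::h5read(path, "X/indptr"))
    return(structure(list(
      n_cells = n_obs, n_genes = n_vars, backed = TRUE,
      row_names = NULL, col_names = NULL,
      fetch = function(rows) {
        out <- matrix(0, length(rows), n_vars)
        for (k in seq_along(rows)) {
          r <- rows[k]
          lo <- indptr[r] + 1; hi <- indptr[r + 1]
          if (hi >= lo) {
            idx <- as.integer(rhdf5::h5read(path, "X/indices", index = list(lo:hi)))
            val <- as.numeric(rhdf5::h5read(path, "X/data", index = list(lo:hi)))
            out[k, idx + 1L] <- val
          }
        }
        out
      }
    ), class = "sc_matrix_accessor"))
  }
  if (backed) rlang::warn("CSC matrix cannot be streamed by rows; loading in full")
  m <- read_h5_sparse(path, "X")
  matrix_accessor(m)
}

read_h5_sparse <- function(path, name) {
  att <- rhdf5::h5readAttributes(path, name)
  shape <- as.integer(att[["shape"]])
  data <- as.numeric(rhdf5::h5read(path, paste0(name, "/data")))
  indices <- as.integer(rhdf5::h5read(path, paste0(name, "/indices")))
  indptr <- as.integer(rhdf5::h5read(path, paste0(name, "/indptr")))
  enc <- att[["encoding-type"]] %||% "csr_matrix"
  if (enc == "csr_matrix") {
    Matrix::sparseMatrix(j = indices + 1L, p = indptr, x = data,
                         dims = shape, repr = "R")
  } else {
    Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                         dims = shape, repr = "C")
  }
}

read_h5_dataframe <- function(path, name) {
  att <- rhdf5::h5readAttributes(path, name)
  idx_col <- att[["_index"]] %||% "_index"
  contents <- rhdf5::h5ls(path)
  children <- contents[contents$group == paste0("/", name), ]
  read_col <- function(cn) {
    cpath <- paste0(name, "/", cn)
    if (children$otype[children$name == cn] == "H5I_GROUP") {
      codes <- as.integer(rhdf5::h5read(path, paste0(cpath, "/codes")))
      cats <- as.character(rhdf5::h5read(path, paste0(cpath, "/categories")))
      out <- rep(NA_character_, length(codes))
      out[codes >= 0] <- cats[codes[codes >= 0] + 1L]
      out
    } else {
      v <- rhdf5::h5read(path, cpath)
      catt <- rhdf5::h5readAttributes(path, cpath)
      if (isTRUE(catt[["scsql-logical"]] == 1L)) as.logical(v) else as.vector(v)
    }
  }
  order_att <- att[["column-order"]]
  cols <- if (!is.null(order_att)) as.character(order_att) else
    setdiff(children$name, idx_col)
  idx <- as.character(rhdf5::h5read(path, paste0(name, "/", idx_col)))
  out <- tibble::tibble(!!idx_col := idx)
  if (length(cols)) {
    df <- tibble::as_tibble(rlang::set_names(lapply(cols, read_col), cols))
    out <- dplyr::bind_cols(out, df)
  }
  out
}

read_h5_uns <- function(path, name) {
  contents <- rhdf5::h5ls(path)
  children <- contents[contents$group == paste0("/", name), ]
  out <- list()
  for (i in seq_len(nrow(children))) {
    cn <- children$name[i]
    cpath <- paste0(name, "/", cn)
    if (children$otype[i] == "H5I_GROUP") {
      out[[cn]] <- read_h5_uns(path, cpath)
    } else {
      v <- rhdf5::h5read(path, cpath)
      catt <- rhdf5::h5readAttributes(path, cpath)
      if (is.array(v) && length(dim(v)) == 2) v <- t(v)
      if (is.array(v) && length(dim(v)) == 1) v <- as.vector(v)
      if (isTRUE(catt[["scsql-logical"]] == 1L)) v <- as.logical(v)
      if (isTRUE(catt[["scsql-scalar"]] == 1L) && length(v) == 1L) v <- v[[1]]
      out[[cn]] <- v
    }
  }
  out
}

#' Write a bundle to an H5AD file
#'
#' Writes the dense expression matrix, obs/var dataframes (character,
#' numeric, integer and logical columns), obsm/varm matrices, obsp sparse
#' matrices (CSR) and the uns layer with the standard group encodings, so
#' the file is readable by scverse tooling and by [read_h5ad()] (including
#' backed mode).
#'
#' @param bundle an [sc_bundle()].
#' @param path destination path (`.h5ad`).
#' @return `path`, invisibly.
#' @export
write_h5ad <- function(bundle, path) {
  stopifnot(inherits(bundle, "sc_bundle"))
  unlink(path)
  rhdf5::h5createFile(path)
  fid <- rhdf5::H5Fopen(path)
  on.exit({
    rhdf5::H5Fclose(fid)
    rhdf5::h5closeAll()
  }, add = TRUE)

  h5_set_attrs(fid, list(`encoding-type` = "anndata", `encoding-version` = "0.1.0"))

  X <- bundle_matrix(bundle)
  # chunked layout so backed mode can read cell blocks efficiently
  rhdf5::h5createDataset(fid, "X", dims = c(ncol(X), nrow(X)),
                         storage.mode = "double",
                         chunk = c(min(ncol(X), 512L), min(nrow(X), 512L)),
                         level = 1)
  rhdf5::h5write(t(unname(X)), fid, "X")
  h5_set_attrs_at(fid, "X", list(`encoding-type` = "array", `encoding-version` = "0.2.0"))

  write_h5_dataframe(fid, "obs", as.data.frame(bundle$obs), index_col = "cell_id")
  write_h5_dataframe(fid, "var", as.data.frame(bundle$var), index_col = "gene")

  write_mats <- function(layer, mats) {
    rhdf5::h5createGroup(fid, layer)
    h5_set_attrs_at(fid, layer, list(`encoding-type` = "dict", `encoding-version` = "0.1.0"))
    for (nm in names(mats)) {
      d <- paste0(layer, "/", nm)
      rhdf5::h5write(t(unname(as.matrix(mats[[nm]]))), fid, d)
      h5_set_attrs_at(fid, d, list(`encoding-type` = "array", `encoding-version` = "0.2.0"))
    }
  }
  write_mats("obsm", bundle$obsm)
  write_mats("varm", bundle$varm)

  rhdf5::h5createGroup(fid, "obsp")
  h5_set_attrs_at(fid, "obsp", list(`encoding-type` = "dict", `encoding-version` = "0.1.0"))
  for (nm in names(bundle$obsp)) {
    g <- paste0("obsp/", nm)
    m <- methods::as(methods::as(bundle$obsp[[nm]], "generalMatrix"), "RsparseMatrix")
    rhdf5::h5createGroup(fid, g)
    rhdf5::h5write(m@x, fid, paste0(g, "/data"))
    rhdf5::h5write(m@j, fid, paste0(g, "/indices"))
    rhdf5::h5write(m@p, fid, paste0(g, "/indptr"))
    h5_set_attrs_at(fid, g, list(`encoding-type` = "csr_matrix",
                                 `encoding-version` = "0.1.0",
                                 shape = as.integer(dim(m))))
  }

  write_h5_uns(fid, "uns", bundle$uns)
  invisible(path)
}

write_h5_dataframe <- function(fid, name, df, index_col) {
  rhdf5::h5createGroup(fid, name)
  props <- setdiff(names(df), index_col)
  h5_set_attrs_at(fid, name, list(
    `encoding-type` = "dataframe", `encoding-version` = "0.2.0",
    `_index` = index_col, `column-order` = as.character(props)))
  write_col <- function(v, d) {
    is_log <- is.logical(v)
    if (is.factor(v)) v <- as.character(v)
    if (is_log) v <- as.integer(v)
    rhdf5::h5write(v, fid, d, variableLengthString = TRUE)
    attrs <- list(`encoding-version` = "0.2.0",
                  `encoding-type` = if (is.character(v)) "string-array" else "array")
    if (is_log) attrs[["scsql-logical"]] <- 1L
    h5_set_attrs_at(fid, d, attrs)
  }
  write_col(as.character(df[[index_col]]), paste0(name, "/", index_col))
  for (cn in props) write_col(df[[cn]], paste0(name, "/", cn))
}

write_h5_uns <- function(fid, name, uns) {
  rhdf5::h5createGroup(fid, name)
  h5_set_attrs_at(fid, name, list(`encoding-type` = "dict", `encoding-version` = "0.1.0"))
  for (nm in names(uns)) {
    v <- uns[[nm]]
    d <- paste0(name, "/", nm)
    if (is.list(v)) {
      write_h5_uns(fid, d, v)
    } else if (is.null(v)) {
      # no standard null encoding; store an empty float array
      rhdf5::h5write(numeric(0), fid, d)
      h5_set_attrs_at(fid, d, list(`scsql-null` = 1L))
    } else {
      scalar <- is.null(dim(v)) && length(v) == 1L
      is_log <- is.logical(v)
      out <- v
      if (is_log) out <- as.integer(out)
      if (is.matrix(out)) out <- t(out)
      rhdf5::h5write(out, fid, d, variableLengthString = TRUE)
      attrs <- list(`encoding-version` = "0.2.0",
                    `encoding-type` = if (is.character(v)) "string-array" else "array")
      if (scalar) attrs[["scsql-scalar"]] <- 1L
      if (is_log) attrs[["scsql-logical"]] <- 1L
      h5_set_attrs_at(fid, d, attrs)
    }
  }
}

h5_set_attrs_at <- function(fid, name, attrs) {
  obj <- tryCatch(rhdf5::H5Oopen(fid, name), error = function(e) NULL)
  if (is.null(obj)) return(invisible())
  h5_set_attrs(obj, attrs)
  rhdf5::H5Oclose(obj)
}

# Attributes named here are always arrays, even with one element.
H5_ARRAY_ATTRS <- c("column-order", "shape")

h5_set_attrs <- function(obj, attrs) {
  for (an in names(attrs)) {
    v <- attrs[[an]]
    if (is.null(v)) next
    if (length(v) == 0L) {
      # zero-length string-array attribute (e.g. column-order of a frame
      # with no value columns): creation succeeds, the no-op write errors,
      # and the library prints the HDF5 stack on the message stream
      invisible(utils::capture.output(
        try(rhdf5::h5writeAttribute(character(0), obj, an,
                                    variableLengthString = TRUE), silent = TRUE),
        type = "message"))
      next
    }
    rhdf5::h5writeAttribute(v, obj, an,
                            variableLengthString = is.character(v),
                            asScalar = length(v) == 1L && !an %in% H5_ARRAY_ATTRS)
  }
  invisible()
}
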