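# Database construction and connection management. The store is an embedded
# SQLite database (in-memory or a single ".asql" file); all layer tables are
# created from a planned schema and X is ingested in cell chunks so backed
# (streamed) sources never need to be materialized in full.

SCSQL_SCHEMA_VERSION <- "1"
# SQLite tables hold at most 2000 columns; X reserves cell_id + total_counts.
SCSQL_MAX_GENES <- 1998L

new_connection <- function(dbfile, read_only = FALSE) {
  flags <- if (read_only) RSQLite::SQLITE_RO else RSQLite::SQLITE_RWC
  con <- DBI::dbConnect(RSQLite::SQLite(), dbfile, flags = flags)
  RSQLite::initExtension(con, "math")
  if (!read_only) {
    DBI::dbExecute(con, "PRAGMA journal_mode=MEMORY")
    DBI::dbExecute(con, "PRAGMA synchronous=OFF")
  }
  con
}

new_handle <- function(con, location, mode) {
  h <- new.env(parent = emptyenv())
  h$con <- con
  h$location <- location
  h$mode <- mode
  h$open <- TRUE
  class(h) <- "scdb"
  h
}

#' @export
print.scdb <- function(x, ...) {
  cat("<scdb> ", x$location, " [", x$mode, if (!x$open) ", closed", "]\n", sep = "")
  invisible(x)
}

db_con <- function(db) {
  if (!inherits(db, "scdb")) abort_scsql("not a database handle", "stale_handle")
  if (!isTRUE(db$open)) abort_scsql("database handle is closed", "stale_handle")
  db$con
}

assert_writable <- function(db) {
  if (!identical(db$mode, "read-write")) {
    abort_scsql("database was opened read-only", "read_only")
  }
}

meta_set <- function(db, key, value) {
  con <- db_con(db)
  DBI::dbExecute(con, "INSERT OR REPLACE INTO _scsql_meta (key, value) VALUES (?, ?)",
                 params = list(key, as.character(value)))
}

meta_get <- function(db, key) {
  con <- db_con(db)
  r <- DBI::dbGetQuery(con, "SELECT value FROM _scsql_meta WHERE key = ?", params = list(key))
  if (nrow(r) == 0) NULL else r$value[[1]]
}

identifier_map <- function(db, table = NULL) {
  con <- db_con(db)
  sql <- "SELECT table_name, original, sanitized, ordinal FROM _scsql_identifier_map"
  if (!is.null(table)) {
    m <- DBI::dbGetQuery(con, paste(sql, "WHERE table_name = ? ORDER BY ordinal"),
                         params = list(table))
  } else {
    m <- DBI::dbGetQuery(con, paste(sql, "ORDER BY table_name, ordinal"))
  }
  tibble::as_tibble(m)
}

# Sanitized gene column names of X, in gene-ordinal order.
gene_columns <- function(db) identifier_map(db, "X")$sanitized

#' Plan a chunked pass over one axis of the expression matrix
#'
#' @param n axis length (number of cells or genes).
#' @param block_size positive block size; the last block may be short.
#' @param axis `"cells"` or `"genes"`.
#' @return a `chunk_plan`: list with `axis`, `block_size`, `n_blocks`, and
#'   `blocks` (list of index vectors covering `1:n` exactly once, in order).
#' @export
chunk_plan <- function(n, block_size, axis = c("cells", "genes")) {
  axis <- match.arg(axis)
  if (!is.numeric(block_size) || block_size < 1) {
    abort_scsql("block_size must be >= 1", "contract")
  }
  blocks <- split_blocks(as.integer(n), as.integer(block_size))
  structure(list(axis = axis, block_size = as.integer(block_size),
                 n_blocks = length(blocks), blocks = blocks),
            class = "chunk_plan")
}

#' Build a database from a layered single-cell object
#'
#' Creates an in-memory database or a single `.asql` file on disk holding
#' the selected layers of `source` as relational tables, plus the `adata`
#' convenience view joining `obs` and `X`. The expression matrix is ingested
#' in chunks of `chunk_size` cells, so a backed H5AD source (or any matrix
#' accessor) is streamed with peak memory proportional to
#' `chunk_size * n_genes` rather than to the full matrix.
#'
#' @param source an [sc_bundle()], or a path to an `.h5ad` file (opened in
#'   backed mode and streamed).
#' @param db_name database name (used as `<db_name>.asql`); required for
#'   on-disk databases.
#' @param db_path directory for the database file, or `NULL` (default) for
#'   an in-memory database.
#' @param layers layers to materialize (see [plan_schema()]).
#' @param chunk_size cells per ingestion block (default 5000).
#' @param convenience_view create the `adata` view (default `TRUE`).
#' @param overwrite replace an existing database file (default `FALSE`;
#'   refuses otherwise).
#' @return a database handle (class `scdb`).
#' @export
make_db <- function(source, db_name = NULL, db_path = NULL,
                    layers = c("X", "obs", "var", "var_names", "obsm",
                               "varm", "obsp", "uns"),
                    chunk_size = 5000, convenience_view = TRUE,
                    overwrite = FALSE) {
  if (is.character(source)) {
    if (!file.exists(source)) {
      abort_scsql(paste0("source file not found: ", source), "io")
    }
    source <- read_h5ad(source, backed = TRUE)
  }
  stopifnot(inherits(source, "sc_bundle"))
  if (chunk_size < 1) abort_scsql("chunk_size must be >= 1", "contract")
  if (source$X$n_genes > SCSQL_MAX_GENES) {
    abort_scsql(paste0("the wide X table supports at most ", SCSQL_MAX_GENES,
                       " genes per database (engine column limit)"), "capacity")
  }

  if (is.null(db_path)) {
    dbfile <- ":memory:"
    location <- "in-memory"
  } else {
    if (is.null(db_name) || !nzchar(db_name)) {
      abort_scsql("db_name must be a non-empty string", "contract")
    }
    dbfile <- file.path(db_path, paste0(db_name, ".asql"))
    if (file.exists(dbfile)) {
      if (!overwrite) {
        abort_scsql(paste0("database exists: ", dbfile,
                           " (set overwrite = TRUE to replace)"), "exists")
      }
      unlink(dbfile)
    }
    location <- dbfile
  }

  db <- new_handle(new_connection(dbfile), location, "read-write")
  plan <- plan_schema(source, layers)
  con <- db_con(db)

  DBI::dbExecute(con, "CREATE TABLE _scsql_meta (key TEXT PRIMARY KEY, value TEXT)")
  DBI::dbExecute(con,
    "CREATE TABLE _scsql_identifier_map (table_name TEXT, original TEXT, sanitized TEXT, ordinal INTEGER)")
  DBI::dbExecute(con,
    "CREATE TABLE _scsql_coltypes (table_name TEXT, column TEXT, class TEXT)")
  if (nrow(plan$identifier_map)) {
    DBI::dbAppendTable(con, "_scsql_identifier_map", as.data.frame(plan$identifier_map))
  }

  for (sc in plan$schemas) {
    ddl <- paste0("CREATE TABLE ", qid(sc$table_name), " (",
                  paste(qid(sc$columns$name), sc$columns$type, collapse = ", "), ")")
    DBI::dbExecute(con, ddl)
  }

  meta_set(db, "schema_version", SCSQL_SCHEMA_VERSION)
  meta_set(db, "n_cells", source$X$n_cells)
  meta_set(db, "n_genes", source$X$n_genes)
  meta_set(db, "convenience_view", if (convenience_view) "1" else "0")
  meta_set(db, "x_mutated_since_total_counts", "0")

  insert_x_chunked(db, source$X,
                   chunk_plan(source$X$n_cells, chunk_size, "cells"),
                   cell_ids = source$obs$cell_id)

  if (!is.null(plan$schemas$obs)) {
    obs_df <- as.data.frame(source$obs)
    props <- setdiff(names(obs_df), "cell_id")
    record_coltypes(db, "obs", obs_df[props], plan$identifier_map)
    names(obs_df) <- c("cell_id", identifier_map(db, "obs")$sanitized)[
      match(names(obs_df), c("cell_id", props))]
    DBI::dbAppendTable(con, "obs", coerce_for_db(obs_df))
  }
  if (!is.null(plan$schemas$var)) {
    pm <- identifier_map(db, "var")
    props <- pm$original
    var_df <- data.frame(id = seq_len(nrow(source$var)) - 1L,
                         gene = source$var$gene, check.names = FALSE)
    if (length(props)) {
      record_coltypes(db, "var", as.data.frame(source$var)[props], plan$identifier_map)
      extra <- as.data.frame(source$var)[props]
      names(extra) <- pm$sanitized
      var_df <- cbind(var_df, extra)
    }
    DBI::dbAppendTable(con, "var", coerce_for_db(var_df))
  }
  if ("obsm" %in% layers) {
    for (prop in names(source$obsm)) {
      tab <- paste0("obsm_", sanitize_identifier(prop))
      m <- as.matrix(source$obsm[[prop]])
      df <- as.data.frame(m)
      names(df) <- identifier_map(db, tab)$sanitized
      DBI::dbAppendTable(con, tab, cbind(cell_id = source$obs$cell_id, df))
    }
  }
  if ("varm" %in% layers) {
    for (prop in names(source$varm)) {
      tab <- paste0("varm_", sanitize_identifier(prop))
      m <- as.matrix(source$varm[[prop]])
      df <- as.data.frame(m)
      names(df) <- identifier_map(db, tab)$sanitized
      DBI::dbAppendTable(con, tab, cbind(id = seq_len(nrow(m)) - 1L, df))
    }
  }
  if ("obsp" %in% layers) {
    for (prop in names(source$obsp)) {
      tab <- paste0("obsp_", sanitize_identifier(prop))
      m <- source$obsp[[prop]]
      trip <- if (inherits(m, "sparseMatrix")) {
        s <- Matrix::summary(methods::as(m, "TsparseMatrix"))
        data.frame(row_id = s$i - 1L, col_id = s$j - 1L, value = s$x)
      } else {
        idx <- which(m != 0, arr.ind = TRUE)
        data.frame(row_id = idx[, 1] - 1L, col_id = idx[, 2] - 1L, value = m[idx])
      }
      trip <- trip[order(trip$row_id, trip$col_id), , drop = FALSE]
      DBI::dbAppendTable(con, tab, trip)
    }
  }
  if ("uns" %in% layers) {
    payload <- build_uns_payload(source$uns)
    if (nrow(payload)) DBI::dbAppendTable(con, "uns_raw", as.data.frame(payload))
  }

  if (convenience_view && !is.null(plan$schemas$obs)) create_convenience_view(db)
  db
}

record_coltypes <- function(db, table, df, map) {
  if (!length(df)) return(invisible())
  m <- map[map$table_name == table, ]
  cls <- vapply(df, function(x) class(x)[[1]], character(1))
  DBI::dbAppendTable(db_con(db), "_scsql_coltypes",
                     data.frame(table_name = table,
                                column = m$sanitized[match(names(df), m$original)],
                                class = unname(cls)))
}

coerce_for_db <- function(df) {
  for (i in seq_along(df)) {
    if (is.factor(df[[i]])) df[[i]] <- as.character(df[[i]])
    if (is.logical(df[[i]])) df[[i]] <- as.integer(df[[i]])
  }
  df
}

#' Ingest the expression matrix in cell chunks
#'
#' Streams cell blocks from a matrix accessor into the pre-created `X`
#' table, one transaction per block. Values are stored in the FLOAT-typed
#' gene columns; cell order is preserved. A failure mid-ingestion leaves a
#' detectably incomplete database (row count below the recorded cell count)
#' and reports the failed block.
#'
#' @param db database handle whose `X` table exists.
#' @param source an `sc_matrix_accessor`.
#' @param plan a [chunk_plan()] over cells.
#' @param cell_ids character vector of cell barcodes (defaults to the
#'   accessor's row names, then `cell_<i>`).
#' @return number of rows inserted (= number of cells).
#' @export
insert_x_chunked <- function(db, source, plan, cell_ids = NULL) {
  con <- db_con(db)
  assert_writable(db)
  if (!"X" %in% DBI::dbListTables(con)) {
    abort_scsql("table 'X' does not exist; create the schema first", "missing_table")
  }
  cols <- gene_columns(db)
  if (is.null(cell_ids)) {
    cell_ids <- source$row_names %||% make_ids("cell_", source$n_cells)
  }
  inserted <- 0L
  for (bi in seq_along(plan$blocks)) {
    rows <- plan$blocks[[bi]]
    tryCatch({
      block <- source$fetch(rows)
      df <- as.data.frame(block)
      names(df) <- cols
      df <- cbind(cell_id = cell_ids[rows], df)
      DBI::dbWithTransaction(con, {
        DBI::dbAppendTable(con, "X", df)
      })
      inserted <- inserted + length(rows)
    }, error = function(e) {
      abort_scsql(paste0("ingestion failed at block ", bi, " of ", plan$n_blocks,
                         ": ", conditionMessage(e)),
                  "ingestion", block = bi)
    })
  }
  inserted
}

#' Check that X ingestion completed
#'
#' Compares the row count of `X` against the cell count recorded when the
#' schema was created; a mismatch indicates an interrupted ingestion.
#' @param db database handle.
#' @return logical scalar.
#' @export
db_ingestion_complete <- function(db) {
  con <- db_con(db)
  n_expected <- as.integer(meta_get(db, "n_cells"))
  n_actual <- DBI::dbGetQuery(con, "SELECT COUNT(*) AS n FROM X")$n
  identical(as.integer(n_actual), n_expected)
}

#' Open an existing database
#'
#' @param path path to a previously built `.asql` file.
#' @param mode `"read-write"` (default) or `"read-only"`.
#' @return a database handle exposing the tables that existed at build time.
#' @export
open_database <- function(path, mode = c("read-write", "read-only")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) {
    abort_scsql(paste0("database file not found: ", path), "not_found")
  }
  if (!grepl("\\.asql$", path)) {
    rlang::warn(paste0("file does not have the .asql extension: ", path))
  }
  new_handle(new_connection(path, read_only = mode == "read-only"), path, mode)
}

#' Close a database handle
#' @param db database handle.
#' @return `NULL`, invisibly.
#' @export
close_database <- function(db) {
  if (inherits(db, "scdb") && isTRUE(db$open)) {
    DBI::dbDisconnect(db$con)
    db$open <- FALSE
  }
  invisible(NULL)
}

#' List user-visible tables and views
#'
#' Internal bookkeeping tables are hidden; everything else — layer tables,
#' result tables such as `PC_scores`, the `adata` view, and any table the
#' user created through [query_raw()] — is listed in creation order.
#' @param db database handle.
#' @return character vector of table/view names.
#' @export
list_tables <- function(db) {
  con <- db_con(db)
  r <- DBI::dbGetQuery(con,
    "SELECT name FROM sqlite_master WHERE type IN ('table','view')
     AND name NOT LIKE '\\_scsql\\_%' ESCAPE '\\' AND name NOT LIKE 'sqlite\\_%' ESCAPE '\\'")
  r$name
}

#' Reconstruct a bundle from a database
#'
#' Inverse of [make_db()]: reads the layer tables back into an
#' [sc_bundle()], restoring original column and gene names through the
#' persisted identifier map and original column classes (integer, double,
#' logical, character) through recorded column types. Factors are stored as
#' text and come back as character.
#'
#' @param db database handle.
#' @return an [sc_bundle()].
#' @export
db_to_bundle <- function(db) {
  con <- db_con(db)
  tabs <- DBI::dbListTables(con)
  gm <- identifier_map(db, "X")
  sel <- paste(c(qid("cell_id"), qid(gm$sanitized)), collapse = ", ")
  xdf <- DBI::dbGetQuery(con, paste0("SELECT ", sel, " FROM X ORDER BY rowid"))
  X <- as.matrix(xdf[, -1, drop = FALSE])
  colnames(X) <- gm$original
  rownames(X) <- xdf$cell_id

  obs <- NULL
  if ("obs" %in% tabs) {
    obs <- tibble::as_tibble(DBI::dbGetQuery(con, "SELECT * FROM obs ORDER BY rowid"))
    obs <- restore_columns(db, "obs", obs, key_cols = "cell_id")
  }
  var <- NULL
  if ("var" %in% tabs) {
    var <- tibble::as_tibble(DBI::dbGetQuery(con, "SELECT * FROM var ORDER BY id"))
    var$id <- NULL
    var <- restore_columns(db, "var", var, key_cols = "gene")
  }

  read_wide <- function(tab, key) {
    m <- identifier_map(db, tab)
    d <- DBI::dbGetQuery(con, paste0("SELECT * FROM ", qid(tab), " ORDER BY rowid"))
    mat <- as.matrix(d[, setdiff(names(d), key), drop = FALSE])
    colnames(mat) <- m$original[match(colnames(mat), m$sanitized)]
    mat
  }
  obsm <- varm <- obsp <- list()
  for (tab in grep("^obsm_", tabs, value = TRUE)) {
    obsm[[sub("^obsm_", "", tab)]] <- read_wide(tab, "cell_id")
  }
  for (tab in grep("^varm_", tabs, value = TRUE)) {
    varm[[sub("^varm_", "", tab)]] <- read_wide(tab, "id")
  }
  n <- nrow(X)
  for (tab in grep("^obsp_", tabs, value = TRUE)) {
    d <- DBI::dbGetQuery(con, paste0("SELECT row_id, col_id, value FROM ", qid(tab)))
    obsp[[sub("^obsp_", "", tab)]] <- Matrix::sparseMatrix(
      i = d$row_id + 1L, j = d$col_id + 1L, x = d$value, dims = c(n, n))
  }
  uns <- list()
  if ("uns_raw" %in% tabs) {
    uns <- reconstruct_uns(tibble::as_tibble(
      DBI::dbGetQuery(con, "SELECT key, value, data_type FROM uns_raw ORDER BY rowid")))
  }
  sc_bundle(X, obs = obs, var = var, obsm = obsm, varm = varm,
            obsp = obsp, uns = uns)
}

# Restore original column names and R classes for obs/var reads.
restore_columns <- function(db, table, df, key_cols) {
  m <- identifier_map(db, table)
  ct <- DBI::dbGetQuery(db_con(db),
    "SELECT column, class FROM _scsql_coltypes WHERE table_name = ?", params = list(table))
  for (j in setdiff(names(df), key_cols)) {
    cls <- ct$class[match(j, ct$column)]
    if (!is.na(cls) && cls == "logical") df[[j]] <- as.logical(df[[j]])
    if (!is.na(cls) && cls == "integer") df[[j]] <- as.integer(df[[j]])
    if (!is.na(cls) && cls == "numeric") df[[j]] <- as.double(df[[j]])
  }
  hit <- match(names(df), m$sanitized)
  names(df)[!is.na(hit)] <- m$original[hit[!is.na(hit)]]
  df
}
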