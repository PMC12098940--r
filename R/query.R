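# The user-facing query surface. query() is SELECT-only and supports three
# return contracts (tibble, annotated matrix, Parquet); query_raw() executes
# any statement verbatim; update_query()/delete_query() are the guarded
# mutation paths. Queries may use original gene/column names — they are
# rewritten to their sanitized database identifiers before execution.

#' Run a read-only SQL query
#'
#' Executes a single `SELECT` (or `WITH ... SELECT`) statement and returns
#' the result in one of three forms: a tibble (default), an annotated
#' matrix (an [sc_bundle()] whose `X` holds the numeric result columns and
#' whose `obs` holds `cell_id` plus non-numeric columns), or a Parquet file.
#' Original (unsanitized) gene and column names may be used; they are
#' rewritten through the persisted identifier map. Row order is unspecified
#' unless the statement has an `ORDER BY`.
#'
#' @param db database handle.
#' @param sql a single SELECT statement.
#' @param return_mode `"frame"`, `"annotated_matrix"`, or `"parquet"`.
#' @param parquet_path destination for `return_mode = "parquet"` (defaults
#'   to a file in `tempdir()`).
#' @return tibble, [sc_bundle()], or the path of the written Parquet file.
#' @examples
#' \dontrun{
#' query(db, "SELECT ENSMUSG00000070880 FROM X WHERE ENSMUSG00000070880 > 0")
#' }
#' @export
query <- function(db, sql, return_mode = c("frame", "annotated_matrix", "parquet"),
                  parquet_path = NULL) {
  return_mode <- match.arg(return_mode)
  con <- db_con(db)
  if (!is_select_statement(sql)) {
    abort_scsql(
      "query() accepts a single SELECT statement; use query_raw(), update_query() or delete_query() for mutations",
      "not_select")
  }
  rewritten <- rewrite_identifiers(db, sql)
  res <- tryCatch(
    tibble::as_tibble(DBI::dbGetQuery(con, rewritten)),
    error = function(e) rethrow_with_names(db, e, sql)
  )
  switch(return_mode,
    frame = res,
    annotated_matrix = to_annotated_matrix(res, db = db),
    parquet = {
      path <- parquet_path %||% tempfile(fileext = ".parquet")
      arrow::write_parquet(res, path)
      path
    })
}

#' Execute a SQL statement verbatim
#'
#' No guarding, no identifier rewriting: the statement runs as given,
#' including DDL and DML. Statements that return rows yield a tibble;
#' others return the number of affected rows.
#'
#' @param db database handle.
#' @param sql any SQL statement.
#' @return tibble (row-returning statements) or affected-row count.
#' @export
query_raw <- function(db, sql) {
  con <- db_con(db)
  tryCatch({
    is_pragma_set <- grepl("^\\s*pragma\\s+[A-Za-z_.]+\\s*=", sql, ignore.case = TRUE)
    if (!is_pragma_set &&
        (is_select_statement(sql) || grepl("^\\s*(pragma|explain)", sql, ignore.case = TRUE))) {
      tibble::as_tibble(DBI::dbGetQuery(con, sql))
    } else {
      DBI::dbExecute(con, sql)
    }
  }, error = function(e) {
    rlang::abort(paste0(conditionMessage(e), "\nstatement: ", sql),
                 class = c("scsql_error_engine", "scsql_error"))
  })
}

#' Update rows of a table
#'
#' @param db read-write database handle.
#' @param table target table.
#' @param set assignment fragment, e.g. `"g1 = 0"` (original names allowed).
#' @param where predicate fragment (without the `WHERE`); `NULL` updates all
#'   rows. A predicate matching nothing returns 0, not an error.
#' @return number of affected rows.
#' @export
update_query <- function(db, table, set, where = NULL) {
  con <- db_con(db)
  assert_writable(db)
  sql <- paste0("UPDATE ", qid(table), " SET ", rewrite_identifiers(db, set))
  if (!is.null(where)) sql <- paste0(sql, " WHERE ", rewrite_identifiers(db, where))
  n <- tryCatch(DBI::dbExecute(con, sql), error = function(e) rethrow_with_names(db, e, sql))
  if (table == "X") mark_x_mutated(db)
  n
}

#' Delete rows of a table
#'
#' @inheritParams update_query
#' @return number of deleted rows.
#' @export
delete_query <- function(db, table, where = NULL) {
  con <- db_con(db)
  assert_writable(db)
  sql <- paste0("DELETE FROM ", qid(table))
  if (!is.null(where)) sql <- paste0(sql, " WHERE ", rewrite_identifiers(db, where))
  n <- tryCatch(DBI::dbExecute(con, sql), error = function(e) rethrow_with_names(db, e, sql))
  if (table == "X") mark_x_mutated(db)
  n
}

mark_x_mutated <- function(db) {
  if ("_scsql_meta" %in% DBI::dbListTables(db_con(db))) {
    meta_set(db, "x_mutated_since_total_counts", "1")
  }
}

#' Convert a query result to an annotated matrix
#'
#' Partitions result columns by type: numeric columns become the `X` matrix
#' (cells x selected features), `cell_id` plus any non-numeric columns
#' become `obs`. When the database handle is supplied, sanitized gene
#' columns are renamed back to their original names.
#'
#' @param result tibble with a `cell_id` column.
#' @param db optional database handle used to restore original gene names.
#' @return an [sc_bundle()].
#' @export
to_annotated_matrix <- function(result, db = NULL) {
  if (!"cell_id" %in% names(result)) {
    abort_scsql("annotated-matrix results require a cell_id column", "contract")
  }
  numeric_cols <- names(result)[vapply(result, is.numeric, logical(1))]
  other_cols <- setdiff(names(result), c(numeric_cols, "cell_id"))
  X <- as.matrix(result[numeric_cols])
  if (!is.null(db)) {
    m <- identifier_map(db)
    hit <- match(colnames(X), m$sanitized[m$table_name == "X"])
    orig <- m$original[m$table_name == "X"]
    colnames(X)[!is.na(hit)] <- orig[hit[!is.na(hit)]]
  }
  rownames(X) <- result$cell_id
  sc_bundle(X, obs = result[c("cell_id", other_cols)])
}

#' Show engine settings
#'
#' Stable key/value listing of the embedded engine's configuration (page
#' cache limit, page size, journal and synchronous modes, memory-map size,
#' engine version). Values are read live, so settings changed through
#' [query_raw()] (e.g. `PRAGMA cache_size = ...`) are reflected.
#'
#' @param db database handle.
#' @return tibble with columns `setting` and `value`.
#' @export
show_settings <- function(db) {
  con <- db_con(db)
  pragma <- function(p) as.character(DBI::dbGetQuery(con, paste0("PRAGMA ", p))[[1]][1])
  cache_pages <- as.numeric(pragma("cache_size"))
  page_size <- as.numeric(pragma("page_size"))
  cache_bytes <- if (cache_pages < 0) -cache_pages * 1024 else cache_pages * page_size
  tibble::tibble(
    setting = c("memory_limit_bytes", "cache_size", "page_size", "journal_mode",
                "synchronous", "mmap_size", "threads", "engine_version"),
    value = c(format(cache_bytes, scientific = FALSE), pragma("cache_size"),
              pragma("page_size"), pragma("journal_mode"), pragma("synchronous"),
              pragma("mmap_size"), pragma("threads"),
              as.character(DBI::dbGetQuery(con, "SELECT sqlite_version() v")$v))
  )
}

#' Alias for [list_tables()]
#' @inheritParams list_tables
#' @return character vector of table/view names.
#' @export
show_tables <- function(db) list_tables(db)

# ---- internals -------------------------------------------------------------

is_select_statement <- function(sql) {
  stripped <- gsub("^(\\s|--[^\n]*\n|/\\*.*?\\*/)+", "", sql, perl = TRUE)
  grepl("^(select|with)\\b", stripped, ignore.case = TRUE)
}

# Rewrite original layer/gene names to their sanitized identifiers. Only
# names that changed during sanitization are touched; matches are taken on
# word-ish boundaries and inside double quotes, longest names first.
rewrite_identifiers <- function(db, sql) {
  m <- identifier_map(db)
  m <- m[m$original != m$sanitized, , drop = FALSE]
  if (nrow(m) == 0) return(sql)
  m <- m[order(-nchar(m$original)), ]
  for (i in seq_len(nrow(m))) {
    orig <- m$original[i]
    repl <- qid(m$sanitized[i])
    quoted <- paste0('"', gsub('"', '""', orig, fixed = TRUE), '"')
    sql <- gsub(quoted, repl, sql, fixed = TRUE)
    pat <- paste0("(?<![A-Za-z0-9_\"])", escape_regex(orig), "(?![A-Za-z0-9_\"])")
    sql <- gsub(pat, repl, sql, perl = TRUE)
  }
  sql
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.-])", "\\\\\\1", x)

rethrow_with_names <- function(db, e, sql) {
  msg <- conditionMessage(e)
  bad <- regmatches(msg, regexec("no such column: ([A-Za-z0-9_.]+)", msg))[[1]]
  if (length(bad) == 2) {
    m <- identifier_map(db)
    orig <- m$original[m$sanitized == bad[2]]
    hint <- if (length(orig)) paste0(" (original name: '", orig[1], "')") else ""
    abort_scsql(paste0("unknown column '", bad[2], "'", hint, "\nstatement: ", sql),
                "unknown_column")
  }
  rlang::abort(paste0(msg, "\nstatement: ", sql),
               class = c("scsql_error_engine", "scsql_error"))
}
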