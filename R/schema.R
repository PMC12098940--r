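#' Plan the relational schema for a layered single-cell bundle
#'
#' Maps each selected layer of a bundle onto table layouts before any DDL is
#' issued: `X` becomes a wide table with a `cell_id` column plus one FLOAT
#' column per (sanitized) gene; `obs` one column per per-cell property;
#' `var` an auto-incremented 0-based `id` (the gene ordinal), the gene name,
#' and one column per per-gene property; each `obsm`/`varm` property its own
#' `<layer>_<property>` table; each `obsp` property an edge-list table
#' `(row_id, col_id, value)`; and `uns` a key/value/data_type table
#' `uns_raw`. Gene names are stored as a column of `var` (there is no
#' separate var_names table).
#'
#' @param bundle an [sc_bundle()].
#' @param layers character vector of layers to include, a subset of
#'   `c("X","obs","var","var_names","obsm","varm","obsp","uns")`. `X` is
#'   always included.
#' @return a list with `schemas` (named list; each element has `table_name`,
#'   `columns` = tibble(name, type), `provenance`) and `identifier_map`
#'   (tibble with table_name, original, sanitized, ordinal).
#' @export
plan_schema <- function(bundle, layers = c("X", "obs", "var", "var_names",
                                           "obsm", "varm", "obsp", "uns")) {
  stopifnot(inherits(bundle, "sc_bundle"))
  layers <- union("X", layers)
  unknown <- setdiff(layers, c("X", "obs", "var", "var_names", "obsm", "varm", "obsp", "uns"))
  if (length(unknown)) {
    abort_scsql(paste0("unknown layers: ", paste(unknown, collapse = ", ")), "invalid_identifier")
  }
  n <- bundle$X$n_cells
  p <- bundle$X$n_genes
  if (nrow(bundle$obs) != n || nrow(bundle$var) != p) {
    abort_scsql("bundle dimensions are inconsistent", "inconsistent_bundle")
  }

  schemas <- list()
  maps <- list()

  gene_map <- sanitize_names(bundle$var$gene, "X")
  maps$X <- gene_map
  schemas$X <- list(
    table_name = "X",
    columns = tibble::tibble(
      name = c("cell_id", gene_map$sanitized),
      type = c("TEXT", rep("FLOAT", p))
    ),
    provenance = "X"
  )

  if ("obs" %in% layers) {
    props <- setdiff(names(bundle$obs), "cell_id")
    pm <- sanitize_names(props, "obs")
    maps$obs <- pm
    schemas$obs <- list(
      table_name = "obs",
      columns = tibble::tibble(
        name = c("cell_id", pm$sanitized),
        type = c("TEXT", vapply(bundle$obs[props], sql_type_of, character(1)))
      ),
      provenance = "obs"
    )
  }
  if (any(c("var", "var_names") %in% layers)) {
    props <- if ("var" %in% layers) setdiff(names(bundle$var), "gene") else character(0)
    pm <- sanitize_names(props, "var")
    maps$var <- pm
    schemas$var <- list(
      table_name = "var",
      columns = tibble::tibble(
        name = c("id", "gene", pm$sanitized),
        type = c("INTEGER", "TEXT", vapply(bundle$var[props], sql_type_of, character(1)))
      ),
      provenance = "var"
    )
  }
  if ("obsm" %in% layers) {
    for (prop in names(bundle$obsm)) {
      tab <- paste0("obsm_", sanitize_identifier(prop))
      m <- bundle$obsm[[prop]]
      cols <- matrix_col_names(m, tab)
      maps[[tab]] <- cols$map
      schemas[[tab]] <- list(
        table_name = tab,
        columns = tibble::tibble(name = c("cell_id", cols$names),
                                 type = c("TEXT", rep("FLOAT", length(cols$names)))),
        provenance = paste0("obsm/", prop)
      )
    }
  }
  if ("varm" %in% layers) {
    for (prop in names(bundle$varm)) {
      tab <- paste0("varm_", sanitize_identifier(prop))
      m <- bundle$varm[[prop]]
      cols <- matrix_col_names(m, tab)
      maps[[tab]] <- cols$map
      schemas[[tab]] <- list(
        table_name = tab,
        columns = tibble::tibble(name = c("id", cols$names),
                                 type = c("INTEGER", rep("FLOAT", length(cols$names)))),
        provenance = paste0("varm/", prop)
      )
    }
  }
  if ("obsp" %in% layers) {
    for (prop in names(bundle$obsp)) {
      tab <- paste0("obsp_", sanitize_identifier(prop))
      schemas[[tab]] <- list(
        table_name = tab,
        columns = tibble::tibble(name = c("row_id", "col_id", "value"),
                                 type = c("INTEGER", "INTEGER", "FLOAT")),
        provenance = paste0("obsp/", prop)
      )
    }
  }
  if ("uns" %in% layers) {
    schemas$uns_raw <- list(
      table_name = "uns_raw",
      columns = tibble::tibble(name = c("key", "value", "data_type"),
                               type = c("TEXT", "TEXT", "TEXT")),
      provenance = "uns"
    )
  }

  list(schemas = schemas, identifier_map = dplyr::bind_rows(maps))
}

sql_type_of <- function(x) {
  if (is.integer(x) || is.logical(x)) "INTEGER"
  else if (is.numeric(x)) "FLOAT"
  else "TEXT"
}

matrix_col_names <- function(m, table_name) {
  d <- ncol(m)
  raw <- colnames(m) %||% paste0("v", seq_len(d))
  map <- sanitize_names(raw, table_name)
  list(names = map$sanitized, map = map)
}

# ---- uns serialization -----------------------------------------------------

#' Serialize unstructured metadata to key/value/data_type rows
#'
#' Each top-level key of the `uns` layer becomes one row holding a
#' self-describing text encoding of the value plus a `data_type` tag from
#' `{string, int, float, bool, array, mapping, null}`, sufficient to
#' reconstruct the original value exactly (including integer-vs-double
#' distinction and array dimensions). The inverse is [reconstruct_uns()].
#'
#' @param uns named list of scalars, atomic vectors/arrays, or nested named
#'   lists.
#' @return tibble with columns `key`, `value` (serialized text), `data_type`.
#' @export
build_uns_payload <- function(uns) {
  if (length(uns) == 0) {
    return(tibble::tibble(key = character(), value = character(), data_type = character()))
  }
  if (is.null(names(uns)) || any(!nzchar(names(uns)))) {
    abort_scsql("uns must be a named list", "serialization")
  }
  rows <- purrr::imap(uns, function(v, k) {
    tag <- tryCatch(encode_uns(v), error = function(e) {
      abort_scsql(paste0("uns value '", k, "' is not serializable: ",
                         conditionMessage(e)), "serialization")
    })
    tibble::tibble(
      key = k,
      value = as.character(jsonlite::toJSON(tag$value, auto_unbox = FALSE,
                                            digits = NA, null = "null")),
      data_type = tag$type
    )
  })
  dplyr::bind_rows(rows)
}

#' Reconstruct unstructured metadata from its serialized rows
#'
#' @param payload tibble as produced by [build_uns_payload()] (or read back
#'   from the `uns_raw` table).
#' @return the original named list, deep-equal to the serialized input.
#' @export
reconstruct_uns <- function(payload) {
  if (nrow(payload) == 0) return(list())
  vals <- purrr::map2(payload$value, payload$data_type, function(v, t) {
    decode_uns(list(type = t, value = jsonlite::fromJSON(v, simplifyVector = FALSE)))
  })
  rlang::set_names(vals, payload$key)
}

# Encode a value as list(type = tag, value = JSON-able structure).
encode_uns <- function(v) {
  if (is.null(v)) return(list(type = "null", value = NULL))
  if (is.list(v)) {
    if (is.null(names(v)) && length(v) > 0) stop("unnamed lists are not supported")
    inner <- purrr::map(v, encode_uns)
    return(list(type = "mapping", value = inner))
  }
  if (!is.atomic(v)) stop("unsupported class: ", paste(class(v), collapse = "/"))
  if (!is.null(dim(v)) || length(v) != 1L) {
    kind <- if (is.logical(v)) "bool" else if (is.integer(v)) "int"
            else if (is.double(v)) "float" else if (is.character(v)) "string"
            else stop("unsupported array mode: ", typeof(v))
    return(list(type = "array",
                value = list(kind = kind,
                             dim = if (is.null(dim(v))) NULL else as.integer(dim(v)),
                             data = as.vector(v))))
  }
  if (is.logical(v)) list(type = "bool", value = v)
  else if (is.integer(v)) list(type = "int", value = v)
  else if (is.double(v)) list(type = "float", value = v)
  else if (is.character(v)) list(type = "string", value = v)
  else stop("unsupported scalar mode: ", typeof(v))
}

decode_uns <- function(tag) {
  # the type tag arrives as a bare string from the table but as a length-1
  # JSON array from nested mappings; normalize before dispatch
  type <- as.character(unlist(tag[["type"]]))[1]
  v <- tag[["value"]]
  switch(type,
    null = NULL,
    bool = as.logical(v[[1]]),
    int = as.integer(v[[1]]),
    float = as.double(v[[1]]),
    string = as.character(v[[1]]),
    array = {
      kind <- v$kind[[1]]
      data <- unlist(v$data, use.names = FALSE)
      data <- switch(kind,
        bool = as.logical(data), int = as.integer(data),
        float = as.double(data), string = as.character(data))
      if (!is.null(v$dim)) array(data, dim = unlist(v$dim, use.names = FALSE)) else data
    },
    mapping = purrr::map(v, decode_uns),
    abort_scsql(paste0("unknown data_type tag: ", type), "serialization")
  )
}

#' Create (or refresh) the convenience view joining obs and X
#'
#' The view `adata` joins the per-cell annotation table and the wide
#' expression table on `cell_id`, so annotations and expression are
#' queryable together. It is a plain SQL view over the base tables: updates
#' and deletes on `X` or `obs` are reflected immediately.
#'
#' @param db a database handle from [make_db()] or [open_database()].
#' @return the handle, invisibly.
#' @export
create_convenience_view <- function(db) {
  con <- db_con(db)
  tabs <- DBI::dbListTables(con)
  missing <- setdiff(c("X", "obs"), tabs)
  if (length(missing)) {
    abort_scsql(paste0("cannot create view 'adata': missing table(s) ",
                       paste(missing, collapse = ", ")), "missing_table")
  }
  DBI::dbExecute(con, "DROP VIEW IF EXISTS adata")
  DBI::dbExecute(con, "CREATE VIEW adata AS SELECT * FROM obs JOIN X USING (cell_id)")
  invisible(db)
}
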