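# Chunked in-database preprocessing. Every operation works through SQL on
# the wide X table, iterating cells in rowid blocks and genes in batches of
# columns, so peak memory stays proportional to one block regardless of the
# dataset size. Long arithmetic over many columns is split into batches to
# stay within the engine's expression-depth limit.

GENE_BATCH <- 300L

has_column <- function(db, table, column) {
  info <- DBI::dbGetQuery(db_con(db), paste0("PRAGMA table_info(", qid(table), ")"))
  column %in% info$name
}

ensure_column <- function(db, table, column, type) {
  if (!has_column(db, table, column)) {
    DBI::dbExecute(db_con(db), paste0("ALTER TABLE ", qid(table),
                                      " ADD COLUMN ", qid(column), " ", type))
  }
}

require_table <- function(db, table) {
  if (!table %in% DBI::dbListTables(db_con(db))) {
    abort_scsql(paste0("table '", table, "' does not exist"), "missing_table")
  }
}

refresh_view <- function(db) {
  tabs <- DBI::dbListTables(db_con(db))
  if (identical(meta_get(db, "convenience_view"), "1") && all(c("X", "obs") %in% tabs)) {
    create_convenience_view(db)
  }
}

# Consecutive rowid ranges covering X in insertion order, as a list of
# c(lo, hi) pairs of at most chunk_size rows each.
x_rowid_ranges <- function(db, chunk_size) {
  rid <- DBI::dbGetQuery(db_con(db), "SELECT rowid AS r FROM X ORDER BY rowid")$r
  lapply(split_blocks(length(rid), as.integer(chunk_size)),
         function(ix) c(rid[ix[1]], rid[ix[length(ix)]]))
}

read_x_block <- function(db, cols, range = NULL) {
  sel <- paste(qid(cols), collapse = ", ")
  sql <- paste0("SELECT ", sel, " FROM X")
  if (!is.null(range)) sql <- paste0(sql, " WHERE rowid BETWEEN ", range[1], " AND ", range[2])
  sql <- paste0(sql, " ORDER BY rowid")
  as.matrix(DBI::dbGetQuery(db_con(db), sql))
}

#' Compute per-cell total counts
#'
#' Iterates cells in chunks and writes each cell's sum over all gene
#' columns into a `total_counts` column on `X` and then on `obs` (the basis
#' of library-size normalization). Recomputing overwrites the previous
#' values and clears the staleness flag used by [expression_normalize()].
#'
#' @param db read-write database handle.
#' @param chunk_size cells per update block (default 5000).
#' @return tibble with `cell_id` and `total_counts`.
#' @export
calculate_total_counts <- function(db, chunk_size = 5000) {
  con <- db_con(db)
  assert_writable(db)
  require_table(db, "X")
  genes <- gene_columns(db)
  ensure_column(db, "X", "total_counts", "FLOAT")
  DBI::dbExecute(con, "UPDATE X SET total_counts = 0")
  batches <- split_blocks(length(genes), GENE_BATCH)
  for (range in x_rowid_ranges(db, chunk_size)) {
    for (b in batches) {
      expr <- paste(qid(genes[b]), collapse = " + ")
      DBI::dbExecute(con, paste0(
        "UPDATE X SET total_counts = total_counts + (", expr,
        ") WHERE rowid BETWEEN ", range[1], " AND ", range[2]))
    }
  }
  if ("obs" %in% DBI::dbListTables(con)) {
    ensure_column(db, "obs", "total_counts", "FLOAT")
    DBI::dbExecute(con,
      "UPDATE obs SET total_counts = (SELECT X.total_counts FROM X WHERE X.cell_id = obs.cell_id)")
  }
  meta_set(db, "x_mutated_since_total_counts", "0")
  refresh_view(db)
  tibble::as_tibble(DBI::dbGetQuery(con,
    "SELECT cell_id, total_counts FROM X ORDER BY rowid"))
}

#' Compute per-gene total counts
#'
#' Sums each gene column with the engine's `SUM` aggregate and writes the
#' result into a `total_gene_counts` column of `var`, ordered by gene
#' ordinal.
#'
#' @param db read-write database handle.
#' @return tibble with `gene` and `total_gene_counts` in gene order.
#' @export
calculate_gene_counts <- function(db) {
  con <- db_con(db)
  assert_writable(db)
  require_table(db, "X")
  require_table(db, "var")
  genes <- gene_columns(db)
  sums <- numeric(length(genes))
  for (b in split_blocks(length(genes), GENE_BATCH)) {
    sel <- paste(paste0("SUM(", qid(genes[b]), ")"), collapse = ", ")
    r <- DBI::dbGetQuery(con, paste0("SELECT ", sel, " FROM X"))
    sums[b] <- as.numeric(r[1, ])
  }
  sums[is.na(sums)] <- 0  # empty table
  ensure_column(db, "var", "total_gene_counts", "FLOAT")
  DBI::dbExecute(con, "UPDATE var SET total_gene_counts = NULL")
  DBI::dbExecute(con, "UPDATE var SET total_gene_counts = ? WHERE id = ?",
                 params = list(sums, seq_along(genes) - 1L))
  tibble::as_tibble(DBI::dbGetQuery(con,
    "SELECT gene, total_gene_counts FROM var ORDER BY id"))
}

#' Library-size normalize the expression matrix
#'
#' Updates `X` in cell chunks: each value is divided by the cell's frozen
#' `total_counts` and multiplied by `target` (default 10,000), so every
#' cell with positive counts ends with row sum `target`. All-zero cells are
#' left untouched. [calculate_total_counts()] must have been run first;
#' if `X` changed since, a warning recommends recomputing totals.
#'
#' @param db read-write database handle.
#' @param target positive normalization target (default 10000).
#' @param chunk_size cells per update block.
#' @return the handle, invisibly.
#' @export
expression_normalize <- function(db, target = 10000, chunk_size = 5000) {
  con <- db_con(db)
  assert_writable(db)
  require_table(db, "X")
  if (!has_column(db, "X", "total_counts")) {
    abort_scsql("total_counts has not been computed; run calculate_total_counts() before expression_normalize()",
                "ordering_contract")
  }
  if (identical(meta_get(db, "x_mutated_since_total_counts"), "1")) {
    rlang::warn("X changed since total_counts was computed; totals are frozen - rerun calculate_total_counts() to renormalize against current values")
  }
  if (!is.numeric(target) || target <= 0) abort_scsql("target must be positive", "contract")
  genes <- gene_columns(db)
  tgt <- sprintf("%.17g", target)
  for (range in x_rowid_ranges(db, chunk_size)) {
    for (b in split_blocks(length(genes), GENE_BATCH)) {
      assigns <- paste0(qid(genes[b]), " = CASE WHEN total_counts > 0 THEN ",
                        qid(genes[b]), " * ", tgt, " / total_counts ELSE ",
                        qid(genes[b]), " END", collapse = ", ")
      DBI::dbExecute(con, paste0("UPDATE X SET ", assigns,
                                 " WHERE rowid BETWEEN ", range[1], " AND ", range[2]))
    }
  }
  meta_set(db, "x_mutated_since_total_counts", "1")
  invisible(db)
}

#' Log-transform the expression matrix
#'
#' Replaces every value `x` with `log(1 + x)` in the requested base
#' (natural log, log2 or log10), computed inside the database in cell
#' chunks. The pseudocount keeps zeros at zero and preserves value order
#' within each gene. Negative values are a domain error.
#'
#' @param db read-write database handle.
#' @param base `"ln"`, `"log2"` or `"log10"`.
#' @param chunk_size cells per update block.
#' @return the handle, invisibly.
#' @export
expression_log <- function(db, base = c("ln", "log2", "log10"), chunk_size = 5000) {
  base <- match.arg(base)
  con <- db_con(db)
  assert_writable(db)
  require_table(db, "X")
  genes <- gene_columns(db)
  for (b in split_blocks(length(genes), GENE_BATCH)) {
    mins <- paste(paste0("MIN(", qid(genes[b]), ")"), collapse = ", ")
    r <- as.numeric(DBI::dbGetQuery(con, paste0("SELECT ", mins, " FROM X"))[1, ])
    if (any(!is.na(r) & r < 0)) {
      g <- genes[b][which(r < 0)[1]]
      cell <- DBI::dbGetQuery(con, paste0("SELECT cell_id FROM X WHERE ",
                                          qid(g), " < 0 LIMIT 1"))$cell_id
      orig <- identifier_map(db, "X")
      abort_scsql(paste0("negative value in gene '",
                         orig$original[match(g, orig$sanitized)],
                         "' (cell '", cell, "'); log transform requires non-negative X"),
                  "domain")
    }
  }
  fmt <- switch(base,
    ln = "log(1.0 + %s)",
    log2 = "(log(1.0 + %s) / log(2.0))",
    log10 = "log10(1.0 + %s)")
  for (range in x_rowid_ranges(db, chunk_size)) {
    for (b in split_blocks(length(genes), GENE_BATCH)) {
      assigns <- paste0(qid(genes[b]), " = ", sprintf(fmt, qid(genes[b])), collapse = ", ")
      DBI::dbExecute(con, paste0("UPDATE X SET ", assigns,
                                 " WHERE rowid BETWEEN ", range[1], " AND ", range[2]))
    }
  }
  mark_x_mutated(db)
  invisible(db)
}

#' Compute per-gene expression variance
#'
#' Variance of each gene column, computed from in-database aggregates
#' (count, sum, sum of squares) and stored in the `variance` column of
#' `var`. The whole-table path defaults to the population estimator
#' (divisor `n`); the chunked path streams per-block moments and defaults
#' to the sample estimator with Bessel's correction (divisor `n - 1`).
#' Both estimators are available on either path.
#'
#' @param db read-write database handle.
#' @param estimator `"population"` or `"sample"`; default depends on
#'   `chunked` as described above.
#' @param chunked stream cell blocks instead of one whole-table pass.
#' @param chunk_size cells per block for the chunked path.
#' @return tibble with `gene` and `variance`; the estimator used is
#'   attached as attribute `"estimator"`.
#' @export
calculate_variable_genes <- function(db, estimator = NULL, chunked = FALSE,
                                     chunk_size = 5000) {
  con <- db_con(db)
  assert_writable(db)
  require_table(db, "X")
  require_table(db, "var")
  estimator <- estimator %||% if (chunked) "sample" else "population"
  estimator <- match.arg(estimator, c("population", "sample"))
  n <- DBI::dbGetQuery(con, "SELECT COUNT(*) AS n FROM X")$n
  if (estimator == "sample" && n < 2) {
    abort_scsql("sample variance is undefined for fewer than 2 cells", "undefined_variance")
  }
  genes <- gene_columns(db)
  s1 <- numeric(length(genes))
  s2 <- numeric(length(genes))
  ranges <- if (chunked) x_rowid_ranges(db, chunk_size) else list(NULL)
  for (range in ranges) {
    for (b in split_blocks(length(genes), GENE_BATCH)) {
      sel <- paste(c(paste0("SUM(", qid(genes[b]), ")"),
                     paste0("SUM(", qid(genes[b]), " * ", qid(genes[b]), ")")),
                   collapse = ", ")
      sql <- paste0("SELECT ", sel, " FROM X")
      if (!is.null(range)) sql <- paste0(sql, " WHERE rowid BETWEEN ", range[1], " AND ", range[2])
      r <- as.numeric(DBI::dbGetQuery(con, sql)[1, ])
      k <- length(b)
      s1[b] <- s1[b] + r[seq_len(k)]
      s2[b] <- s2[b] + r[k + seq_len(k)]
    }
  }
  centered <- s2 - s1^2 / n
  variance <- pmax(0, centered / if (estimator == "sample") (n - 1) else n)
  ensure_column(db, "var", "variance", "FLOAT")
  DBI::dbExecute(con, "UPDATE var SET variance = ? WHERE id = ?",
                 params = list(variance, seq_along(genes) - 1L))
  meta_set(db, "variance_estimator", estimator)
  out <- tibble::as_tibble(DBI::dbGetQuery(con, "SELECT gene, variance FROM var ORDER BY id"))
  attr(out, "estimator") <- estimator
  out
}

#' Select the most variable genes
#'
#' Genes sorted by stored variance, descending; ties broken by gene ordinal
#' ascending. Requires [calculate_variable_genes()] to have been run.
#'
#' @param db database handle.
#' @param n_top number of genes to return (clamped to the number of genes).
#' @return character vector of gene names, most variable first.
#' @export
select_top_variable_genes <- function(db, n_top) {
  con <- db_con(db)
  require_table(db, "var")
  if (!has_column(db, "var", "variance")) {
    abort_scsql("variance has not been computed; run calculate_variable_genes() first",
                "ordering_contract")
  }
  r <- DBI::dbGetQuery(con, paste0(
    "SELECT gene FROM var ORDER BY variance DESC, id ASC LIMIT ",
    as.integer(max(0, n_top))))
  r$gene
}

#' Principal component analysis of the expression matrix
#'
#' Covariance-matrix PCA of the top variable genes, computed as a hybrid:
#' per-block cross-products and column sums are accumulated by streaming
#' cell chunks out of the database, the (centered) covariance matrix is
#' eigendecomposed in R, and per-cell scores are written back to the
#' `PC_scores` table (`cell_id`, `pc1` ... `pck`). Genes are mean-centered
#' but not variance-scaled by default. For reproducibility across
#' eigensolvers, each loading vector's largest-magnitude element is made
#' positive.
#'
#' @param db read-write database handle.
#' @param n_components number of components k.
#' @param n_top_genes number of top variable genes to use (default: all
#'   genes, at most 2000).
#' @param center mean-center genes (default `TRUE`).
#' @param scale divide genes by their standard deviation (default `FALSE`).
#' @param chunk_size cells per streamed block.
#' @return an object of class `sc_pca`: list with `scores` (tibble),
#'   `loadings` (genes_used x k matrix), `explained_variance` (length-k,
#'   non-increasing eigenvalues), and `genes_used`.
#' @export
calculate_pca <- function(db, n_components, n_top_genes = NULL, center = TRUE,
                          scale = FALSE, chunk_size = 5000) {
  con <- db_con(db)
  assert_writable(db)
  require_table(db, "X")
  if (!has_column(db, "var", "variance")) {
    abort_scsql("variance has not been computed; run calculate_variable_genes() before calculate_pca()",
                "ordering_contract")
  }
  n_genes <- length(gene_columns(db))
  n_top_genes <- n_top_genes %||% min(n_genes, 2000L)
  if (n_components > n_top_genes) {
    abort_scsql("n_components must not exceed n_top_genes", "contract")
  }
  genes_used <- select_top_variable_genes(db, n_top_genes)
  vmax <- DBI::dbGetQuery(con, "SELECT MAX(variance) AS v FROM var")$v
  if (!is.na(vmax) && vmax <= 0) {
    abort_scsql("all selected genes have zero variance; PCA is degenerate", "degenerate")
  }
  m <- identifier_map(db, "X")
  cols <- m$sanitized[match(genes_used, m$original)]
  p <- length(cols)

  n <- 0
  s <- numeric(p)
  C <- matrix(0, p, p)
  ranges <- x_rowid_ranges(db, chunk_size)
  for (range in ranges) {
    M <- read_x_block(db, cols, range)
    n <- n + nrow(M)
    s <- s + colSums(M)
    C <- C + crossprod(M)
  }
  if (n < 2) abort_scsql("PCA requires at least 2 cells", "degenerate")
  mu <- if (center) s / n else numeric(p)
  cov <- (C - n * tcrossprod(mu)) / (n - 1)
  sd_scale <- rep(1, p)
  if (scale) {
    sd_scale <- sqrt(pmax(diag(cov), .Machine$double.eps))
    cov <- cov / tcrossprod(sd_scale)
  }
  eig <- eigen(cov, symmetric = TRUE)
  k <- as.integer(n_components)
  V <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  ev <- pmax(eig$values[seq_len(k)], 0)

  pc_cols <- paste0("pc", seq_len(k))
  DBI::dbExecute(con, "DROP TABLE IF EXISTS PC_scores")
  DBI::dbExecute(con, paste0("CREATE TABLE PC_scores (cell_id TEXT, ",
                             paste(qid(pc_cols), "FLOAT", collapse = ", "), ")"))
  for (range in ranges) {
    ids <- DBI::dbGetQuery(con, paste0(
      "SELECT cell_id FROM X WHERE rowid BETWEEN ", range[1], " AND ", range[2],
      " ORDER BY rowid"))$cell_id
    M <- read_x_block(db, cols, range)
    S <- sweep(M, 2, mu, "-")
    if (scale) S <- sweep(S, 2, sd_scale, "/")
    S <- S %*% V
    df <- as.data.frame(S)
    names(df) <- pc_cols
    DBI::dbAppendTable(con, "PC_scores", cbind(cell_id = ids, df))
  }

  rownames(V) <- genes_used
  colnames(V) <- pc_cols
  structure(list(
    scores = tibble::as_tibble(DBI::dbGetQuery(con, "SELECT * FROM PC_scores ORDER BY rowid")),
    loadings = V,
    explained_variance = ev,
    genes_used = genes_used,
    center = center, scale = scale, n_cells = n
  ), class = "sc_pca")
}

#' @export
print.sc_pca <- function(x, ...) {
  cat("<sc_pca> ", x$n_cells, " cells x ", length(x$genes_used), " genes, k = ",
      length(x$explained_variance), "\n", sep = "")
  pct <- 100 * x$explained_variance / max(sum(x$explained_variance), .Machine$double.eps)
  cat("  explained variance (%):", paste(sprintf("%.1f", pct), collapse = ", "), "\n")
  invisible(x)
}

#' Differential expression between two cell groups
#'
#' Welch's two-sample t test per gene, computed from in-database per-group
#' moments (count, sum, sum of squares) so no expression values leave the
#' database. The fold change is `log2((mean_a + eps) / (mean_b + eps))`
#' with `eps = 1e-9` to keep silent genes finite. Two-sided p-values use
#' the t distribution with Welch-Satterthwaite degrees of freedom;
#' Benjamini-Hochberg q-values are appended when `adjust = TRUE` (an
#' optional convenience, not part of the core test).
#'
#' @param db database handle.
#' @param group_column obs column holding group labels (original name
#'   allowed).
#' @param group_a,group_b the two labels to compare.
#' @param genes optional subset of genes (original names); default all.
#' @param adjust append BH-adjusted q-values (default `TRUE`).
#' @return tibble of class `sc_de` with per-gene statistics.
#' @export
calculate_differential_expression <- function(db, group_column, group_a, group_b,
                                              genes = NULL, adjust = TRUE) {
  con <- db_con(db)
  require_table(db, "X")
  require_table(db, "obs")
  om <- identifier_map(db, "obs")
  col <- group_column
  hit <- match(group_column, om$original)
  if (!is.na(hit)) col <- om$sanitized[hit]
  if (!has_column(db, "obs", col)) {
    abort_scsql(paste0("obs has no column '", group_column, "'"), "unknown_column")
  }
  labels <- DBI::dbGetQuery(con, paste0("SELECT DISTINCT ", qid(col),
                                        " AS l FROM obs ORDER BY l"))$l
  for (g in c(group_a, group_b)) {
    if (!g %in% labels) {
      abort_scsql(paste0("unknown group label '", g, "'; available: ",
                         paste(labels, collapse = ", ")), "unknown_group")
    }
  }

  gm <- identifier_map(db, "X")
  if (is.null(genes)) {
    genes <- gm$original
    cols <- gm$sanitized
  } else {
    hit <- match(genes, gm$original)
    if (anyNA(hit)) {
      abort_scsql(paste0("unknown gene(s): ",
                         paste(genes[is.na(hit)], collapse = ", ")), "unknown_column")
    }
    cols <- gm$sanitized[hit]
  }
  p <- length(cols)

  group_moments <- function(label) {
    nrows <- DBI::dbGetQuery(con, paste0(
      "SELECT COUNT(*) AS n FROM obs WHERE ", qid(col), " = ?"), params = list(label))$n
    if (nrows < 2) {
      abort_scsql(paste0("group '", label, "' has fewer than 2 cells"), "insufficient_cells")
    }
    s1 <- numeric(p); s2 <- numeric(p)
    for (b in split_blocks(p, GENE_BATCH)) {
      sel <- paste(c(paste0("SUM(x.", qid(cols[b]), ")"),
                     paste0("SUM(x.", qid(cols[b]), " * x.", qid(cols[b]), ")")),
                   collapse = ", ")
      r <- as.numeric(DBI::dbGetQuery(con, paste0(
        "SELECT ", sel, " FROM X x JOIN obs o ON x.cell_id = o.cell_id WHERE o.",
        qid(col), " = ?"), params = list(label))[1, ])
      k <- length(b)
      s1[b] <- r[seq_len(k)]
      s2[b] <- r[k + seq_len(k)]
    }
    list(n = nrows, mean = s1 / nrows,
         var = pmax(0, (s2 - s1^2 / nrows) / (nrows - 1)))
  }
  a <- group_moments(group_a)
  b <- group_moments(group_b)

  se2 <- a$var / a$n + b$var / b$n
  diff <- a$mean - b$mean
  stat <- ifelse(se2 > 0, diff / sqrt(se2), ifelse(diff == 0, 0, Inf * sign(diff)))
  df <- ifelse(se2 > 0,
               se2^2 / ((a$var / a$n)^2 / (a$n - 1) + (b$var / b$n)^2 / (b$n - 1)),
               a$n + b$n - 2)
  p_value <- ifelse(is.finite(stat), 2 * stats::pt(-abs(stat), df),
                    ifelse(stat == 0, 1, 0))
  p_value[stat == 0] <- 1
  eps <- 1e-9
  lfc <- log2((a$mean + eps) / (b$mean + eps))

  out <- tibble::tibble(
    gene = genes,
    n_a = a$n, n_b = b$n,
    mean_a = a$mean, mean_b = b$mean,
    log2_fold_change = lfc,
    statistic = stat, df = df, p_value = p_value
  )
  if (adjust) out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  class(out) <- c("sc_de", class(out))
  attr(out, "groups") <- c(group_a, group_b)
  out
}

# ---- delegation points -----------------------------------------------------

pc_score_matrix <- function(db) {
  con <- db_con(db)
  if (!"PC_scores" %in% DBI::dbListTables(con)) {
    abort_scsql("PC_scores does not exist; run calculate_pca() first", "ordering_contract")
  }
  d <- DBI::dbGetQuery(con, "SELECT * FROM PC_scores ORDER BY rowid")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$cell_id
  m
}

align_delegate_output <- function(out, cell_ids) {
  rn <- rownames(out) %||% names(out)
  if (!is.null(rn) && setequal(rn, cell_ids)) {
    if (is.matrix(out) || is.data.frame(out)) out[match(cell_ids, rn), , drop = FALSE]
    else out[match(cell_ids, rn)]
  } else {
    if (NROW(out) != length(cell_ids)) {
      abort_scsql("delegate output length does not match the number of cells", "contract")
    }
    out
  }
}

#' Run a pluggable 2-D embedding over the PC scores
#'
#' The embedding algorithm itself is not implemented here: a delegate
#' routine (e.g. a UMAP implementation) receives the cells x k PC-score
#' matrix (cell ids as row names) and must return a cells x 2 matrix.
#' Output rows named by cell id are re-aligned by name; unnamed output is
#' taken positionally. The embedding is persisted to the
#' `umap_embeddings` table.
#'
#' @param db read-write database handle with a `PC_scores` table.
#' @param delegate function of one matrix argument returning a cells x 2
#'   matrix.
#' @return tibble `cell_id`, `umap1`, `umap2`.
#' @export
run_embedding <- function(db, delegate = NULL) {
  if (is.null(delegate)) {
    abort_scsql("no embedding delegate configured; supply a function(scores) -> cells x 2 matrix",
                "not_configured")
  }
  con <- db_con(db)
  assert_writable(db)
  scores <- pc_score_matrix(db)
  out <- delegate(scores)
  out <- align_delegate_output(as.matrix(out), rownames(scores))
  if (ncol(out) != 2) abort_scsql("embedding delegate must return 2 columns", "contract")
  DBI::dbExecute(con, "DROP TABLE IF EXISTS umap_embeddings")
  DBI::dbExecute(con, "CREATE TABLE umap_embeddings (cell_id TEXT, umap1 FLOAT, umap2 FLOAT)")
  DBI::dbAppendTable(con, "umap_embeddings",
                     data.frame(cell_id = rownames(scores),
                                umap1 = out[, 1], umap2 = out[, 2]))
  tibble::as_tibble(DBI::dbGetQuery(con, "SELECT * FROM umap_embeddings ORDER BY rowid"))
}

#' Run a pluggable clustering over the PC scores
#'
#' Like [run_embedding()], a delegation point: the delegate receives the
#' PC-score matrix and returns one integer label per cell (named output is
#' re-aligned by cell id). Labels are persisted as the `leiden_clusters`
#' column of `obs`.
#'
#' @param db read-write database handle with a `PC_scores` table.
#' @param delegate function of one matrix argument returning per-cell
#'   integer labels.
#' @return tibble `cell_id`, `leiden_clusters`.
#' @export
run_clustering <- function(db, delegate = NULL) {
  if (is.null(delegate)) {
    abort_scsql("no clustering delegate configured; supply a function(scores) -> integer labels",
                "not_configured")
  }
  con <- db_con(db)
  assert_writable(db)
  require_table(db, "obs")
  scores <- pc_score_matrix(db)
  out <- delegate(scores)
  labels <- align_delegate_output(out, rownames(scores))
  labels <- as.integer(labels)
  ensure_column(db, "obs", "leiden_clusters", "INTEGER")
  DBI::dbExecute(con, "UPDATE obs SET leiden_clusters = NULL")
  DBI::dbExecute(con,
    "UPDATE obs SET leiden_clusters = ? WHERE cell_id = ?",
    params = list(labels, rownames(scores)))
  refresh_view(db)
  tibble::as_tibble(DBI::dbGetQuery(con,
    "SELECT cell_id, leiden_clusters FROM obs ORDER BY rowid"))
}
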