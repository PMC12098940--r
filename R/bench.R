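# Query benchmarking harness: a configurable suite of increasingly complex
# queries, executed against both the database and a dense in-memory oracle.
# Correctness gates timing — a (method, query) pair only ever gets timing
# rows after its database result has been shown equal to the oracle's.

#' Default six-query benchmark suite
#'
#' Six queries of increasing complexity over a dataset with a `celltype`
#' obs column: (1) single-gene select, (2) single-gene threshold filter,
#' (3) two-gene conjunctive filter, (4) per-gene average over all cells,
#' (5) group-by cell type aggregate, (6) join-with-obs filtered aggregate.
#' Each entry carries the SQL text and an equivalent dense-matrix oracle;
#' the suite is an ordinary list, so entries can be replaced or extended.
#'
#' @param bundle the [sc_bundle()] the suite will run against (used to pick
#'   gene names and thresholds).
#' @param max_avg_genes cap on the number of genes aggregated by query 4.
#' @return list of `sc_bench_query` entries with fields `query_id`,
#'   `label`, `sql`, `oracle`.
#' @export
default_query_suite <- function(bundle, max_avg_genes = 500L) {
  genes <- bundle$var$gene
  ga <- genes[1]
  gb <- genes[min(2, length(genes))]
  avg_genes <- genes[seq_len(min(length(genes), max_avg_genes))]
  q <- function(query_id, label, sql, oracle) {
    structure(list(query_id = query_id, label = label, sql = sql, oracle = oracle),
              class = "sc_bench_query")
  }
  key_sort <- function(df) df[do.call(order, unname(as.list(df))), , drop = FALSE]

  list(
    q(1L, "single-gene select",
      paste0("SELECT cell_id, ", qid(ga), " FROM X"),
      function(b) {
        X <- bundle_matrix(b)
        tibble::tibble(cell_id = rownames(X), !!ga := unname(X[, ga]))
      }),
    q(2L, "single-gene threshold filter",
      paste0("SELECT cell_id, ", qid(ga), " FROM X WHERE ", qid(ga), " > 5.0"),
      function(b) {
        X <- bundle_matrix(b)
        keep <- X[, ga] > 5.0
        tibble::tibble(cell_id = rownames(X)[keep], !!ga := unname(X[keep, ga]))
      }),
    q(3L, "two-gene conjunctive filter",
      paste0("SELECT cell_id FROM X WHERE ", qid(ga), " > 2.5 AND ", qid(gb), " <= 7.5"),
      function(b) {
        X <- bundle_matrix(b)
        keep <- X[, ga] > 2.5 & X[, gb] <= 7.5
        tibble::tibble(cell_id = rownames(X)[keep])
      }),
    q(4L, "per-gene average",
      paste0("SELECT ", paste0("AVG(", qid(avg_genes), ") AS ", qid(avg_genes),
                               collapse = ", "), " FROM X"),
      function(b) {
        X <- bundle_matrix(b)
        tibble::as_tibble(as.list(colMeans(X[, avg_genes, drop = FALSE])))
      }),
    q(5L, "group-by cell type aggregate",
      paste0("SELECT celltype, COUNT(*) AS n, AVG(", qid(ga),
             ") AS mean_expr FROM adata GROUP BY celltype ORDER BY celltype"),
      function(b) {
        X <- bundle_matrix(b)
        d <- tibble::tibble(celltype = b$obs$celltype, v = unname(X[, ga]))
        out <- dplyr::summarise(dplyr::group_by(d, .data$celltype),
                                n = dplyr::n(), mean_expr = mean(.data$v),
                                .groups = "drop")
        dplyr::arrange(out, .data$celltype)
      }),
    q(6L, "join-with-obs filtered aggregate",
      paste0("SELECT o.celltype, SUM(x.", qid(ga), ") AS total FROM X x ",
             "JOIN obs o ON x.cell_id = o.cell_id WHERE x.", qid(gb),
             " > 5.0 GROUP BY o.celltype ORDER BY o.celltype"),
      function(b) {
        X <- bundle_matrix(b)
        keep <- X[, gb] > 5.0
        d <- tibble::tibble(celltype = b$obs$celltype[keep], v = unname(X[keep, ga]))
        out <- dplyr::summarise(dplyr::group_by(d, .data$celltype),
                                total = sum(.data$v), .groups = "drop")
        dplyr::arrange(out, .data$celltype)
      })
  )
}

# Compare a database result and an oracle result, unordered, with a small
# numeric tolerance. Returns TRUE or a description of the first mismatch.
results_equivalent <- function(db_res, oracle_res, tol = 1e-8) {
  if (!setequal(names(db_res), names(oracle_res))) {
    return(paste0("column mismatch: ", paste(names(db_res), collapse = ","), " vs ",
                  paste(names(oracle_res), collapse = ",")))
  }
  oracle_res <- oracle_res[names(db_res)]
  if (nrow(db_res) != nrow(oracle_res)) {
    return(paste0("row count ", nrow(db_res), " vs ", nrow(oracle_res)))
  }
  canon <- function(d) {
    d <- as.data.frame(d)
    if (nrow(d) > 1) d <- d[do.call(order, unname(as.list(d))), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  a <- canon(db_res); b <- canon(oracle_res)
  for (j in names(a)) {
    if (is.numeric(a[[j]])) {
      scale <- pmax(abs(b[[j]]), 1)
      if (any(abs(a[[j]] - b[[j]]) / scale > tol)) return(paste0("numeric mismatch in ", j))
    } else if (!identical(as.character(a[[j]]), as.character(b[[j]]))) {
      return(paste0("value mismatch in ", j))
    }
  }
  TRUE
}

#' Run the benchmark suite with correctness-gated timing
#'
#' Every query is first executed once on the database path and once on the
#' dense oracle path and the results compared value-for-value; any mismatch
#' is a hard failure and no timings are reported. Only then is each query
#' timed `replicates` times on both paths.
#'
#' @param db database handle built from `bundle`.
#' @param bundle the source [sc_bundle()] (dense-oracle path).
#' @param suite list of query entries, e.g. [default_query_suite()].
#' @param replicates timing repetitions per query (default 6).
#' @return list with `results` (per-query verified result tibbles) and
#'   `timings` (tibble of class `sc_bench`: `method_label`, `library_size`,
#'   `query_id`, `replicate`, `wall_time` in seconds).
#' @export
run_query_suite <- function(db, bundle, suite = default_query_suite(bundle),
                            replicates = 6) {
  n_cells <- bundle$X$n_cells
  results <- list()
  for (qe in suite) {
    db_res <- query(db, qe$sql)
    oracle_res <- qe$oracle(bundle)
    ok <- results_equivalent(db_res, oracle_res)
    if (!isTRUE(ok)) {
      abort_scsql(paste0("benchmark query ", qe$query_id, " (", qe$label,
                         ") disagrees with the dense oracle: ", ok,
                         "; refusing to report timings"), "bench_mismatch")
    }
    results[[as.character(qe$query_id)]] <- db_res
  }
  rows <- list()
  for (r in seq_len(replicates)) {
    for (qe in suite) {
      t_db <- system.time(query(db, qe$sql))[["elapsed"]]
      t_dense <- system.time(qe$oracle(bundle))[["elapsed"]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        method_label = c("database", "dense"),
        library_size = n_cells, query_id = qe$query_id,
        replicate = r, wall_time = c(t_db, t_dense))
    }
  }
  timings <- dplyr::bind_rows(rows)
  class(timings) <- c("sc_bench", class(timings))
  list(results = results, timings = timings)
}

#' Paired t tests with Bonferroni correction over library sizes
#'
#' The statistical kernel of [compare_methods()]: given one vector of
#' paired timing differences per library size, computes a paired t test
#' per size, multiplies p-values by the number of sizes (capped at 1), and
#' flags significance at the corrected threshold. A zero-variance,
#' nonzero-mean difference vector is a degenerate pairing: it is reported
#' as significant with p = 0 and flagged.
#'
#' @param diffs named list; each element the per-pair timing differences
#'   (method A minus method B) for one library size.
#' @param alpha significance threshold on the corrected p-value
#'   (default 0.001).
#' @return tibble with one row per library size.
#' @export
paired_t_bonferroni <- function(diffs, alpha = 0.001) {
  m <- length(diffs)
  rows <- lapply(seq_along(diffs), function(i) {
    d <- diffs[[i]]
    n <- length(d)
    sd_d <- stats::sd(d)
    degenerate <- FALSE
    if (n < 2) abort_scsql("paired t test needs at least 2 pairs", "pairing")
    # a difference vector constant up to floating-point rounding is degenerate
    if (sd_d <= abs(mean(d)) * 1e-12) {
      if (mean(d) == 0) {
        stat <- 0; p <- 1
      } else {
        stat <- Inf * sign(mean(d)); p <- 0; degenerate <- TRUE
      }
    } else {
      stat <- mean(d) / (sd_d / sqrt(n))
      p <- 2 * stats::pt(-abs(stat), df = n - 1)
    }
    tibble::tibble(
      library_size = names(diffs)[i] %||% as.character(i),
      n_pairs = n, mean_diff = mean(d), statistic = stat, df = n - 1,
      p_value = p, p_adjusted = min(1, p * m),
      significant = min(1, p * m) < alpha, degenerate = degenerate)
  })
  dplyr::bind_rows(rows)
}

#' Compare two timed methods per library size
#'
#' Pairs timing replicates of two methods on matched
#' `(library_size, query_id, replicate)` cells and runs a paired t test
#' per library size with Bonferroni correction across sizes, mirroring the
#' runtime-curve significance procedure. An unmatched design is an error.
#'
#' @param timings an `sc_bench` tibble from [run_query_suite()] (possibly
#'   concatenated over sizes).
#' @param method_a,method_b the two `method_label` values to compare.
#' @param alpha corrected significance threshold (default 0.001).
#' @return tibble with one row per library size (see
#'   [paired_t_bonferroni()]).
#' @export
compare_methods <- function(timings, method_a = "database", method_b = "dense",
                            alpha = 0.001) {
  a <- timings[timings$method_label == method_a, ]
  b <- timings[timings$method_label == method_b, ]
  keys <- c("library_size", "query_id", "replicate")
  merged <- dplyr::inner_join(a, b, by = keys, suffix = c("_a", "_b"))
  if (nrow(merged) != nrow(a) || nrow(merged) != nrow(b)) {
    abort_scsql("methods do not have matched (size, query, replicate) cells", "pairing")
  }
  merged <- dplyr::arrange(merged, .data$library_size, .data$query_id, .data$replicate)
  sizes <- sort(unique(merged$library_size))
  diffs <- lapply(sizes, function(s) {
    d <- merged[merged$library_size == s, ]
    d$wall_time_a - d$wall_time_b
  })
  names(diffs) <- as.character(sizes)
  out <- paired_t_bonferroni(diffs, alpha = alpha)
  out$library_size <- sizes
  out
}
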