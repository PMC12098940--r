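test_that("gene threshold filters return exactly the positive cells", {
  set.seed(31)
  X <- matrix(0, 20, 2)
  X[sample(20, 7), 1] <- runif(7, 0.5, 5)  # 7 positive cells for the marker
  X[, 2] <- runif(20)
  b <- sc_bundle(X, var = tibble::tibble(gene = c("ENSMUSG00000070880", "other")))
  with_db(b, function(db) {
    r <- query(db,
      "SELECT ENSMUSG00000070880 FROM X WHERE ENSMUSG00000070880 > 0")
    expect_equal(nrow(r), 7)
    expect_true(all(r[[1]] > 0))
  })
})

test_that("row counts and aggregates match the dense matrix", {
  b <- make_fixture(100, 6, seed = 32)
  with_db(b, function(db) {
    expect_equal(query(db, "SELECT COUNT(*) AS n FROM X")$n, 100)
    avg <- query_raw(db, "SELECT AVG(g2) AS a FROM X")$a
    oracle <- mean(bundle_matrix(b)[, 2])
    expect_lt(abs(avg - oracle) / abs(oracle), 1e-6)
  })
})

test_that("randomized filter predicates agree with the boolean-mask oracle", {
  b <- make_fixture(200, 20, seed = 33)
  X <- bundle_matrix(b)
  with_db(b, function(db) {
    set.seed(34)
    for (i in 1:25) {
      g1 <- sample(20, 1); g2 <- sample(20, 1)
      t1 <- runif(1, 0, 10); t2 <- runif(1, 0, 10)
      op2 <- sample(c("<=", ">"), 1)
      sql <- sprintf("SELECT cell_id FROM X WHERE g%d > %.6f AND g%d %s %.6f",
                     g1, t1, g2, op2, t2)
      got <- query(db, sql)$cell_id
      mask <- X[, g1] > t1 & (if (op2 == "<=") X[, g2] <= t2 else X[, g2] > t2)
      expect_setequal(got, rownames(X)[mask])
    }
  })
})

test_that("query() is SELECT-only; query_raw executes anything", {
  b <- make_fixture(10, 3, seed = 35)
  with_db(b, function(db) {
    expect_error(query(db, "UPDATE X SET g1 = 0"), class = "scsql_error_not_select")
    expect_error(query(db, "DROP TABLE X"), class = "scsql_error_not_select")

    query_raw(db, "CREATE TABLE t (a INT)")
    expect_true("t" %in% list_tables(db))
    query_raw(db, "UPDATE X SET g1 = 0")
    expect_equal(query(db, "SELECT MAX(g1) AS m FROM X")$m, 0)
    err <- tryCatch(query_raw(db, "SELECT FROM nowhere"), error = identity)
    expect_match(conditionMessage(err), "nowhere")  # offending statement attached
  })
})

test_that("update and delete report affected rows and keep the view coherent", {
  set.seed(36)
  X <- matrix(runif(40, 3, 5), 20, 2)   # totals in (6, 10)
  X[c(2, 9, 15), ] <- 0.5               # exactly three cells with total < 5
  b <- sc_bundle(X)
  with_db(b, function(db) {
    calculate_total_counts(db)
    expect_equal(update_query(db, "X", "g1 = g1", where = "1 = 0"), 0)
    n <- delete_query(db, "X", where = "total_counts < 5")
    expect_equal(n, 3)
    expect_equal(query(db, "SELECT COUNT(*) AS n FROM X")$n, 17)
    # the convenience view reflects the deletion with no rebuild
    expect_equal(query(db, "SELECT COUNT(*) AS n FROM adata")$n, 17)
  })
})

test_that("original gene names are usable in queries after sanitization", {
  X <- matrix(c(1, 0, 2, 5, 3, 1), 3, 2)
  b <- sc_bundle(X, var = tibble::tibble(gene = c("HLA-A", "MT.CO1")))
  with_db(b, function(db) {
    r1 <- query(db, "SELECT cell_id FROM X WHERE HLA-A > 0 ORDER BY cell_id")
    r2 <- query(db, 'SELECT cell_id FROM X WHERE "HLA-A" > 0 ORDER BY cell_id')
    r3 <- query(db, "SELECT cell_id FROM X WHERE HLA_A > 0 ORDER BY cell_id")
    expect_equal(r1, r3)
    expect_equal(r2, r3)
    expect_equal(nrow(r1), 2)
    err <- expect_error(query(db, "SELECT nope FROM X"),
                        class = "scsql_error_unknown_column")
    expect_match(conditionMessage(err), "nope")
  })
})

test_that("return modes carry identical values", {
  b <- make_fixture(15, 4, seed = 37)
  with_db(b, function(db) {
    sql <- "SELECT cell_id, g1, g2 FROM X ORDER BY cell_id"
    frame <- query(db, sql)
    ann <- query(db, sql, return_mode = "annotated_matrix")
    pq <- query(db, sql, return_mode = "parquet")

    expect_s3_class(ann, "sc_bundle")
    expect_equal(dim(ann), c(15, 2))
    expect_equal(unname(bundle_matrix(ann)),
                 unname(as.matrix(frame[, c("g1", "g2")])), tolerance = 1e-12)

    expect_true(file.exists(pq))
    back <- tibble::as_tibble(arrow::read_parquet(pq))
    expect_equal(back, frame)
  })
})

test_that("annotated-matrix conversion partitions columns by type", {
  b <- make_fixture(12, 3, seed = 38)
  with_db(b, function(db) {
    res <- query(db, "SELECT cell_id, celltype, g1 FROM adata ORDER BY cell_id")
    ann <- to_annotated_matrix(res, db = db)
    expect_identical(colnames(bundle_matrix(ann)), "g1")
    expect_true("celltype" %in% names(ann$obs))
    expect_error(to_annotated_matrix(res["celltype"]), class = "scsql_error_contract")
  })
})

test_that("round trip through a SELECT * recovers the matrix and gene names", {
  b <- make_fixture(10, 5, seed = 39,
                    genes = c("HLA-A", "MT.CO1", "ok", "4ever", "x y"))
  with_db(b, function(db) {
    res <- query(db, "SELECT * FROM X ORDER BY cell_id", return_mode = "annotated_matrix")
    X <- bundle_matrix(res)
    orig <- bundle_matrix(b)[res$obs$cell_id, ]
    expect_identical(colnames(X), colnames(orig))
    expect_matrix_equal(X, orig, tol = 1e-7)
  })
})

test_that("show_settings is stable, non-empty and reflects live changes", {
  b <- make_fixture(5, 2, seed = 40)
  db1 <- make_db(b)
  db2 <- make_db(b)
  on.exit({ close_database(db1); close_database(db2) })
  s1 <- show_settings(db1)
  expect_true("memory_limit_bytes" %in% s1$setting)
  expect_identical(s1, show_settings(db2))
  query_raw(db1, "PRAGMA cache_size = -1048576")  # ~1 GiB page cache
  s <- show_settings(db1)
  expect_equal(as.numeric(s$value[s$setting == "memory_limit_bytes"]), 1048576 * 1024)
})
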