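test_that("make_db writes a .asql file and refuses silent overwrite", {
  b <- make_fixture(10, 4, seed = 2)
  dir <- withr::local_tempdir()
  db <- make_db(b, db_name = "fix", db_path = dir, chunk_size = 3)
  expect_true(file.exists(file.path(dir, "fix.asql")))
  expect_equal(chunk_plan(10, 3)$n_blocks, 4)  # ceil(10/3) ingestion blocks
  close_database(db)
  expect_error(make_db(b, db_name = "fix", db_path = dir),
               class = "scsql_error_exists")
  db2 <- make_db(b, db_name = "fix", db_path = dir, overwrite = TRUE)
  expect_equal(query(db2, "SELECT COUNT(*) AS n FROM X")$n, 10)
  close_database(db2)
})

test_that("ingestion is chunk-invariant and conserves rows and values", {
  b <- make_fixture(37, 8, seed = 3)
  sums <- lapply(c(1, 10, 37), function(cs) {
    with_db(b, function(db) {
      as.numeric(query(db, paste0("SELECT ", paste0("SUM(g", 1:8, ")", collapse = ", "),
                                  " FROM X"))[1, ])
    }, chunk_size = cs)
  })
  expect_identical(sums[[1]], sums[[2]])
  expect_identical(sums[[1]], sums[[3]])
  expect_equal(sums[[1]], unname(colSums(bundle_matrix(b))), tolerance = 1e-9)
})

test_that("sparse sources are densified on ingestion", {
  set.seed(9)
  Xs <- Matrix::rsparsematrix(40, 6, density = 0.3)
  Xs@x <- abs(Xs@x)
  b <- sc_bundle(Xs)
  with_db(b, function(db) {
    got <- bundle_matrix(db_to_bundle(db))
    expect_matrix_equal(got, as.matrix(Xs), tol = 1e-7)
  })
})

test_that("values survive storage at least to single precision", {
  b <- sc_bundle(matrix(c(0.1, 1/3, 2/7, 1e-4), 2, 2))
  with_db(b, function(db) {
    v <- query(db, "SELECT g1 FROM X ORDER BY cell_id")$g1[1]
    expect_lt(abs(v - 0.1), 1e-7)
  })
})

test_that("insert_x_chunked preserves cell order and reports failed blocks", {
  b <- make_fixture(5, 2, seed = 4)
  db <- make_db(b, chunk_size = 2)
  on.exit(close_database(db))
  ids <- query(db, "SELECT cell_id FROM X")$cell_id
  expect_identical(ids, b$obs$cell_id)

  # a source that dies mid-stream leaves a detectably incomplete database
  poison <- matrix_accessor(bundle_matrix(b))
  calls <- 0L
  inner <- poison$fetch
  poison$fetch <- function(rows) {
    calls <<- calls + 1L
    if (calls == 2L) stop("disk vanished")
    inner(rows)
  }
  db2 <- make_db(sc_bundle(matrix(numeric(0), 0, 2)), chunk_size = 2)  # empty shell, same genes
  on.exit(close_database(db2), add = TRUE)
  scsql:::meta_set(db2, "n_cells", 5L)
  err <- expect_error(
    insert_x_chunked(db2, poison, chunk_plan(5, 2), cell_ids = b$obs$cell_id),
    class = "scsql_error_ingestion")
  expect_match(conditionMessage(err), "block 2")
  expect_false(db_ingestion_complete(db2))
})

test_that("per-gene sums after ingestion match the dense column-sum oracle", {
  b <- make_fixture(200, 50, seed = 6)
  with_db(b, function(db) {
    got <- as.numeric(query(db, paste0(
      "SELECT ", paste0("SUM(g", 1:50, ")", collapse = ", "), " FROM X"))[1, ])
    oracle <- unname(colSums(bundle_matrix(b)))
    expect_lt(max(abs(got - oracle) / pmax(abs(oracle), 1)), 1e-3)
  })
})

test_that("databases persist across reopen and honor read-only mode", {
  b <- make_fixture(30, 5, seed = 7)
  dir <- withr::local_tempdir()
  db <- make_db(b, db_name = "persist", db_path = dir)
  tabs_before <- list_tables(db)
  before <- query(db, "SELECT cell_id, g2 FROM X WHERE g2 > 0 ORDER BY cell_id")
  close_database(db)

  path <- file.path(dir, "persist.asql")
  db2 <- open_database(path)
  expect_identical(list_tables(db2), tabs_before)
  after <- query(db2, "SELECT cell_id, g2 FROM X WHERE g2 > 0 ORDER BY cell_id")
  expect_equal(after, before)
  close_database(db2)

  ro <- open_database(path, mode = "read-only")
  expect_error(update_query(ro, "X", "g1 = 0"), class = "scsql_error_read_only")
  close_database(ro)

  expect_error(open_database(file.path(dir, "nope.asql")),
               class = "scsql_error_not_found")
  file.copy(path, file.path(dir, "odd.sqlite"))
  expect_warning(db3 <- open_database(file.path(dir, "odd.sqlite")), "extension")
  close_database(db3)
})

test_that("list_tables shows layer tables, tracks the view flag and new results", {
  b <- make_fixture(20, 4, seed = 8)
  db <- make_db(b, layers = c("X", "obs"))
  on.exit(close_database(db))
  expect_setequal(list_tables(db), c("X", "obs", "adata"))

  db2 <- make_db(b, layers = c("X", "obs"), convenience_view = FALSE)
  on.exit(close_database(db2), add = TRUE)
  expect_setequal(list_tables(db2), c("X", "obs"))

  db3 <- make_db(b)
  on.exit(close_database(db3), add = TRUE)
  before <- list_tables(db3)
  calculate_variable_genes(db3)
  pca <- calculate_pca(db3, n_components = 2, n_top_genes = 4)
  expect_identical(setdiff(list_tables(db3), before), "PC_scores")

  close_database(db3)
  expect_error(list_tables(db3), class = "scsql_error_stale_handle")
})

test_that("a backed-style accessor is never asked for more than one chunk", {
  b <- make_fixture(103, 6, seed = 10)
  acc <- instrument_accessor(b$X)
  b2 <- sc_bundle(acc, obs = b$obs, var = b$var)
  with_db(b2, function(db) {
    expect_equal(query(db, "SELECT COUNT(*) AS n FROM X")$n, 103)
  }, chunk_size = 7)
  expect_lte(acc$max_rows_requested(), 7L)
})

test_that("bundle -> database -> bundle round trip preserves every layer", {
  b <- make_fixture(40, 12, seed = 12, layers_rich = TRUE)
  with_db(b, function(db) {
    back <- db_to_bundle(db)
    expect_matrix_equal(bundle_matrix(back), bundle_matrix(b), tol = 1e-7)
    expect_identical(as.data.frame(back$obs), as.data.frame(b$obs))
    expect_identical(as.data.frame(back$var), as.data.frame(b$var))
    expect_matrix_equal(back$obsm$X_pca, unname(b$obsm$X_pca) + 0, tol = 1e-7)
    expect_matrix_equal(as.matrix(back$obsp$connectivities),
                        as.matrix(b$obsp$connectivities), tol = 1e-7)
    for (k in names(b$uns)) expect_identical(back$uns[[k]], b$uns[[k]])
  })
})

test_that("databases refuse gene counts beyond the engine column cap", {
  b <- make_fixture(2, 5)
  fake <- b
  fake$X$n_genes <- 5000L
  expect_error(make_db(fake), class = "scsql_error_capacity")
})
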