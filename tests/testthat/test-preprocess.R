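test_that("total counts equal dense row sums for any chunk size", {
  b <- sc_bundle(rbind(c(1, 2, 3), c(0, 0, 0)))
  with_db(b, function(db) {
    tc <- calculate_total_counts(db)
    expect_equal(tc$total_counts, c(6, 0))   # (1,2,3) -> 6; all-zero cell -> 0
    obs <- query(db, "SELECT total_counts FROM obs")
    expect_equal(obs$total_counts, c(6, 0))  # written to X and then obs
  })

  b2 <- make_fixture(300, 40, seed = 51)
  oracle <- unname(rowSums(bundle_matrix(b2)))
  for (cs in c(1, 7, 300)) {
    with_db(b2, function(db) {
      tc <- calculate_total_counts(db, chunk_size = cs)
      expect_lt(max(abs(tc$total_counts - oracle) / pmax(oracle, 1)), 1e-6)
    })
  }
})

test_that("gene counts equal dense column sums and track deletions", {
  b <- sc_bundle(matrix(c(0, 1, 4, 1, 1, 1), 3, 2))
  with_db(b, function(db) {
    gc <- calculate_gene_counts(db)
    expect_equal(gc$total_gene_counts, c(5, 3))
    delete_query(db, "X", where = "cell_id = 'cell_3'")
    gc2 <- calculate_gene_counts(db)
    expect_equal(gc2$total_gene_counts, c(1, 2))  # sums drop by that cell's values
  })

  b2 <- make_fixture(150, 25, seed = 52)
  with_db(b2, function(db) {
    gc <- calculate_gene_counts(db)
    expect_equal(gc$total_gene_counts, unname(colSums(bundle_matrix(b2))),
                 tolerance = 1e-9)
  })
})

test_that("library totals and gene totals conserve the grand sum exactly", {
  b <- make_fixture(80, 15, seed = 53, distribution = "negative-binomial")
  with_db(b, function(db) {
    tc <- calculate_total_counts(db)
    gc <- calculate_gene_counts(db)
    expect_identical(sum(tc$total_counts), sum(gc$total_gene_counts))
  })
})

test_that("normalization scales each positive cell to the target and spares empty cells", {
  b <- sc_bundle(matrix(c(1, 0, 3, 0), 2, 2))
  with_db(b, function(db) {
    calculate_total_counts(db)
    expression_normalize(db)
    r <- query(db, "SELECT g1, g2 FROM X ORDER BY rowid")
    expect_equal(unname(unlist(r[1, ])), c(2500, 7500))  # (1,3) at target 10000
    expect_equal(unname(unlist(r[2, ])), c(0, 0))        # all-zero cell untouched
  })

  b2 <- make_fixture(120, 30, seed = 54)
  X <- bundle_matrix(b2)
  oracle <- X * 1e4 / rowSums(X)
  with_db(b2, function(db) {
    calculate_total_counts(db, chunk_size = 17)
    expression_normalize(db, chunk_size = 17)
    got <- bundle_matrix(db_to_bundle(db))[, 1:30]
    expect_matrix_equal(unname(got), unname(oracle), tol = 1e-5)
  })
})

test_that("normalize before total counts fails with the ordering-contract error", {
  b <- make_fixture(10, 4, seed = 55)
  with_db(b, function(db) {
    expect_error(expression_normalize(db), class = "scsql_error_ordering_contract")
  })
})

test_that("normalize warns when X changed after totals were frozen", {
  b <- make_fixture(10, 4, seed = 56)
  with_db(b, function(db) {
    calculate_total_counts(db)
    update_query(db, "X", "g1 = g1 + 1")
    expect_warning(expression_normalize(db), "frozen")
  })
})

test_that("log transforms apply log(1+x) in the requested base", {
  b <- sc_bundle(matrix(c(0, 3, 0, 9, 0, 99), 2, 3))
  for (base in c("ln", "log2", "log10")) {
    with_db(b, function(db) {
      expression_log(db, base)
      r <- query(db, "SELECT g1, g2, g3 FROM X ORDER BY rowid")
      expect_equal(unname(unlist(r[1, ])), c(0, 0, 0))  # zeros stay zero
      expected <- switch(base, ln = log(c(4, 10, 100)),
                         log2 = c(2, log2(10), log2(100)),
                         log10 = c(log10(4), 1, 2))
      expect_equal(unname(unlist(r[2, ])), expected, tolerance = 1e-9)
    })
  }

  b2 <- make_fixture(200, 20, seed = 57)
  with_db(b2, function(db) {
    expression_log(db, "ln", chunk_size = 23)
    got <- bundle_matrix(db_to_bundle(db))
    expect_lt(max(abs(got - log1p(bundle_matrix(b2)))), 1e-6)
  })
})

test_that("negative values abort the log transform with cell and gene named", {
  X <- matrix(c(1, -2, 3, 4), 2, 2)
  b <- sc_bundle(X, var = tibble::tibble(gene = c("bad.gene", "fine")))
  with_db(b, function(db) {
    err <- expect_error(expression_log(db, "ln"), class = "scsql_error_domain")
    expect_match(conditionMessage(err), "bad.gene", fixed = TRUE)
    expect_match(conditionMessage(err), "cell_2")
  })
})

test_that("variance estimators match closed forms and each other via Bessel", {
  b <- sc_bundle(matrix(c(1, 2, 3, 5, 5, 5), 3, 2))
  with_db(b, function(db) {
    vpop <- calculate_variable_genes(db, estimator = "population")
    expect_equal(vpop$variance, c(2 / 3, 0), tolerance = 1e-12)
    vsamp <- calculate_variable_genes(db, estimator = "sample")
    expect_equal(vsamp$variance, c(1, 0), tolerance = 1e-12)
  })

  b2 <- make_fixture(400, 30, seed = 58)
  with_db(b2, function(db) {
    vpop <- calculate_variable_genes(db, estimator = "population")$variance
    vsamp <- calculate_variable_genes(db, estimator = "sample")$variance
    n <- 400
    nz <- vpop > 0
    expect_lt(max(abs(vsamp[nz] / vpop[nz] - n / (n - 1))), 1e-10)
  })
})

test_that("the chunked path streams moments and defaults to the sample estimator", {
  b <- make_fixture(1000, 30, seed = 59)
  oracle <- apply(bundle_matrix(b), 2, var)
  with_db(b, function(db) {
    v <- calculate_variable_genes(db, chunked = TRUE, chunk_size = 37)
    expect_identical(attr(v, "estimator"), "sample")
    expect_lt(max(abs(v$variance - oracle) / oracle), 1e-6)
    vw <- calculate_variable_genes(db)
    expect_identical(attr(vw, "estimator"), "population")
  })
})

test_that("sample variance with one cell is an explicit error", {
  b <- sc_bundle(matrix(c(1, 2), 1, 2))
  with_db(b, function(db) {
    expect_error(calculate_variable_genes(db, estimator = "sample"),
                 class = "scsql_error_undefined_variance")
  })
})

test_that("top variable genes are ordered by variance with ordinal tie-break", {
  X <- cbind(rep(c(0, 1), 5) * 0.3,      # variance ~0.025
             rep(c(0, 10), 5),           # largest
             rep(c(0, 4), 5),            # middle
             rep(c(0, 4), 5))            # tie with g3 -> g3 first
  b <- sc_bundle(X)
  with_db(b, function(db) {
    expect_error(select_top_variable_genes(db, 2),
                 class = "scsql_error_ordering_contract")
    calculate_variable_genes(db)
    expect_identical(select_top_variable_genes(db, 2), c("g2", "g3"))
    expect_identical(select_top_variable_genes(db, 99), c("g2", "g3", "g4", "g1"))
  })
})

test_that("the full chunked pipeline equals the dense oracle pipeline", {
  b <- make_fixture(500, 50, seed = 60)
  X <- bundle_matrix(b)
  oracle <- dense_pipeline(X, base = "ln")
  for (cs in c(211, 500)) {
    with_db(b, function(db) {
      calculate_total_counts(db, chunk_size = cs)
      expression_normalize(db, chunk_size = cs)
      expression_log(db, "ln", chunk_size = cs)
      got <- bundle_matrix(db_to_bundle(db))[, 1:50]
      expect_matrix_equal(unname(got), unname(oracle), tol = 1e-5)
    })
  }
})

test_that("PCA handles the rank-1 case and keeps scores orthogonal", {
  set.seed(61)
  base <- rnorm(100)
  X <- cbind(base, 2 * base + 3)  # perfectly correlated pair
  colnames(X) <- c("g1", "g2")
  b <- sc_bundle(X)
  with_db(b, function(db) {
    calculate_variable_genes(db)
    pca <- calculate_pca(db, n_components = 2, n_top_genes = 2)
    expect_gt(pca$explained_variance[1] / sum(pca$explained_variance), 1 - 1e-10)
    expect_lt(max(abs(pca$scores$pc2)), 1e-6)
  })

  b2 <- make_fixture(200, 20, seed = 62)
  with_db(b2, function(db) {
    calculate_variable_genes(db)
    pca <- calculate_pca(db, n_components = 5, n_top_genes = 15, chunk_size = 71)
    S <- as.matrix(pca$scores[, -1])
    G <- crossprod(scale(S, center = TRUE, scale = FALSE))
    off <- G - diag(diag(G))
    expect_lt(max(abs(off)) / max(diag(G)), 1e-6)
    # explained variance is non-increasing; loadings are unit norm
    expect_true(all(diff(pca$explained_variance) <= 1e-12))
    expect_equal(unname(sqrt(colSums(pca$loadings^2))), rep(1, 5), tolerance = 1e-9)
  })
})

test_that("PC scores match a dense covariance-eigendecomposition oracle up to sign", {
  b <- make_fixture(300, 40, seed = 63)
  with_db(b, function(db) {
    calculate_variable_genes(db)
    pca <- calculate_pca(db, n_components = 8, n_top_genes = 30, chunk_size = 97)
    X <- bundle_matrix(b)[, match(pca$genes_used, b$var$gene)]
    oracle <- prcomp(X, center = TRUE, scale. = FALSE)
    for (j in 1:8) {
      s <- pca$scores[[paste0("pc", j)]]
      o <- oracle$x[, j]
      rel <- min(sqrt(sum((s - o)^2)), sqrt(sum((s + o)^2))) / sqrt(sum(o^2))
      expect_lt(rel, 1e-4)
    }
    # scores are persisted and queryable
    expect_true("PC_scores" %in% list_tables(db))
    expect_equal(query(db, "SELECT COUNT(*) AS n FROM PC_scores")$n, 300)
  })
})

test_that("PCA preconditions fail loudly", {
  b <- make_fixture(20, 5, seed = 64)
  with_db(b, function(db) {
    expect_error(calculate_pca(db, 2), class = "scsql_error_ordering_contract")
    calculate_variable_genes(db)
    expect_error(calculate_pca(db, 6, n_top_genes = 5), class = "scsql_error_contract")
  })
  bz <- sc_bundle(matrix(5, 10, 3))
  with_db(bz, function(db) {
    calculate_variable_genes(db)
    expect_error(calculate_pca(db, 2, n_top_genes = 3),
                 class = "scsql_error_degenerate")
  })
})

test_that("differential expression matches Welch's t on dense data", {
  # identical groups: zero statistic, p = 1, zero fold change
  X <- rbind(matrix(1:6, 2, 3, byrow = TRUE), matrix(1:6, 2, 3, byrow = TRUE))
  b <- sc_bundle(X, obs = tibble::tibble(cell_id = paste0("c", 1:4),
                                         grp = c("a", "a", "b", "b")))
  with_db(b, function(db) {
    de <- calculate_differential_expression(db, "grp", "a", "b")
    expect_equal(de$statistic, rep(0, 3))
    expect_equal(de$p_value, rep(1, 3))
    expect_equal(de$log2_fold_change, rep(0, 3))
  })

  # exact doubling: log2 fold change of 1
  Xa <- matrix(c(2, 4, 6, 8), 2, 2, byrow = TRUE)
  b2 <- sc_bundle(rbind(Xa * 2, Xa),
                  obs = tibble::tibble(cell_id = paste0("c", 1:4),
                                       grp = rep(c("hi", "lo"), each = 2)))
  with_db(b2, function(db) {
    de <- calculate_differential_expression(db, "grp", "hi", "lo")
    expect_equal(de$log2_fold_change, rep(1, 2), tolerance = 1e-8)
  })

  # random fixture with a planted shift: statistics match t.test, planted
  # genes carry the largest |t|
  set.seed(65)
  n <- 60
  X <- matrix(rnorm(n * 20, mean = 5), n, 20)
  grp <- rep(c("A", "B"), each = n / 2)
  planted <- c(2, 7, 11, 16, 19)
  X[grp == "A", planted] <- X[grp == "A", planted] + 3
  b3 <- sc_bundle(X, obs = tibble::tibble(cell_id = paste0("c", 1:n), grp = grp))
  with_db(b3, function(db) {
    de <- calculate_differential_expression(db, "grp", "A", "B")
    for (g in c(1, 5, planted)) {
      tt <- t.test(X[grp == "A", g], X[grp == "B", g])
      expect_equal(de$statistic[g], unname(tt$statistic), tolerance = 1e-6)
      expect_equal(de$p_value[g], tt$p.value, tolerance = 1e-6)
      expect_equal(de$df[g], unname(tt$parameter), tolerance = 1e-6)
    }
    top5 <- order(abs(de$statistic), decreasing = TRUE)[1:5]
    expect_setequal(top5, planted)
    expect_true(all(c("q_value") %in% names(de)))
  })
})

test_that("differential expression validates groups", {
  b <- make_fixture(20, 4, seed = 66)
  with_db(b, function(db) {
    err <- expect_error(
      calculate_differential_expression(db, "celltype", "type_1", "nope"),
      class = "scsql_error_unknown_group")
    expect_match(conditionMessage(err), "type_1")  # lists available labels
    query_raw(db, "UPDATE obs SET celltype = 'solo' WHERE cell_id = 'cell_1'")
    expect_error(
      calculate_differential_expression(db, "celltype", "solo", "type_2"),
      class = "scsql_error_insufficient_cells")
    expect_error(
      calculate_differential_expression(db, "missing_col", "a", "b"),
      class = "scsql_error_unknown_column")
  })
})

test_that("embedding and clustering delegates are aligned, persisted and required", {
  b <- make_fixture(30, 8, seed = 67)
  with_db(b, function(db) {
    expect_error(run_embedding(db, function(s) s[, 1:2]),
                 class = "scsql_error_ordering_contract")
    calculate_variable_genes(db)
    calculate_pca(db, n_components = 3, n_top_genes = 8)

    expect_error(run_embedding(db), class = "scsql_error_not_configured")
    expect_error(run_clustering(db), class = "scsql_error_not_configured")

    emb <- run_embedding(db, function(s) s[, 1:2])
    pc <- query(db, "SELECT * FROM PC_scores ORDER BY rowid")
    expect_equal(emb$umap1, pc$pc1, tolerance = 1e-9)
    expect_true("umap_embeddings" %in% list_tables(db))

    cl <- run_clustering(db, function(s) rep(0L, nrow(s)))
    expect_true(all(cl$leiden_clusters == 0L))

    # a delegate that permutes its rows (named) is re-aligned by cell id
    perm_emb <- run_embedding(db, function(s) {
      perm <- sample(nrow(s))
      s[perm, 1:2]
    })
    expect_equal(perm_emb$umap1, pc$pc1, tolerance = 1e-9)
    perm_cl <- run_clustering(db, function(s) {
      lab <- as.integer(seq_len(nrow(s)))
      names(lab) <- rownames(s)
      rev(lab)
    })
    expect_identical(perm_cl$leiden_clusters, seq_len(30))
  })
})
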