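# Fixtures are generated in code; nothing is stored on disk.

# Small dense fixture with annotation layers exercising all column types.
make_fixture <- function(n = 50, g = 10, seed = 1, genes = NULL,
                         layers_rich = FALSE, distribution = "uniform") {
  b <- generate_dataset(synthetic_spec(n, n_genes = g, seed = seed,
                                       value_distribution = distribution))
  X <- bundle_matrix(b)
  if (!is.null(genes)) colnames(X) <- genes
  obs <- b$obs
  var <- tibble::tibble(gene = colnames(X))
  obsm <- list(); varm <- list(); obsp <- list(); uns <- list()
  if (layers_rich) {
    set.seed(seed + 1)
    obs$score <- rnorm(n)
    obs$n_detected <- sample.int(100L, n, replace = TRUE)
    obs$pass_qc <- sample(c(TRUE, FALSE), n, replace = TRUE)
    var$chrom <- sample(paste0("chr", 1:5), g, replace = TRUE)
    var$length_kb <- runif(g, 0.5, 100)
    obsm$X_pca <- matrix(rnorm(n * 2), n, 2)
    varm$loadings <- matrix(rnorm(g * 2), g, 2)
    obsp$connectivities <- Matrix::rsparsematrix(n, n, density = 0.05)
    uns <- list(note = "qc-pass", k = 5L, rate = 0.25, ok = TRUE,
                grid = matrix(1:4, 2, 2), meta = list(a = 1L, b = "x"))
  }
  sc_bundle(X, obs = obs, var = var, obsm = obsm, varm = varm,
            obsp = obsp, uns = uns)
}

with_db <- function(bundle, code, ...) {
  db <- make_db(bundle, ...)
  on.exit(close_database(db))
  code(db)
}

# Dense oracle for the standard pipeline: row-normalize then log1p.
dense_pipeline <- function(X, target = 1e4, base = "ln") {
  rs <- rowSums(X)
  Xn <- X
  pos <- rs > 0
  Xn[pos, ] <- X[pos, , drop = FALSE] * target / rs[pos]
  switch(base,
    ln = log(1 + Xn), log2 = log2(1 + Xn), log10 = log10(1 + Xn))
}

expect_matrix_equal <- function(a, b, tol = 1e-8) {
  expect_equal(dim(a), dim(b))
  scale <- pmax(abs(b), 1)
  expect_lt(max(abs(a - b) / scale), tol)
}
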