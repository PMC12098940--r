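#' Specify a synthetic cell-by-gene dataset
#'
#' Describes the simulated datasets used for runtime and correctness work:
#' a fully dense cells x genes expression matrix of random values plus an
#' obs layer with uniformly random cell-type assignments. The default
#' shape follows the simulation conditions of the benchmark design:
#' 10,000 genes, uniform random expression on `[0, 10)`, and one cell-type
#' label per cell. A negative-binomial mode (mean `nb_mean`, dispersion
#' `nb_dispersion`) is available for more count-like data.
#'
#' @param n_cells number of cells (>= 1).
#' @param n_genes number of genes (default 10000).
#' @param n_cell_types number of cell-type categories (default 5).
#' @param value_distribution `"uniform"` (on `[0, 10)`) or
#'   `"negative-binomial"`.
#' @param seed integer RNG seed; the same spec always generates a
#'   bit-identical dataset.
#' @param nb_mean,nb_dispersion negative-binomial mean and dispersion
#'   (variance = mean + dispersion * mean^2).
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cells, n_genes = 10000, n_cell_types = 5,
                           value_distribution = c("uniform", "negative-binomial"),
                           seed = 1, nb_mean = 2, nb_dispersion = 0.5) {
  value_distribution <- match.arg(value_distribution)
  if (n_cells < 1 || n_genes < 1) {
    abort_scsql("n_cells and n_genes must be >= 1", "contract")
  }
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_cell_types = as.integer(n_cell_types),
                 value_distribution = value_distribution,
                 seed = as.integer(seed),
                 nb_mean = nb_mean, nb_dispersion = nb_dispersion),
            class = "synthetic_spec")
}

#' Generate a synthetic dataset
#'
#' Draws the dense expression matrix and random cell-type labels described
#' by a [synthetic_spec()], optionally writing the dataset to an H5AD
#' file. Generation is deterministic in the spec's seed and leaves the
#' caller's RNG state untouched.
#'
#' @param spec a [synthetic_spec()] (or arguments forwarded to it).
#' @param h5ad_path optional path; if given, the bundle is also written as
#'   an H5AD file (ingestible by [make_db()] in backed mode).
#' @return an [sc_bundle()] with `obs$celltype`, nonnegative dense values,
#'   and the generation parameters recorded in `uns`.
#' @examples
#' b <- generate_dataset(synthetic_spec(100, n_genes = 50, seed = 7))
#' dim(b)
#' @export
generate_dataset <- function(spec, h5ad_path = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  n <- spec$n_cells
  p <- spec$n_genes
  X <- switch(spec$value_distribution,
    uniform = matrix(stats::runif(n * p, 0, 10), n, p),
    `negative-binomial` = matrix(
      as.double(stats::rnbinom(n * p, mu = spec$nb_mean, size = 1 / spec$nb_dispersion)),
      n, p))
  rownames(X) <- paste0("cell_", seq_len(n))
  colnames(X) <- paste0("g", seq_len(p))
  obs <- tibble::tibble(
    cell_id = rownames(X),
    celltype = paste0("type_", sample.int(spec$n_cell_types, n, replace = TRUE)))
  bundle <- sc_bundle(X, obs = obs,
                      uns = list(generation = list(
                        value_distribution = spec$value_distribution,
                        seed = spec$seed,
                        n_cell_types = spec$n_cell_types)))
  if (!is.null(h5ad_path)) write_h5ad(bundle, h5ad_path)
  bundle
}

#' Canonical content digest of a bundle
#'
#' MD5 of a canonical serialization of all layers (X densified, layers in
#' sorted order), used to assert generator determinism independent of file
#' container details.
#' @param bundle an [sc_bundle()].
#' @return character MD5 digest.
#' @export
bundle_digest <- function(bundle) {
  sort_named <- function(x) if (length(x)) x[order(names(x))] else x
  payload <- list(
    X = bundle_matrix(bundle),
    obs = as.data.frame(bundle$obs),
    var = as.data.frame(bundle$var),
    obsm = sort_named(bundle$obsm),
    varm = sort_named(bundle$varm),
    obsp = lapply(sort_named(bundle$obsp), as.matrix),
    uns = sort_named(bundle$uns)
  )
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  serialize(payload, con, version = 3L)
  close(con)
  unname(tools::md5sum(tmp))
}
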