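---
title: "Methods: relational storage and out-of-core preprocessing for cell-by-gene matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relational storage and out-of-core preprocessing for cell-by-gene matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scsql)
```

## The problem

Single-cell RNA-seq experiments produce a cells x genes expression matrix
`X` together with aligned annotation layers: per-cell metadata (`obs`),
per-gene metadata (`var`), per-cell and per-gene matrices (`obsm`,
`varm`), cell-pairwise matrices (`obsp`) and unstructured metadata
(`uns`). The standard container for this layered object is an H5AD file.
Atlas-scale datasets no longer fit in memory on ordinary machines, yet
most of the routine operations — filtering cells by marker expression,
library-size statistics, normalization, log transformation, gene
variance, PCA — are exactly the aggregate/scan workloads relational
engines are built for.

scsql maps the layered object onto an embedded SQL database (SQLite via
DBI/RSQLite): one wide table for `X` with a FLOAT column per gene and a
`cell_id` barcode column, one table per remaining layer property, and a
convenience view `adata` joining `obs` and `X` so annotations and
expression are queryable together. The database lives in memory or in a
single `.asql` file, requires no server process, and is queried with
plain SQL through `query()`. Preprocessing operations run *inside* the
database, iterating cells in chunks, so a dataset only ever occupies
O(chunk_size x n_genes) memory regardless of its total size.

## Schema mapping

- `X` → table `X(cell_id, g1, g2, ...)`, values stored in FLOAT-typed
  columns. Gene names are sanitized for SQL (every character outside
  `[A-Za-z0-9_]` becomes `_`, a leading digit gains a `_` prefix, and
  collisions receive `_1`, `_2`, ... suffixes in source order). The
  original-to-sanitized mapping is persisted, queries may use original
  names (they are rewritten before execution), and annotated-matrix
  results are translated back.
- `obs` → `obs(cell_id, <properties>)`; `var` → `var(id, gene,
  <properties>)` where `id` is the 0-based gene ordinal. Gene names are a
  column of `var`; there is no separate var_names table.
- each `obsm`/`varm` property → its own wide table named
  `<layer>_<property>` (e.g. `obsm_X_pca`).
- each `obsp` property → an edge-list table `(row_id, col_id, value)`
  with 0-based cell ordinals. A cells-wide table per cell is infeasible,
  and pairwise layers are sparse by construction.
- `uns` → `uns_raw(key, value, data_type)`. Values are serialized with a
  self-describing JSON text encoding tagged by one of
  `{string, int, float, bool, array, mapping, null}`; arrays keep their
  element kind and dimensions, so `reconstruct_uns(build_uns_payload(u))`
  is deep-equal to `u`, including the integer/double distinction.

Generated identifiers are always emitted double-quoted, so even a gene
literally named `SELECT` needs no reserved-word handling. Cell barcodes
come from the source object's observation names; when absent, ids
`cell_1 ... cell_n` are generated.

## Ingestion and the out-of-core contract

`make_db()` accepts an in-memory bundle or an H5AD path; file sources
are opened in backed mode and streamed. Ingestion walks the cell axis in
blocks of `chunk_size` (default 5,000 cells), fetching each block
through a matrix accessor and appending it in one transaction. The
accessor abstraction is what makes the memory contract testable: an
instrumented accessor records the largest row request, and the test
suite asserts it never exceeds one chunk. Sparse sources are densified
per chunk; `X` is stored fully dense, one value per cell and gene.

Two engine-level facts are worth knowing. First, values land in 8-byte
REAL storage even though the declared column type is FLOAT, so the
single-precision guarantee in the contracts is conservative; note that
integer counts above 2^24 would still be exact here, but the format
contract only promises FLOAT precision. Second, SQLite caps tables at
2,000 columns, which caps a database at 1,998 gene columns (cell_id and
total_counts are reserved). The synthetic generator defaults to 10,000
genes — a realistic transcriptome-scale width — but databases built from
such data must select at most 1,998 genes; the benchmark harness
therefore runs at 1,000 genes by default. Wide-table DDL is issued as a
single CREATE statement: with at most 2,000 columns the statement is a
few tens of kilobytes, far below the engine's statement-size limit, so
no batching is needed.

Long arithmetic *expressions* are a different matter: the engine limits
expression-tree depth to 1,000, so row sums and multi-column updates are
computed in gene batches of 300 columns and accumulated across batches.

`make_db()` refuses to overwrite an existing database unless
`overwrite = TRUE`; a failed ingestion leaves a database whose `X` row
count disagrees with the recorded cell count, detectable with
`db_ingestion_complete()`.

## Query surface

`query()` accepts exactly one SELECT (or WITH ... SELECT) statement —
mutation goes through `update_query()`, `delete_query()` or
`query_raw()`, which executes anything verbatim. Three return contracts
exist: a tibble (default), an annotated matrix (numeric columns become
`X`, `cell_id` and non-numeric columns become `obs` — the partition rule
is a documented package choice, since arbitrary result sets do not map
canonically onto a layered object), and a Parquet file. Row order is
unspecified without an ORDER BY; the tests always order by `cell_id`.

## Preprocessing semantics

All operations iterate cells in rowid blocks and genes in batches, with
every arithmetic step expressed in SQL against the stored table.

- `calculate_total_counts()` writes per-cell sums to `X.total_counts`
  and then `obs.total_counts`. Totals are *frozen* at compute time:
  `expression_normalize()` uses the stored column and warns if `X`
  changed since, rather than silently renormalizing against drifted
  values. Recomputing overwrites.
- `calculate_gene_counts()` writes per-gene SUMs to
  `var.total_gene_counts`.
- `expression_normalize(target = 10000)` rescales each cell with
  positive counts to row sum `target`; all-zero cells are left alone
  (the division-by-zero guard is a CASE expression).
- `expression_log(base)` applies `log_base(1 + x)`. The pseudocount is
  the single-cell convention, chosen so zeros remain finite and map to
  zero; the transform is monotone within each gene. Negative input is a
  domain error naming the offending gene and cell.
- `calculate_variable_genes()` computes per-gene variance from
  in-database aggregates (count, sum, sum of squares). The whole-table
  path defaults to the population estimator (divisor n); the chunked
  path streams per-block moments and defaults to the sample estimator
  with Bessel's correction (divisor n-1). This asymmetry of defaults is
  deliberate and mirrors the two computational routes; both estimators
  are available on both paths, and `sample = population x n/(n-1)`
  exactly. The sum-of-squares form can go negative by rounding for
  constant genes, so results are clamped at zero; for values of typical
  magnitude (0-10 after log transforms) the cancellation error is orders
  of magnitude below the 1e-6 relative tolerance the tests assert.

## PCA

`calculate_pca()` is a hybrid: cross-products and column sums of the
top-variable-gene submatrix are accumulated by streaming cell chunks out
of the database, the covariance matrix (divisor n-1, genes mean-centered,
not variance-scaled — scaling is an option, off by default) is
eigendecomposed in R with `eigen(symmetric = TRUE)`, and scores are
written back to the `PC_scores` table in a second streamed pass. Because
eigenvectors are defined only up to sign, each loading vector's
largest-magnitude element is made positive, which fixes the sign
reproducibly across eigensolvers. Degenerate inputs (all selected genes
constant, or fewer than 2 cells) fail loudly. Ties in the variance
ranking are broken by gene ordinal, ascending, so gene selection is
deterministic.

## Differential expression

The moment-based route dictated by the out-of-core design: per-group
count, mean and sample variance are computed in SQL, and Welch's
two-sample t statistic, Welch–Satterthwaite degrees of freedom and
two-sided p-values follow from those moments alone. The fold change is
`log2((mean_a + eps)/(mean_b + eps))` with `eps = 1e-9` so silent genes
stay finite. Benjamini–Hochberg q-values are appended as an optional
convenience column. Zero-variance edge cases are handled explicitly:
equal means give statistic 0 and p = 1; unequal means with zero pooled
variance give an infinite statistic and p = 0.

## Embedding and clustering delegation

UMAP embeddings and Leiden clusterings are deliberately *not*
implemented: `run_embedding()` and `run_clustering()` are delegation
points that hand the PC-score matrix (cell ids as row names) to a
user-supplied routine and persist its output under the conventional
names (`umap_embeddings` table, `obs.leiden_clusters` column), row-aligned
to `cell_id`. Delegate output with matching row names is re-aligned by
name; a missing delegate is an explicit error, never a silent fallback.

## Synthetic data and the benchmark harness

`generate_dataset()` emulates the simulated datasets used for runtime
work: a fully dense matrix of random expression values — uniform on
[0, 10) by default — over 10,000 genes, with one uniformly random
cell-type label per cell (5 types by default, a typical coarse
annotation granularity). A negative-binomial mode (mean 2, dispersion
0.5) produces more count-like data. Generation is bit-identical under a
fixed seed and leaves the caller's RNG untouched. What the generator
does *not* emulate: sparsity (real count matrices are mostly zeros),
gene-specific mean/dispersion structure, or correlated expression
programs — so passing tests demonstrate storage, query and numerical
fidelity, not biological realism.

The six-query default suite rises in complexity from a single-gene
select through threshold and conjunctive filters to whole-matrix
aggregates, group-by-cell-type aggregates, and a join-with-obs filtered
aggregate; the suite is an ordinary list and fully replaceable. Timing
is correctness-gated: every query's database result must equal the dense
oracle's before any timing row is emitted, and a mismatch is a hard
error. `compare_methods()` pairs replicates on (size, query, replicate)
cells and runs a paired t test per library size, Bonferroni-corrected
across sizes, flagging significance at corrected p < 0.001; a
zero-variance difference vector is reported as significant with p = 0
and flagged degenerate rather than erroring.

## Problem sizes in the default test run

The suite exercises chunking with chunk sizes {1, a prime, n} on
fixtures around 120 x 30 to 1,000 x 30, round-trips twenty randomized
fixtures up to 2,000 x 500, verifies the out-of-core contract on a
50,000 x 1,000 backed file, checks the paired-t procedure's type-I error
with 10,000 null simulations, and measures the 25,000 → 50,000-cell
scaling step at 1,000 genes with three replicates — sizes chosen so a
single CPU completes the run in minutes while every contract is still
exercised beyond one chunk and one gene batch.

## Known limitations

- At most 1,998 genes per database (engine column cap); wider data must
  be subset before ingestion.
- `X` is stored dense; a mostly-zero matrix costs the same space as a
  dense one.
- Single writer at a time; no server mode (the engine is in-process by
  design).
- obs/var factors are stored as text and return as character.
- The identifier rewriter replaces original gene names textually
  (word-boundary aware, quoted or bare); an original name occurring
  inside a string literal in a query would also be rewritten.
- No schema normalization: the layered-object mapping is deliberately
  literal, one table per layer property.
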