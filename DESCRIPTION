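Package: scsql
Title: Relational Databases and Out-of-Core Preprocessing for Single-Cell Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts layered single-cell expression objects (an X matrix plus
    obs/var/obsm/varm/obsp/uns annotation layers, read from H5AD files in full
    or streamed "backed" mode) into an embedded single-file SQL database, and
    exposes a query interface with data-frame, annotated-matrix and Parquet
    return modes. Preprocessing (library and gene counts, count normalization,
    log transforms, gene variance with Bessel's correction, covariance-based
    PCA, and a moment-based differential-expression test) runs chunked inside
    the database, so datasets larger than memory can be processed with bounded
    peak memory. Includes a synthetic-data generator and a correctness-gated
    query benchmarking harness with paired-t/Bonferroni comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    rhdf5,
    arrow,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    Matrix,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
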