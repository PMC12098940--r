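# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy PCA results
#'
#' @param x an `sc_pca` from [calculate_pca()].
#' @param matrix `"scores"` (one row per cell per component),
#'   `"loadings"` (one row per gene per component), or `"eigenvalues"`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.sc_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  k <- length(x$explained_variance)
  switch(matrix,
    scores = tidyr::pivot_longer(x$scores, -"cell_id",
                                 names_to = "component", values_to = "score"),
    loadings = {
      d <- tibble::as_tibble(x$loadings, rownames = "gene")
      tidyr::pivot_longer(d, -"gene", names_to = "component", values_to = "loading")
    },
    eigenvalues = tibble::tibble(
      component = paste0("pc", seq_len(k)),
      eigenvalue = x$explained_variance,
      prop_variance = x$explained_variance / sum(x$explained_variance)))
}

#' @rdname tidy.sc_pca
#' @export
glance.sc_pca <- function(x, ...) {
  tibble::tibble(
    n_cells = x$n_cells,
    n_genes_used = length(x$genes_used),
    n_components = length(x$explained_variance),
    prop_variance_explained =
      sum(x$explained_variance) / max(sum(x$explained_variance), .Machine$double.eps),
    first_component_share =
      x$explained_variance[1] / max(sum(x$explained_variance), .Machine$double.eps))
}

#' Plot PCA scores
#'
#' Scatter of the first two principal-component scores.
#' @param object an `sc_pca`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sc_pca <- function(object, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = "PC1", y = "PC2", title = "PC scores") +
    ggplot2::theme_minimal()
}

#' Summarize a differential-expression table
#'
#' @param x an `sc_de` from [calculate_differential_expression()].
#' @param q_threshold significance threshold on the BH q-value.
#' @param ... unused.
#' @return one-row tibble.
#' @export
glance.sc_de <- function(x, q_threshold = 0.05, ...) {
  groups <- attr(x, "groups")
  tibble::tibble(
    group_a = groups[1], group_b = groups[2],
    n_genes = nrow(x),
    n_significant = if ("q_value" %in% names(x)) sum(x$q_value < q_threshold) else NA_integer_,
    max_abs_statistic = max(abs(x$statistic)))
}

#' Volcano plot of differential expression
#'
#' @param object an `sc_de`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sc_de <- function(object, ...) {
  d <- tibble::tibble(lfc = object$log2_fold_change,
                      nlp = -log10(pmax(object$p_value, 1e-300)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lfc, y = .data$nlp)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", title = "Differential expression") +
    ggplot2::theme_minimal()
}

#' Summarize benchmark timings per method and library size
#'
#' @param x an `sc_bench` timing tibble from [run_query_suite()].
#' @param ... unused.
#' @return tibble with mean, sd and normal-approximation 95% CI of wall
#'   time per (method, library size).
#' @export
tidy.sc_bench <- function(x, ...) {
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$method_label, .data$library_size),
    n = dplyr::n(),
    mean_time = mean(.data$wall_time),
    sd_time = stats::sd(.data$wall_time),
    .groups = "drop")
  out$ci_low <- out$mean_time - 1.96 * out$sd_time / sqrt(out$n)
  out$ci_high <- out$mean_time + 1.96 * out$sd_time / sqrt(out$n)
  out
}

#' Runtime curves for a benchmark
#'
#' Mean wall time versus library size per method, with 95% confidence
#' ribbons, on log-log axes.
#' @param object an `sc_bench` timing tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sc_bench <- function(object, ...) {
  d <- tidy.sc_bench(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$library_size, y = .data$mean_time,
                                  color = .data$method_label, fill = .data$method_label)) +
    ggplot2::geom_line() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$ci_low, 0), ymax = .data$ci_high),
                         alpha = 0.2, color = NA) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "library size (cells)", y = "wall time (s)",
                  color = "method", fill = "method") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data :=
NULL
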