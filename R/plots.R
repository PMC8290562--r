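# ggplot2 views of the main result types.

#' Boxplots of family sizes by taxonomic order
#'
#' One panel per ABC family, boxplots over taxonomic orders, with the
#' compact letters from the rank tests (when supplied) printed above each
#' box — the standard way family-size comparisons are displayed.
#'
#' @param matrix An `abc_family_matrix`.
#' @param tests Optional output of [family_size_tests()] providing the
#'   letters.
#' @param families Families to show (default all plus the total).
#' @return A ggplot object.
#' @export
plot_family_sizes <- function(matrix, tests = NULL,
                              families = c(ABC_FAMILIES, "total")) {
  families <- intersect(families, names(matrix))
  long <- matrix |>
    as_tibble() |>
    tidyr::pivot_longer(dplyr::all_of(families), names_to = "family",
                        values_to = "size") |>
    mutate(family = factor(.data$family, levels = families))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$taxon_order,
                                          y = .data$size,
                                          fill = .data$taxon_order)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_wrap(~family, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Family size (genes)", fill = "Order") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (!is.null(tests)) {
    lab <- purrr::map_dfr(names(tests$results), function(f) {
      g <- tests$results[[f]]$groups
      if (is.null(g$letter)) return(tibble())
      tibble(family = f, taxon_order = g$group, letter = g$letter)
    })
    tops <- long |>
      group_by(.data$family, .data$taxon_order) |>
      summarise(y = max(.data$size), .groups = "drop")
    lab <- lab |>
      mutate(family = factor(.data$family, levels = families)) |>
      dplyr::inner_join(tops, by = c("family", "taxon_order"))
    p <- p + ggplot2::geom_text(
      data = lab,
      mapping = ggplot2::aes(x = .data$taxon_order, y = .data$y,
                             label = .data$letter),
      vjust = -0.6, size = 3, inherit.aes = FALSE)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot abc_family_matrix
#' @export
autoplot.abc_family_matrix <- function(object, ...) {
  plot_family_sizes(object, ...)
}

#' Expression heatmap of z-transformed TPM
#'
#' Genes on the y axis, samples on the x axis, tile fill by per-gene
#' z-score.
#'
#' @param z Tibble from [zscore_by_gene()].
#' @param gene Gene id column name.
#' @return A ggplot object.
#' @export
plot_expression_heatmap <- function(z, gene = "gene") {
  samples <- setdiff(names(z), c(gene, "length"))
  long <- z |>
    select(dplyr::all_of(c(gene, samples))) |>
    tidyr::pivot_longer(dplyr::all_of(samples), names_to = "sample",
                        values_to = "zscore")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data[[gene]],
                                     fill = .data$zscore)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z(TPM)") +
    ggplot2::theme_minimal()
}

#' Benchmark deviation plot
#'
#' Signed percent deviation of predicted vs literature transporter totals
#' per species.
#'
#' @param x An `abc_benchmark`.
#' @return A ggplot object.
#' @export
plot_benchmark <- function(x) {
  ggplot2::ggplot(x$per_species,
                  ggplot2::aes(x = .data$species_id,
                               y = .data$pct_deviation)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "% deviation from literature") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @method autoplot abc_benchmark
#' @export
autoplot.abc_benchmark <- function(object, ...) plot_benchmark(object)

#' @rdname benchmark_counts
#' @param x An `abc_benchmark`.
#' @param ... Unused.
#' @method tidy abc_benchmark
#' @export
tidy.abc_benchmark <- function(x, ...) x$per_species

#' @rdname benchmark_counts
#' @method glance abc_benchmark
#' @export
glance.abc_benchmark <- function(x, ...) {
  tibble(n_species = nrow(x$per_species),
         mean_abs_deviation = x$mean_abs_deviation,
         mean_signed_deviation = x$mean_signed_deviation)
}
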