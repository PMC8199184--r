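#' Plot the fold-change class distribution
#'
#' Bar chart of the fraction of analyzable genes per FC class, the standard
#' display for a genome-wide co-localization scan.
#'
#' @param object A `coloc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coloc_result
#' @export
autoplot.coloc_result <- function(object, ...) {
  tab <- classify_fc(object)
  tab <- tab[tab$bin != "excluded", , drop = FALSE]
  tab$bin <- factor(tab$bin, levels = tab$bin)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$bin, y = .data$fraction)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(
      x = "co-localization likelihood fold-change",
      y = "fraction of genes",
      title = "Genes by co-localization fold-change class"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the inter-loci distance-decay curve
#'
#' @param object A `decay_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot decay_curve
#' @export
autoplot.decay_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$likelihood)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$k) +
    ggplot2::labs(
      x = "gene-order distance from gene of interest",
      y = "co-localization likelihood",
      title = "Co-localization likelihood across inter-loci distances"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the per-gene overlap histogram
#'
#' @param object An `overlap_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot overlap_result
#' @export
autoplot.overlap_result <- function(object, ...) {
  h <- summarize_overlaps(object)$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = .data$overlaps, y = .data$n_genes)) +
    ggplot2::geom_col(fill = "#31a354") +
    ggplot2::labs(
      x = "conserved neighbor partner events per homolog gene",
      y = "number of homolog genes",
      title = "Cross-species neighborhood overlap"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of pairwise D' (or r2)
#'
#' @param object An `ld_matrix`.
#' @param stat Which statistic to color, `"D_prime"` (default) or `"r2"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ld_matrix
#' @export
autoplot.ld_matrix <- function(object, stat = c("D_prime", "r2"), ...) {
  stat <- match.arg(stat)
  lev <- unique(c(object$variant_i, object$variant_j))
  df <- as_tibble(object) |>
    mutate(
      variant_i = factor(.data$variant_i, levels = lev),
      variant_j = factor(.data$variant_j, levels = lev)
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$variant_i, y = .data$variant_j,
    fill = .data[[stat]]
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(
      low = "white", high = "#d7301f", limits = c(0, 1),
      name = if (stat == "D_prime") "D'" else expression(r^2)
    ) +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = "Pairwise linkage disequilibrium"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
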