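# ggplot2 autoplot methods for the package's result types. All plots are
# plain ggplot objects and can be re-themed by the caller.

#' Plot a repeat map
#'
#' Arcs link the two copies of each repeat pair along the genome axis,
#' coloured by orientation and sized by repeat length.
#'
#' @param object An `mm_repeats` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.mm_repeats <- function(object, ...) {
  df <- as_tibble(object)
  L <- attr(object, "genome_length")
  df$mid1 <- (df$copy1_start + df$copy1_end) / 2
  df$mid2 <- (df$copy2_start + df$copy2_end) / 2
  ggplot2::ggplot(df) +
    ggplot2::geom_curve(
      ggplot2::aes(x = .data$mid1, xend = .data$mid2, y = 0, yend = 0,
                   colour = .data$orientation, linewidth = .data$size),
      curvature = -0.35, alpha = 0.7) +
    ggplot2::scale_linewidth_continuous(range = c(0.2, 2)) +
    ggplot2::scale_x_continuous(limits = c(0, L %||% NA),
                                labels = function(x) x / 1000) +
    ggplot2::labs(x = "genome position (kb)", y = NULL,
                  colour = "orientation", linewidth = "size (bp)",
                  title = "Repeat pairs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank(),
                   panel.grid.minor.y = ggplot2::element_blank())
}

#' Heatmap of pairwise rearrangement distances
#'
#' @param object An `mm_dcj` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.mm_dcj <- function(object, ...) {
  p <- attr(object, "pairs")
  both <- bind_rows(p, tibble(genome_a = p$genome_b, genome_b = p$genome_a,
                              distance = p$distance,
                              n_shared = p$n_shared))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$genome_a,
                                     y = .data$genome_b,
                                     fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$distance),
                       colour = "white", size = 3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "DCJ distance",
                  title = "Pairwise genome rearrangements") +
    ggplot2::theme_minimal()
}

#' Boxplot of per-intron length distributions
#'
#' @param object An `mm_intron_lengths` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.mm_intron_lengths <- function(object, ...) {
  df <- filter(as_tibble(object), .data$present)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$intron, y = .data$length)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 1,
                         alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "intron length (bp)",
                  title = "Intron length variation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Bar chart of a genome composition report
#'
#' @param object An `mm_composition` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.mm_composition <- function(object, ...) {
  df <- tidyr::pivot_longer(
    select(as_tibble(object), "coding_pct", "intron_pct",
           "intergenic_pct"),
    cols = dplyr::everything(), names_to = "category",
    values_to = "pct")
  df$category <- sub("_pct$", "", df$category)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$category,
                                                      -.data$pct),
                                   y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$pct)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "% of genome",
                  title = "Genome composition") +
    ggplot2::theme_minimal()
}

#' Bar chart of absolute substitution rates per branch
#'
#' @param object An `mm_rates` object (from [rate_table()]).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.mm_rates <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), cols = c("R_S", "R_N"),
                            names_to = "rate", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$branch, y = .data$value,
                                   fill = .data$rate)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "substitutions / site / Byr",
                  fill = NULL, title = "Absolute substitution rates") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
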