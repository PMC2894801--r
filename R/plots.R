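#' Ternary plot of unannotated probeset locations
#'
#' Draws each unannotated probeset as a point in the coding / border /
#' non-coding simplex (the standard triangle projection), coloured by its
#' flag: probesets that look like under-supported coding targets in blue,
#' probesets over non-protein-coding genes in red.
#'
#' @param profiles Output of [profile_probesets()].
#' @return A ggplot object.
#' @export
plot_unannotated_ternary <- function(profiles) {
  df <- profiles |>
    mutate(tx = .data$coding + 0.5 * .data$border,
           ty = sqrt(3) / 2 * .data$border)
  tri <- tibble(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tx, y = .data$ty)) +
    ggplot2::geom_path(data = tri, ggplot2::aes(x = .data$x, y = .data$y),
                       inherit.aes = FALSE, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$flag), alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      plain = "grey30", putative_coding = "blue",
      noncoding_gene = "red")) +
    ggplot2::annotate("text", x = c(-0.03, 1.03, 0.5),
                      y = c(-0.04, -0.04, sqrt(3) / 2 + 0.05),
                      label = c("non-coding", "coding", "border"),
                      size = 3.2) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL,
                  title = "Genomic context of unannotated probesets")
}

#' Histogram of genes per annotated probeset
#'
#' @param histogram Output of [genes_per_probeset()].
#' @return A ggplot object.
#' @export
plot_genes_per_probeset <- function(histogram) {
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = factor(.data$n_genes),
                               y = .data$n_probesets)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = "genes per probeset", y = "probesets",
                  title = "Probesets annotated to multiple genes") +
    ggplot2::theme_minimal()
}

#' Bar chart of SNP-by-match-status groups
#'
#' @param records Output of [snp_overlap()].
#' @return A ggplot object.
#' @export
plot_snp_groups <- function(records) {
  df <- records |> count(.data$group)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "probe placements",
                  title = "Placements by mismatch status and SNP overlap") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Mapping and annotation summary plot for a pipeline run
#'
#' @param object A `probemapr_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot probemapr_run
#' @export
autoplot.probemapr_run <- function(object, ...) {
  s <- object$summary
  df <- tibble(
    metric = c("probes mapped", "probesets annotated",
               "probesets multi-gene"),
    fraction = c(s$frac_probes_mapped, s$frac_probesets_annotated,
                 s$frac_probesets_multi_gene))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$fraction)) +
    ggplot2::geom_col(fill = "darkgreen", width = 0.6) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%",
                                                             100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Pipeline run summary") +
    ggplot2::theme_minimal()
}
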