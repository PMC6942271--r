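#' Karyotype paint of subgenome labels with a dominance side-track
#'
#' Draws each chromosome as a vertical ideogram: genes tinted by subgenome
#' on the left track, and, on the right track, the members of homeolog
#' pairs whose copy dominates on average.
#'
#' @param assignment Label tibble ([label_subgenomes()]).
#' @param gene_coords Tibble `gene`, `chrom`, `start`, `end`.
#' @param avg_dom Optional average-dominance tibble ([average_dominance()]).
#' @return A ggplot object.
#' @export
plot_karyotype <- function(assignment, gene_coords, avg_dom = NULL) {
  d <- inner_join(assignment, gene_coords, by = "gene") |>
    filter(.data$subgenome != "UNASSIGNED")
  p <- ggplot2::ggplot(d) +
    ggplot2::geom_segment(
      ggplot2::aes(x = 0, xend = 0.45, y = .data$start, yend = .data$start,
                   colour = .data$subgenome)
    ) +
    ggplot2::scale_colour_manual(
      values = c(SUB1 = "#c0392b", SUB2 = "#2980b9",
                 SELF_DOM = "#27ae60", PARTNER_DOM = "#f39c12")
    ) +
    ggplot2::facet_wrap(~chrom, nrow = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "position (bp)", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
  if (!is.null(avg_dom)) {
    dom_gene <- dplyr::bind_rows(
      tibble(gene = avg_dom$sub1_gene, dom = avg_dom$call == "SUB1_DOM"),
      tibble(gene = avg_dom$sub2_gene, dom = avg_dom$call == "SUB2_DOM")
    ) |> filter(.data$dom)
    d2 <- d[d$gene %in% dom_gene$gene, ]
    p <- p + ggplot2::geom_segment(
      data = d2,
      ggplot2::aes(x = 0.55, xend = 1, y = .data$start, yend = .data$start),
      colour = "#27ae60"
    )
  }
  p
}

#' Heatmap of the per-tissue correlation structure
#'
#' @param cm Output of [correlation_matrix()].
#' @return A ggplot object (tiles: tissue x comparison, fill = Spearman
#'   rho).
#' @export
plot_correlation_matrix <- function(cm) {
  ggplot2::ggplot(cm, ggplot2::aes(
    x = factor(.data$tissue, levels = unique(.data$tissue)),
    y = factor(.data$comparison,
               levels = rev(c("sub1_expr_abun", "sub2_expr_abun",
                              "expr_sub1_sub2", "abun_sub1_sub2"))),
    fill = .data$rho
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman ρ") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Tissue profile of one homeolog pair
#'
#' The per-pair view behind the four dominance archetypes: two lines, one
#' per homeolog, across the tissue panel.
#'
#' @param profiles Long profile tibble ([build_pair_profiles()]).
#' @param sub1_gene SUB1-side gene id selecting the pair.
#' @return A ggplot object.
#' @export
plot_pair_profile <- function(profiles, sub1_gene) {
  d <- profiles[profiles$sub1_gene == sub1_gene, ] |>
    tidyr::pivot_longer(c("v1", "v2"), names_to = "copy", values_to = "value") |>
    mutate(copy = if_else(.data$copy == "v1", "SUB1", "SUB2"))
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$tissue, levels = unique(.data$tissue)),
    y = .data$value, colour = .data$copy, group = .data$copy
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(SUB1 = "#c0392b", SUB2 = "#2980b9")) +
    ggplot2::labs(x = NULL, y = "value", colour = NULL, title = sub1_gene) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Isoform-count scatter for homeolog pairs
#'
#' Jittered SUB2-versus-SUB1 isoform counts with the identity line; colour
#' encodes the log2 count ratio.
#'
#' @param cmp Output of [compare_isoforms()].
#' @return A ggplot object.
#' @export
plot_isoform_comparison <- function(cmp) {
  ggplot2::ggplot(cmp, ggplot2::aes(x = .data$n1, y = .data$n2,
                                    colour = .data$log2_ratio)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "black") +
    ggplot2::geom_jitter(width = 0.2, height = 0.2, alpha = 0.6) +
    ggplot2::scale_colour_gradient2(low = "#2166ac", mid = "grey80",
                                    high = "#b2182b") +
    ggplot2::labs(x = "SUB1 isoforms", y = "SUB2 isoforms",
                  colour = "log2 ratio") +
    ggplot2::theme_minimal()
}
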