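#' Domain-architecture map of harvested hits
#'
#' Draws each protein as a horizontal line with its magnetochrome hits as
#' coloured segments, the classic tandem-architecture view.
#'
#' @param hits Hit tibble from [harvest_domains()].
#' @param records Optional record tibble supplying protein lengths.
#' @return A ggplot object.
#' @export
plot_domain_architecture <- function(hits, records = NULL) {
  hits <- dplyr::mutate(hits, protein_id = factor(.data$protein_id,
                                                  levels = rev(unique(.data$protein_id))))
  p <- ggplot2::ggplot(hits)
  if (!is.null(records)) {
    backbone <- tibble(protein_id = factor(records$id, levels = levels(hits$protein_id)),
                       len = nchar(records$sequence))
    p <- p + ggplot2::geom_segment(
      data = backbone,
      ggplot2::aes(x = 1, xend = .data$len, y = .data$protein_id,
                   yend = .data$protein_id),
      linewidth = 0.3, colour = "grey60"
    )
  }
  p +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$protein_id,
                   yend = .data$protein_id, colour = factor(.data$position_index)),
      linewidth = 3
    ) +
    ggplot2::labs(x = "residue position", y = NULL, colour = "MCR position") +
    ggplot2::theme_minimal()
}

#' Alignment tile plot
#'
#' @param object An `mcr_alignment`.
#' @param ... Unused.
#' @return A ggplot object showing residues as coloured tiles.
#' @export
autoplot.mcr_alignment <- function(object, ...) {
  mat <- alignment_matrix(object)
  df <- tibble(
    row = rep(factor(rownames(mat), levels = rev(rownames(mat))), ncol(mat)),
    column = rep(seq_len(ncol(mat)), each = nrow(mat)),
    residue = as.vector(mat)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$row,
                                   fill = .data$residue)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "alignment column", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none", axis.text.y = ggplot2::element_blank())
}

#' Retention-index view of a duplication verdict
#'
#' Bar chart of the retention indices of the family and position characters
#' with the decision margin drawn around their midpoint.
#'
#' @param object A `duplication_verdict`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.duplication_verdict <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$character,
                                   y = .data$retention_index,
                                   fill = .data$character)) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = mean(df$retention_index) +
                          c(-0.5, 0.5) * object$delta,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "retention index",
                  subtitle = paste("verdict:", object$verdict)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
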