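#' Scatter plot of an embedding coloured by cluster and by prior label
#'
#' One panel coloured by discovered cluster; when prior labels are given, a
#' second panel shows the same point positions coloured by prior label, so
#' the relation between new and known subtypes can be read off directly.
#'
#' @param coords samples x 2 coordinate matrix.
#' @param assignments per-sample cluster ids.
#' @param labels optional per-sample prior labels.
#' @return a ggplot (patchwork of two panels when labels are given).
#' @export
plotEmbedding <- function(coords, assignments, labels = NULL) {
  df <- data.frame(x = coords[, 1], y = coords[, 2],
                   cluster = factor(assignments))
  p1 <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                         colour = .data$cluster)) +
    ggplot2::geom_point(size = 1.2, alpha = 0.8) +
    ggplot2::labs(title = "Discovered clusters",
                  x = colnames(coords)[1], y = colnames(coords)[2]) +
    ggplot2::theme_minimal()
  if (is.null(labels)) return(p1)
  df$label <- factor(labels)
  p2 <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                         colour = .data$label)) +
    ggplot2::geom_point(size = 1.2, alpha = 0.8) +
    ggplot2::labs(title = "Prior subtype labels",
                  x = colnames(coords)[1], y = colnames(coords)[2]) +
    ggplot2::theme_minimal()
  patchwork::wrap_plots(p1, p2)
}

#' Export a t-SNE view of the subtyping result
#'
#' Computes a seed-controlled t-SNE embedding of the given matrix, writes
#' the coordinates as TSV, and renders the two-panel scatter (coloured by
#' cluster and, if given, by prior label) to a PNG. Both panels share the
#' identical point positions.
#'
#' @param x samples x features matrix to embed.
#' @param assignments per-sample cluster ids.
#' @param labels optional prior labels.
#' @param file output PNG path; the TSV is written next to it.
#' @param perplexity,maxIter,seed passed to \code{\link{tsneEmbed}}.
#' @param width,height figure size in inches.
#' @return invisibly, a list with \code{coords} and the plot object.
#' @export
exportTsnePlot <- function(x, assignments, labels = NULL,
                           file = "tsne.png", perplexity = 30,
                           maxIter = 500, seed = 1, width = 9,
                           height = 4.5) {
  coords <- tsneEmbed(x, perplexity = perplexity, maxIter = maxIter,
                      seed = seed)
  plt <- plotEmbedding(coords, assignments, labels)
  ggplot2::ggsave(file, plt, width = width, height = height, dpi = 150)
  tsv <- sub("\\.[A-Za-z]+$", ".tsv", file)
  ids <- rownames(coords)
  if (is.null(ids)) ids <- sprintf("sample%04d", seq_len(nrow(coords)))
  utils::write.table(
    data.frame(sample_id = ids, coords),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(coords = coords, plot = plt))
}
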