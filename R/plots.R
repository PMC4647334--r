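# Thin plotting wrappers; heatmaps delegate to pheatmap when available.

#' Heatmap of a regulation or logFC matrix
#'
#' Draws a clustered heatmap (average-linkage, Euclidean) of any numeric
#' matrix from the pipeline: GO count matrices, pathway fraction matrices,
#' extracellular logFC matrices. Requires the pheatmap package.
#'
#' @param m numeric matrix.
#' @param filename optional output file (png/pdf); NULL draws to the
#'   active device.
#' @param ... passed to \code{pheatmap::pheatmap}.
#' @return the pheatmap object, invisibly.
#' @export
plot_regulation_heatmap <- function(m, filename = NA, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_regulation_heatmap requires the pheatmap package")
  }
  p <- pheatmap::pheatmap(m, clustering_method = "average",
                          clustering_distance_rows = "euclidean",
                          clustering_distance_cols = "euclidean",
                          filename = filename, ...)
  invisible(p)
}
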