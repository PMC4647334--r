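# Per-pathway fractions of up-/down-regulated genes over a metabolic
# network, the >= 50% "highly affected" rule, and the two-block descriptor
# matrix used for clustering inducers by metabolic regulation.

as_pathway_sets <- function(pathways) {
  if (inherits(pathways, "metabolic_network")) pathways <- pathways$pathways
  if (!is.list(pathways)) stop("pathways must be a metabolic_network or a named list")
  pathways
}

#' Fractions of up- and down-regulated genes per pathway and inducer
#'
#' f_up(p, i) is the fraction of pathway p's genes significantly
#' up-regulated in inducer i (and analogously f_down). Fractions range from
#' 0 (no gene in the pathway differentially expressed) to 1 (every gene).
#' Genes belonging to several pathways contribute to each. Empty pathways
#' are excluded with a warning.
#'
#' @param sig_sets output of \code{significant_sets}.
#' @param pathways a \code{metabolic_network} or named list of gene sets.
#' @return object of class \code{pathway_regulation}: arrays \code{f_up},
#'   \code{f_down}, \code{f_total} (pathways x inducers) and
#'   \code{denominator} (pathway sizes).
#' @export
pathway_fractions <- function(sig_sets, pathways) {
  pw <- as_pathway_sets(pathways)
  empty <- !lengths(pw)
  if (any(empty)) {
    warning("excluding ", sum(empty), " empty pathways")
    pw <- pw[!empty]
  }
  inducers <- names(sig_sets)
  f_up <- matrix(0, nrow = length(pw), ncol = length(inducers),
                 dimnames = list(names(pw), inducers))
  f_down <- f_up
  denom <- lengths(pw)
  for (ind in inducers) {
    up <- sig_sets[[ind]]$up; down <- sig_sets[[ind]]$down
    f_up[, ind] <- vapply(pw, function(g) length(intersect(g, up)),
                          numeric(1)) / denom
    f_down[, ind] <- vapply(pw, function(g) length(intersect(g, down)),
                            numeric(1)) / denom
  }
  structure(list(f_up = f_up, f_down = f_down, f_total = f_up + f_down,
                 denominator = denom),
            class = "pathway_regulation")
}

#' @export
print.pathway_regulation <- function(x, ...) {
  cat("pathway_regulation:", nrow(x$f_up), "pathways x", ncol(x$f_up),
      "inducers; max f_total =", format(max(x$f_total), digits = 4), "\n")
  invisible(x)
}

#' Highly affected pathway-inducer pairs
#'
#' Pairs where at least the threshold fraction of the pathway's genes
#' (up- and down-regulated counted together) changed significantly; the
#' boundary value is included ("at least"). Sorted by inducer, then
#' decreasing total fraction.
#'
#' @param reg a \code{pathway_regulation}.
#' @param threshold total-fraction cutoff in [0, 1] (default 0.5).
#' @return data.frame inducer / pathway / f_up / f_down / f_total.
#' @export
highly_affected <- function(reg, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  hits <- which(reg$f_total >= threshold, arr.ind = TRUE)
  out <- data.frame(
    inducer = colnames(reg$f_total)[hits[, "col"]],
    pathway = rownames(reg$f_total)[hits[, "row"]],
    f_up = reg$f_up[hits], f_down = reg$f_down[hits],
    f_total = reg$f_total[hits],
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$inducer, -out$f_total, out$pathway), , drop = FALSE]
}

#' Two-block descriptor matrix for clustering inducers by pathway regulation
#'
#' Inducers as items; for every pathway two descriptor columns, its up- and
#' its down-regulated fraction. This is the input for hierarchical or
#' SOM/k-means clustering of the inducers by metabolic regulation pattern.
#'
#' @param reg a \code{pathway_regulation}.
#' @return inducers x (2 * pathways) numeric matrix, columns
#'   \code{<pathway>_up} and \code{<pathway>_down}.
#' @export
build_two_block_matrix <- function(reg) {
  up <- t(reg$f_up); down <- t(reg$f_down)
  colnames(up) <- paste0(colnames(up), "_up")
  colnames(down) <- paste0(colnames(down), "_down")
  cbind(up, down)
}

#' Export the pathway-inducer regulation graph (SIF)
#'
#' One edge per highly-affected pair, annotated with the dominant direction
#' and total fraction; a simple interchange form for network viewers.
#'
#' @param affected data.frame from \code{highly_affected}.
#' @param path output path.
#' @export
write_pathway_sif <- function(affected, path) {
  lines <- sprintf("%s\t%s\t%s", affected$inducer,
                   ifelse(affected$f_up >= affected$f_down,
                          "affects_up", "affects_down"),
                   affected$pathway)
  writeLines(lines, path)
  invisible(path)
}
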