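# Guilt-by-association: ternary significance profiles, exact profile
# matching of extracellular candidates against CAZy genes, and the typed
# gene-inducer association network.

#' Signed significance profiles per gene
#'
#' Encodes each gene's regulation across inducers on the ternary alphabet
#' {-1, 0, +1}: -1 significant down, +1 significant up, 0 not significant.
#'
#' @param de differential-expression table.
#' @return integer matrix genes x inducers with values in \{-1, 0, 1\}.
#' @export
signed_profiles <- function(de) {
  genes <- sort(unique(de$gene))
  inducers <- sort(unique(de$inducer))
  m <- matrix(0L, nrow = length(genes), ncol = length(inducers),
              dimnames = list(genes, inducers))
  sub <- de[de$direction != "none", , drop = FALSE]
  m[cbind(match(sub$gene, genes), match(sub$inducer, inducers))] <-
    ifelse(sub$direction == "up", 1L, -1L)
  m
}

#' Associate candidate genes to CAZy genes by shared expression profile
#'
#' An edge (c, g) is drawn from CAZy gene c to candidate g when the two
#' signed profiles are identical on c's support set S(c) (the inducers
#' where c is significant), S(c) has at least \code{min_support} members,
#' and g is significant (nonzero) on all of S(c). Candidates are expected
#' to be restricted to extracellular non-CAZy genes by the caller.
#'
#' @param cazy_genes CAZy gene ids (profile rows).
#' @param candidate_genes candidate gene ids (profile rows).
#' @param profiles matrix from \code{signed_profiles}.
#' @param min_support minimum support-set size (>= 1; default 2).
#' @return data.frame cazy_gene / candidate_gene / support.
#' @export
associate_profiles <- function(cazy_genes, candidate_genes, profiles,
                               min_support = 2) {
  if (min_support < 1) stop("min_support must be >= 1")
  cazy_genes <- intersect(cazy_genes, rownames(profiles))
  candidate_genes <- intersect(candidate_genes, rownames(profiles))
  out <- list()
  for (cz in cazy_genes) {
    support <- which(profiles[cz, ] != 0)
    if (length(support) < min_support) next
    for (g in setdiff(candidate_genes, cz)) {
      if (all(profiles[g, support] == profiles[cz, support])) {
        out[[length(out) + 1L]] <- data.frame(
          cazy_gene = cz, candidate_gene = g, support = length(support),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(cazy_gene = character(), candidate_gene = character(),
                      support = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Pearson-correlation association mode (optional alternative)
#'
#' Associates candidates to CAZy genes whose logFC values over the CAZy
#' gene's significant inducers correlate at least \code{r_min}, requiring
#' the candidate significant on the same support. Not the default rule.
#'
#' @param cazy_genes,candidate_genes gene id vectors.
#' @param de differential-expression table.
#' @param r_min minimum Pearson correlation.
#' @param min_support minimum support-set size.
#' @return data.frame cazy_gene / candidate_gene / r / support.
#' @export
associate_correlation <- function(cazy_genes, candidate_genes, de,
                                  r_min = 0.9, min_support = 3) {
  profiles <- signed_profiles(de)
  genes <- rownames(profiles)
  lfc <- de_logfc_matrix(de, genes)[, colnames(profiles), drop = FALSE]
  out <- list()
  for (cz in intersect(cazy_genes, genes)) {
    support <- which(profiles[cz, ] != 0)
    if (length(support) < min_support) next
    for (g in setdiff(intersect(candidate_genes, genes), cz)) {
      if (!all(profiles[g, support] != 0)) next
      r <- suppressWarnings(stats::cor(lfc[cz, support], lfc[g, support]))
      if (is.finite(r) && r >= r_min) {
        out[[length(out) + 1L]] <- data.frame(
          cazy_gene = cz, candidate_gene = g, r = r,
          support = length(support), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(cazy_gene = character(), candidate_gene = character(),
                      r = numeric(), support = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Build the typed gene-inducer association network
#'
#' Nodes are CAZy genes, associated candidate genes and inducers; edges are
#' gene-gene profile matches (directed CAZy to candidate) and gene-inducer
#' significance links (a gene is connected to every inducer in which it is
#' significant).
#'
#' @param edges data.frame from \code{associate_profiles}.
#' @param de differential-expression table.
#' @param cazy_genes,candidate_genes optional explicit node sets; default
#'   to the edge endpoints.
#' @return an \code{igraph} with vertex attribute \code{type} in
#'   \{cazy_gene, associated_gene, inducer\} and edge attribute
#'   \code{type} in \{profile_match, significant_in\}.
#' @export
build_association_network <- function(edges, de,
                                      cazy_genes = unique(edges$cazy_gene),
                                      candidate_genes = unique(edges$candidate_gene)) {
  genes <- unique(c(cazy_genes, candidate_genes))
  sig <- de[de$significant & de$gene %in% genes, , drop = FALSE]
  inducers <- sort(unique(sig$inducer))
  vertices <- data.frame(
    name = c(cazy_genes, setdiff(candidate_genes, cazy_genes), inducers),
    type = c(rep("cazy_gene", length(cazy_genes)),
             rep("associated_gene", length(setdiff(candidate_genes,
                                                   cazy_genes))),
             rep("inducer", length(inducers))),
    stringsAsFactors = FALSE)
  e_gene <- if (nrow(edges)) {
    data.frame(from = edges$cazy_gene, to = edges$candidate_gene,
               type = "profile_match", stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(), to = character(), type = character(),
               stringsAsFactors = FALSE)
  }
  e_ind <- data.frame(from = sig$gene, to = sig$inducer,
                      type = "significant_in", stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(rbind(e_gene, e_ind), directed = TRUE,
                                vertices = vertices)
}

#' Export a network as GraphML or SIF
#'
#' @param graph an igraph.
#' @param path output path.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_sif <- function(graph, path) {
  el <- igraph::as_data_frame(graph, what = "edges")
  writeLines(sprintf("%s\t%s\t%s", el$from,
                     if (nrow(el)) el$type else character(), el$to), path)
  invisible(path)
}
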