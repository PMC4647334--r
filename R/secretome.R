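# Secretome and CAZy regulation tables: extracellular logFC matrix for
# heatmap clustering, per-CAZy-class distinct-gene regulation counts, and
# the per-gene induction-substrate arrow table.

de_logfc_matrix <- function(de, genes) {
  inducers <- sort(unique(de$inducer))
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(inducers),
              dimnames = list(genes, inducers))
  sub <- de[de$gene %in% genes, , drop = FALSE]
  m[cbind(match(sub$gene, genes), match(sub$inducer, inducers))] <- sub$logFC
  m
}

#' Extracellular genes with significant regulation in at least one inducer
#'
#' Filters the differential-expression table to genes flagged extracellular
#' in the catalog that change significantly in one or more inducers, and
#' returns their full logFC row across inducers (heatmap clustering input).
#'
#' @param de differential-expression table (\code{de_table}).
#' @param catalog an \code{annotation_catalog} with extracellular flags.
#' @return list with \code{genes} (character) and \code{logfc} (genes x
#'   inducers matrix of log fold-changes for the retained genes).
#' @export
extracellular_table <- function(de, catalog) {
  extra <- names(catalog$extracellular)[catalog$extracellular]
  sig_genes <- unique(de$gene[de$significant])
  keep <- sort(intersect(extra, sig_genes))
  list(genes = keep, logfc = de_logfc_matrix(de, keep))
}

cazy_class_of <- function(family) sub("[0-9]+$", "", family)

#' Per-CAZy-class counts of regulated genes
#'
#' A gene counts as "up" if significantly up-regulated in at least one
#' inducer and "down" if down-regulated in at least one (a gene can be
#' both; it then increments both tallies and the overlap column). Counts
#' are distinct genes, not gene-inducer events.
#'
#' @param de differential-expression table.
#' @param catalog an \code{annotation_catalog} with CAZy family labels
#'   (families such as \code{GH7} are grouped into classes GH, GT, PL, CE,
#'   AA by stripping the family number).
#' @return data.frame cazy_class / n_up / n_down / n_overlap / n_regulated.
#' @export
cazy_regulation_summary <- function(de, catalog) {
  cazy_genes <- names(catalog$cazy)[!is.na(catalog$cazy)]
  sub <- de[de$gene %in% cazy_genes & de$significant, , drop = FALSE]
  classes <- sort(unique(cazy_class_of(catalog$cazy[cazy_genes])))
  rows <- lapply(classes, function(cl) {
    members <- cazy_genes[cazy_class_of(catalog$cazy[cazy_genes]) == cl]
    d <- sub[sub$gene %in% members, , drop = FALSE]
    up <- unique(d$gene[d$direction == "up"])
    down <- unique(d$gene[d$direction == "down"])
    data.frame(cazy_class = cl, n_up = length(up), n_down = length(down),
               n_overlap = length(intersect(up, down)),
               n_regulated = length(union(up, down)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Induction-substrate table with per-inducer regulation arrows
#'
#' One row per requested gene: putative function label, CAZy family,
#' extracellular flag and one arrow per inducer (up-arrow for significant
#' up-regulation, down-arrow for down, em-dash for no significant change),
#' mirroring the printed induction-substrate listings in this field.
#'
#' @param genes gene ids to tabulate.
#' @param de differential-expression table.
#' @param catalog an \code{annotation_catalog}.
#' @param functions optional named character vector of function labels.
#' @return data.frame: gene, function, cazy_family, extracellular, one
#'   arrow column per inducer.
#' @export
induction_table <- function(genes, de, catalog, functions = NULL) {
  unknown <- setdiff(genes, unique(de$gene))
  if (length(unknown)) {
    stop("unknown genes: ", paste(unknown, collapse = ", "))
  }
  inducers <- sort(unique(de$inducer))
  arrows <- matrix("—", nrow = length(genes), ncol = length(inducers),
                   dimnames = list(genes, inducers))
  sub <- de[de$gene %in% genes & de$direction != "none", , drop = FALSE]
  arrows[cbind(match(sub$gene, genes), match(sub$inducer, inducers))] <-
    ifelse(sub$direction == "up", "↑", "↓")
  data.frame(
    gene = genes,
    putative_function = if (is.null(functions)) NA_character_
                        else unname(functions[genes]),
    cazy_family = unname(catalog$cazy[genes]),
    extracellular = unname(catalog$extracellular[genes]),
    arrows, check.names = FALSE, row.names = NULL, stringsAsFactors = FALSE)
}

#' Write an induction table as UTF-8 TSV
#'
#' @param tab data.frame from \code{induction_table}.
#' @param path output path.
#' @export
write_induction_table <- function(tab, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_induction_table
#' @export
read_induction_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    encoding = "UTF-8")
}
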