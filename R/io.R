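# TSV / GMT / reaction-table readers and writers shared across the pipeline.

#' Read a numeric matrix from TSV
#'
#' Expects row identifiers in the first column and one named column per
#' sample/descriptor. Used for expression matrices, GO count matrices and
#' descriptor matrices alike.
#'
#' @param path file path.
#' @return numeric matrix with rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a numeric matrix to TSV
#'
#' @param m matrix with rownames and colnames.
#' @param path output path.
#' @param id_col name for the identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write gene sets in GMT format
#'
#' One line per set: set name, description, then member genes, tab-separated.
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a reaction equation string
#'
#' Equations use the form \code{"A + 2 B => C"} (irreversible) or
#' \code{"A <=> B"} (reversible). Leading stoichiometric coefficients are
#' stripped; only metabolite identity is retained, since the pipeline never
#' uses stoichiometry beyond reactant/product membership.
#'
#' @param equation equation string.
#' @return list with \code{reactants}, \code{products} (character vectors)
#'   and \code{reversible} (logical).
#' @export
parse_equation <- function(equation) {
  reversible <- grepl("<=>", equation, fixed = TRUE)
  arrow <- if (reversible) "<=>" else "=>"
  sides <- strsplit(equation, arrow, fixed = TRUE)[[1]]
  if (length(sides) != 2L) {
    stop("malformed reaction equation: ", equation)
  }
  split_side <- function(s) {
    terms <- strsplit(s, "+", fixed = TRUE)[[1]]
    terms <- trimws(terms)
    terms <- sub("^[0-9.]+ +", "", terms)  # strip coefficients
    terms[nzchar(terms)]
  }
  list(
    reactants  = split_side(sides[1]),
    products   = split_side(sides[2]),
    reversible = reversible
  )
}

#' Read a metabolic reaction table
#'
#' Columns: \code{reaction_id}, \code{equation}, \code{enzyme_name},
#' \code{gene_association} (\code{;}-separated gene ids, may be empty) and
#' optionally \code{pathway}. Returns a \code{metabolic_network} object: the
#' parsed reaction list plus a pathway-to-gene-set map derived from the
#' pathway column (when present).
#'
#' @param path TSV path.
#' @return a \code{metabolic_network} object.
#' @export
read_reaction_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("reaction_id", "equation", "enzyme_name", "gene_association")
  missing <- setdiff(required, colnames(df))
  if (length(missing)) stop("reaction table lacks columns: ",
                            paste(missing, collapse = ", "))
  reactions <- lapply(seq_len(nrow(df)), function(i) {
    eq <- parse_equation(df$equation[i])
    genes <- strsplit(df$gene_association[i], ";", fixed = TRUE)[[1]]
    genes <- trimws(genes[nzchar(trimws(genes))])
    list(
      id          = df$reaction_id[i],
      equation    = df$equation[i],
      reactants   = eq$reactants,
      products    = eq$products,
      reversible  = eq$reversible,
      enzyme      = df$enzyme_name[i],
      genes       = genes,
      pathway     = if ("pathway" %in% colnames(df)) df$pathway[i] else NA_character_
    )
  })
  names(reactions) <- df$reaction_id
  pathways <- list()
  if ("pathway" %in% colnames(df)) {
    for (r in reactions) {
      if (!is.na(r$pathway) && nzchar(r$pathway) && length(r$genes)) {
        pathways[[r$pathway]] <- union(pathways[[r$pathway]], r$genes)
      }
    }
  }
  metabolic_network(reactions, pathways)
}

#' Construct a metabolic network object
#'
#' @param reactions list of reaction records (id, equation, reactants,
#'   products, reversible, enzyme, genes, pathway).
#' @param pathways named list mapping pathway id to gene set.
#' @return object of class \code{metabolic_network}.
#' @export
metabolic_network <- function(reactions, pathways = list()) {
  for (r in reactions) {
    if (!length(r$reactants) || !length(r$products)) {
      stop("reaction ", r$id, " must have at least one reactant and one product")
    }
  }
  if (length(pathways) && any(!lengths(pathways))) {
    stop("pathway gene sets must be nonempty")
  }
  structure(list(reactions = reactions, pathways = pathways),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  mets <- unique(unlist(lapply(x$reactions, function(r) c(r$reactants, r$products))))
  cat("metabolic_network:", length(x$reactions), "reactions,",
      length(mets), "unique metabolites,",
      length(x$pathways), "pathways\n")
  invisible(x)
}

#' Write a metabolic network as a TSV reaction table
#'
#' @param network a \code{metabolic_network}.
#' @param path output path.
#' @export
write_reaction_table <- function(network, path) {
  df <- data.frame(
    reaction_id      = vapply(network$reactions, `[[`, "", "id"),
    equation         = vapply(network$reactions, `[[`, "", "equation"),
    enzyme_name      = vapply(network$reactions, `[[`, "", "enzyme"),
    gene_association = vapply(network$reactions, function(r)
      paste(r$genes, collapse = ";"), ""),
    pathway          = vapply(network$reactions, function(r)
      if (is.na(r$pathway)) "" else r$pathway, ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
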