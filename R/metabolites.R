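# Metabolite -> reaction -> enzyme -> gene -> per-inducer logFC association
# tables for candidate transcription-factor-binding metabolites, with
# direction-consistency classification and a packaged reference fixture.

#' Reactions in which a metabolite participates
#'
#' All and only the reactions containing the metabolite among reactants or
#' products; reversible reactions match on either side. A metabolite absent
#' from the network yields an empty list with a warning, not an error.
#'
#' @param metabolite metabolite id.
#' @param network a \code{metabolic_network}.
#' @return character vector of reaction ids.
#' @export
reactions_of <- function(metabolite, network) {
  stopifnot(inherits(network, "metabolic_network"))
  hit <- vapply(network$reactions, function(r)
    metabolite %in% c(r$reactants, r$products), logical(1))
  if (!any(hit)) {
    warning("metabolite not found in any reaction: ", metabolite)
    return(character())
  }
  names(network$reactions)[hit]
}

#' Build the metabolite-reaction-enzyme-gene logFC association table
#'
#' One row per (metabolite, reaction, gene) triple for every reaction the
#' metabolite participates in and every gene associated with that reaction.
#' Each row carries the gene's log fold-change per inducer; cells where the
#' gene is not significant in that inducer are missing (NA, serialized as
#' \code{"-"}). Gene association strings listing several genes produce one
#' row per gene.
#'
#' @param metabolites metabolite ids (e.g. candidate strong binders).
#' @param network a \code{metabolic_network}.
#' @param de differential-expression table.
#' @return object of class \code{metabolite_gene_table}: a data.frame with
#'   columns metabolite, reaction, enzyme, gene, then one numeric column
#'   per inducer.
#' @export
build_metabolite_table <- function(metabolites, network, de) {
  inducers <- unique(de$inducer)
  rows <- list()
  for (met in metabolites) {
    rids <- suppressWarnings(reactions_of(met, network))
    for (rid in rids) {
      r <- network$reactions[[rid]]
      for (g in r$genes) {
        lfc <- stats::setNames(rep(NA_real_, length(inducers)), inducers)
        sub <- de[de$gene == g & de$significant, , drop = FALSE]
        lfc[sub$inducer] <- sub$logFC
        rows[[length(rows) + 1L]] <- c(
          list(metabolite = met, reaction = r$equation, enzyme = r$enzyme,
               gene = g), as.list(lfc))
      }
    }
  }
  df <- if (length(rows)) {
    do.call(rbind, lapply(rows, function(x)
      as.data.frame(x, check.names = FALSE, stringsAsFactors = FALSE)))
  } else {
    empty <- data.frame(metabolite = character(), reaction = character(),
                        enzyme = character(), gene = character(),
                        stringsAsFactors = FALSE)
    for (ind in inducers) empty[[ind]] <- numeric()
    empty
  }
  structure(df, class = c("metabolite_gene_table", "data.frame"),
            inducers = inducers, metabolites = metabolites)
}

mgt_inducers <- function(table) {
  ind <- attr(table, "inducers")
  if (is.null(ind)) ind <- setdiff(colnames(table),
                                   c("metabolite", "reaction", "enzyme",
                                     "gene"))
  ind
}

#' Classify per-metabolite direction consistency
#'
#' A metabolite is down-consistent when every non-missing logFC cell of
#' every associated gene is negative, up-consistent when every cell is
#' positive, mixed when both signs occur, and no-data when no cell is
#' observed. Invariant to row and column order.
#'
#' @param table a \code{metabolite_gene_table}.
#' @return data.frame metabolite / call with call in
#'   \{down_consistent, up_consistent, mixed, no_data\}.
#' @export
classify_consistency <- function(table) {
  inducers <- mgt_inducers(table)
  # metabolites that produced no table rows still get a no_data call
  mets <- unique(c(attr(table, "metabolites"), table$metabolite))
  call <- vapply(mets, function(met) {
    cells <- unlist(table[table$metabolite == met, inducers])
    cells <- cells[!is.na(cells)]
    if (!length(cells)) "no_data"
    else if (all(cells < 0)) "down_consistent"
    else if (all(cells > 0)) "up_consistent"
    else "mixed"
  }, character(1))
  data.frame(metabolite = mets, call = unname(call),
             stringsAsFactors = FALSE)
}

#' Summary statistics over a gene's logFC cells
#'
#' Minimum, maximum, mean and count over the non-missing per-inducer logFC
#' cells of every table row carrying the gene.
#'
#' @param table a \code{metabolite_gene_table}.
#' @param gene gene id present in the table.
#' @return list with \code{min}, \code{max}, \code{mean},
#'   \code{n_nonmissing}.
#' @export
row_stats <- function(table, gene) {
  if (!gene %in% table$gene) stop("gene not present in table: ", gene)
  cells <- unlist(table[table$gene == gene, mgt_inducers(table)])
  cells <- cells[!is.na(cells)]
  if (!length(cells)) {
    return(list(min = NA_real_, max = NA_real_, mean = NA_real_,
                n_nonmissing = 0L))
  }
  list(min = min(cells), max = max(cells), mean = mean(cells),
       n_nonmissing = length(cells))
}

#' Write / read a metabolite-gene table as TSV (missing cells as "-")
#'
#' @param table a \code{metabolite_gene_table}.
#' @param path file path.
#' @export
write_metabolite_table <- function(table, path) {
  out <- as.data.frame(table, check.names = FALSE)
  for (ind in mgt_inducers(table)) {
    out[[ind]] <- ifelse(is.na(out[[ind]]), "-",
                         format(out[[ind]], trim = TRUE, scientific = FALSE))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metabolite_table
#' @export
read_metabolite_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  inducers <- setdiff(colnames(df), c("metabolite", "reaction", "enzyme",
                                      "gene"))
  for (ind in inducers) {
    df[[ind]] <- suppressWarnings(as.numeric(ifelse(df[[ind]] == "-",
                                                    NA, df[[ind]])))
  }
  structure(df, class = c("metabolite_gene_table", "data.frame"),
            inducers = inducers)
}

# md5 of the packaged fixture, frozen at packaging time
.strong_binder_fixture_md5 <- "636bba9e4dca440154a0f21b33985a1f"

#' Load the packaged strong-binder association table
#'
#' The packaged reference table associates six strong-binder candidate
#' metabolites (sulfite, sulfate, uroporphyrinogen III, ethanolamine
#' phosphate, D-glyceraldehyde 3-phosphate, taurine) with their reactions,
#' catalyzing enzymes, gene ids and per-inducer log fold-changes against
#' glucose across ten oligosaccharide inducers; \code{"-"} marks cells with
#' no significant change. The file checksum is verified on load.
#'
#' @return a \code{metabolite_gene_table} with 6 metabolites.
#' @export
load_strong_binder_table <- function() {
  path <- system.file("extdata", "strong_binder_logfc.tsv",
                      package = "cazyreg", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, .strong_binder_fixture_md5)) {
    stop("strong-binder fixture failed its checksum: ", md5)
  }
  read_metabolite_table(path)
}

#' Check metabolite-reaction membership of a table against a network
#'
#' Verifies that every (metabolite, reaction) pair in the table names a
#' reaction whose reactants or products contain the metabolite.
#'
#' @param table a \code{metabolite_gene_table}.
#' @param network a \code{metabolic_network} (matched on equation string).
#' @return TRUE invisibly; stops on a violation.
#' @export
check_membership <- function(table, network) {
  eqs <- vapply(network$reactions, `[[`, "", "equation")
  for (i in seq_len(nrow(table))) {
    rid <- names(eqs)[match(table$reaction[i], eqs)]
    if (is.na(rid)) stop("unknown reaction equation: ", table$reaction[i])
    r <- network$reactions[[rid]]
    if (!table$metabolite[i] %in% c(r$reactants, r$products)) {
      stop("membership violation: ", table$metabolite[i], " not in ",
           table$reaction[i])
    }
  }
  invisible(TRUE)
}
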