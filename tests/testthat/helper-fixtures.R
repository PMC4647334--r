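# Small in-code fixtures shared across test files.

# Expression matrix from explicit per-condition replicate vectors:
# values is a named list condition -> (genes x reps) matrix or vector.
make_expr <- function(values, reference = "Glucose") {
  conds <- names(values)
  mats <- lapply(values, function(v) {
    if (is.null(dim(v))) v <- matrix(v, nrow = 1)
    v
  })
  n_genes <- nrow(mats[[1]])
  m <- do.call(cbind, mats)
  colnames(m) <- unlist(lapply(conds, function(cn)
    paste0(cn, "_r", seq_len(ncol(mats[[cn]])))))
  rownames(m) <- paste0("g", seq_len(n_genes))
  attr(m, "reference") <- reference
  m
}

# Minimal hand-built annotation catalog.
make_catalog <- function(genes,
                         go = stats::setNames(rep(list(character()),
                                                  length(genes)), genes),
                         go_terms = data.frame(term = character(),
                                               ontology_class = character(),
                                               stringsAsFactors = FALSE),
                         pathways = list(),
                         cazy = stats::setNames(rep(NA_character_,
                                                    length(genes)), genes),
                         extracellular = stats::setNames(
                           rep(FALSE, length(genes)), genes)) {
  structure(list(genes = genes, go = go, go_terms = go_terms,
                 pathways = pathways, cazy = cazy,
                 extracellular = extracellular),
            class = "annotation_catalog")
}

# Hand-built DE table row block.
de_rows <- function(gene, inducer, logFC, p_value = 0.01,
                    significant = TRUE) {
  n <- max(length(gene), length(inducer), length(logFC))
  if (n == 0) {
    return(data.frame(gene = character(), inducer = character(),
                      logFC = numeric(), p_value = numeric(),
                      significant = logical(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  gene <- rep_len(gene, n); inducer <- rep_len(inducer, n)
  logFC <- rep_len(logFC, n)
  significant <- rep_len(significant, n)
  direction <- ifelse(!significant | logFC == 0, "none",
                      ifelse(logFC > 0, "up", "down"))
  data.frame(gene = gene, inducer = inducer, logFC = logFC,
             p_value = rep_len(p_value, n), significant = significant,
             direction = direction, stringsAsFactors = FALSE)
}

# Adjusted Rand index between two labelings (independent of mclust).
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_i * sum_j / n
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}
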