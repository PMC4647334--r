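# GO-term x inducer count matrix, row standardization, and correlation-based
# descriptor ranking under cross-validation.

#' Build the GO-term by inducer significant-gene count matrix
#'
#' Cell (t, i) counts the significant genes in inducer i annotated to GO
#' term t. A gene annotated to several terms contributes once to each of
#' them (no deduplication across terms). The fraction of significant genes
#' with at least one GO annotation is reported per inducer as the
#' \code{coverage} attribute.
#'
#' @param sig_sets output of \code{significant_sets}.
#' @param catalog an \code{annotation_catalog}.
#' @return integer matrix (terms x inducers) with attributes
#'   \code{ontology_class} (per row) and \code{coverage} (per column).
#' @export
build_go_matrix <- function(sig_sets, catalog) {
  if (!length(catalog$go_terms$term)) stop("annotation catalog is empty")
  terms <- sort(catalog$go_terms$term)
  inducers <- names(sig_sets)
  m <- matrix(0L, nrow = length(terms), ncol = length(inducers),
              dimnames = list(terms, inducers))
  coverage <- stats::setNames(numeric(length(inducers)), inducers)
  for (ind in inducers) {
    sig <- unique(c(sig_sets[[ind]]$up, sig_sets[[ind]]$down))
    ann <- catalog$go[sig]
    ann[vapply(ann, is.null, logical(1))] <- list(character())
    coverage[ind] <- if (length(sig))
      mean(lengths(ann) > 0) else NA_real_
    tab <- table(factor(unlist(ann), levels = terms))
    m[, ind] <- as.integer(tab)
  }
  attr(m, "ontology_class") <- catalog$go_terms$ontology_class[
    match(terms, catalog$go_terms$term)]
  attr(m, "coverage") <- coverage
  m
}

#' Row-standardize a matrix (z-scores with population standard deviation)
#'
#' Each row is centered and scaled to mean 0, sd 1 (population sd, i.e.
#' divisor n). Rows with zero variance map to all-zero and are flagged in
#' the \code{constant_rows} attribute.
#'
#' @param m numeric matrix with >= 2 columns.
#' @return standardized matrix with attribute \code{constant_rows}.
#' @export
standardize_matrix <- function(m) {
  if (ncol(m) < 2) stop("standardization needs >= 2 columns")
  mu <- rowMeans(m)
  sd_pop <- sqrt(rowMeans((m - mu)^2))
  constant <- sd_pop == 0
  z <- (m - mu) / ifelse(constant, 1, sd_pop)
  z[constant, ] <- 0
  attr(z, "constant_rows") <- rownames(m)[constant]
  z
}

# Correlation ratio (eta) between a numeric vector and a categorical label:
# sqrt of the between-group share of total sum of squares. Equals |Pearson r|
# when the label is a binary indicator.
eta_correlation <- function(x, labels) {
  labels <- as.factor(labels)
  tot <- sum((x - mean(x))^2)
  if (tot == 0 || nlevels(droplevels(labels)) < 2) return(0)
  gm <- tapply(x, labels, mean)
  gn <- tapply(x, labels, length)
  between <- sum(gn * (gm[levels(labels)] - mean(x))^2, na.rm = TRUE)
  sqrt(max(0, min(1, between / tot)))
}

#' Correlation-based feature-selection merit of a descriptor subset
#'
#' merit = k * mean(descriptor-label correlation) /
#'         sqrt(k + k (k - 1) * mean(|descriptor-descriptor correlation|)),
#' where descriptor-label correlation is the correlation ratio (eta) against
#' the cluster labels and descriptor-descriptor correlation is Pearson.
#' For a single descriptor this reduces to its label correlation.
#'
#' @param m descriptors x items matrix.
#' @param subset descriptor (row) names forming the subset.
#' @param labels per-item cluster labels.
#' @return the merit (numeric scalar).
#' @export
cfs_merit <- function(m, subset, labels) {
  k <- length(subset)
  if (k == 0) return(0)
  r_cf <- mean(vapply(subset, function(d) eta_correlation(m[d, ], labels),
                      numeric(1)))
  if (k == 1) return(r_cf)
  cm <- abs(stats::cor(t(m[subset, , drop = FALSE])))
  cm[!is.finite(cm)] <- 0
  r_ff <- mean(cm[upper.tri(cm)])
  k * r_cf / sqrt(k + k * (k - 1) * r_ff)
}

#' Rank descriptors by cross-validated label correlation merit
#'
#' Scores each descriptor (row) by its correlation-based feature-selection
#' merit against the item cluster labels, averaged over cross-validation
#' folds that each hold out a subset of items. With as many folds as items
#' (the default when folds >= number of items) this is leave-one-out. Ties
#' are broken lexicographically by descriptor name.
#'
#' @param m descriptors x items matrix.
#' @param labels per-item cluster assignment (named or in column order).
#' @param folds number of CV folds (default 10; capped at the item count).
#' @param seed seed for the fold partition.
#' @return data.frame with columns descriptor, merit, rank (1 = highest).
#' @export
rank_descriptors <- function(m, labels, folds = 10, seed = 1L) {
  if (ncol(m) < 2) stop("need >= 2 items to rank descriptors")
  if (!is.null(names(labels))) labels <- labels[colnames(m)]
  if (length(labels) != ncol(m)) stop("labels must cover every item")
  folds <- min(folds, ncol(m))
  # fold membership is keyed to sorted item names so the ranking is
  # invariant to column permutation
  ord <- if (!is.null(colnames(m))) order(colnames(m)) else seq_len(ncol(m))
  fold_of <- integer(ncol(m))
  fold_of[ord] <- with_seed(seed,
    sample(rep(seq_len(folds), length.out = ncol(m))))
  merits <- vapply(rownames(m), function(d) {
    mean(vapply(seq_len(folds), function(f) {
      train <- fold_of != f
      eta_correlation(m[d, train], labels[train])
    }, numeric(1)))
  }, numeric(1))
  ord <- order(-merits, rownames(m))
  out <- data.frame(descriptor = rownames(m)[ord], merit = merits[ord],
                    rank = seq_along(ord), row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}

#' Write a GO count matrix with ontology classes as TSV
#'
#' @param m matrix from \code{build_go_matrix}.
#' @param path output path.
#' @export
write_go_matrix <- function(m, path) {
  df <- data.frame(term = rownames(m),
                   ontology_class = attr(m, "ontology_class"),
                   m, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
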