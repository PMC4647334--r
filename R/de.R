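# Per-inducer differential expression against the glucose reference:
# Welch two-sample t-tests on log2 intensities, vectorized across genes.

conditions_of <- function(m) sub("_r[0-9]+$", "", colnames(m))

#' Pairwise differential expression of one inducer against the reference
#'
#' Per gene, a two-sample t-test on log2 values of the inducer replicates
#' against the reference replicates. The default pools the within-group
#' variances (Student's test), which is exact at triplicate sample sizes
#' under a common noise model; \code{var_equal = FALSE} gives the Welch
#' unequal-variance variant, which is conservative at n = 3. The log2
#' fold-change is mean(inducer) - mean(reference), so positive values mean
#' up-regulation in the inducer. When both groups have zero within-group
#' variance and equal means the p-value is 1 (no evidence, not an error).
#' Genes with missing values in any used sample are dropped with a warning.
#'
#' @param expr genes x samples log2 matrix, colnames
#'   \code{<condition>_r<rep>}; the reference condition defaults to the
#'   matrix's \code{reference} attribute, else \code{"Glucose"}.
#' @param inducer condition to compare against the reference.
#' @param reference reference condition name.
#' @param alpha significance level (default 0.05).
#' @param adjust multiple-testing policy, \code{"none"} (raw p < alpha, the
#'   default) or \code{"BH"} (Benjamini-Hochberg across genes).
#' @param var_equal pool within-group variances (default TRUE).
#' @return data.frame with columns gene, inducer, logFC, p_value,
#'   significant, direction (\code{up}/\code{down}/\code{none}).
#' @export
pairwise_de <- function(expr, inducer, reference = NULL, alpha = 0.05,
                        adjust = c("none", "BH"), var_equal = TRUE) {
  adjust <- match.arg(adjust)
  if (is.null(reference)) {
    reference <- attr(expr, "reference")
    if (is.null(reference)) reference <- "Glucose"
  }
  cond <- conditions_of(expr)
  if (!inducer %in% cond) stop("inducer not present in matrix: ", inducer)
  if (!reference %in% cond) stop("reference not present in matrix: ", reference)
  x <- expr[, cond == inducer, drop = FALSE]
  y <- expr[, cond == reference, drop = FALSE]
  if (ncol(x) < 2 || ncol(y) < 2) {
    stop("both conditions need >= 2 replicates")
  }
  bad <- rowSums(is.na(x)) + rowSums(is.na(y)) > 0
  if (any(bad)) {
    warning(sum(bad), " genes dropped due to missing values")
    x <- x[!bad, , drop = FALSE]; y <- y[!bad, , drop = FALSE]
  }
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  if (var_equal) {
    vp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- vp * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate groups: zero variance in both
  zerovar <- se2 == 0
  p[zerovar & m1 == m2] <- 1
  p[zerovar & m1 != m2] <- .Machine$double.xmin
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1]
  p_used <- if (adjust == "BH") stats::p.adjust(p, method = "BH") else p
  significant <- p_used < alpha
  logfc <- m1 - m2
  direction <- ifelse(!significant | logfc == 0, "none",
                      ifelse(logfc > 0, "up", "down"))
  data.frame(gene = rownames(x), inducer = inducer, logFC = logfc,
             p_value = p, significant = significant, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential expression of every inducer against the reference
#'
#' @inheritParams pairwise_de
#' @param inducers conditions to test; defaults to every non-reference
#'   condition in the matrix.
#' @return stacked data.frame (one \code{pairwise_de} block per inducer).
#' @export
de_table <- function(expr, inducers = NULL, reference = NULL, alpha = 0.05,
                     adjust = c("none", "BH"), var_equal = TRUE) {
  adjust <- match.arg(adjust)
  if (is.null(reference)) {
    reference <- attr(expr, "reference")
    if (is.null(reference)) reference <- "Glucose"
  }
  if (is.null(inducers)) {
    inducers <- setdiff(unique(conditions_of(expr)), reference)
  }
  do.call(rbind, lapply(inducers, function(ind)
    pairwise_de(expr, ind, reference = reference, alpha = alpha,
                adjust = adjust, var_equal = var_equal)))
}

#' Up- and down-regulated gene sets per inducer
#'
#' @param de a differential-expression table from \code{de_table}.
#' @return named list: inducer -> list(up = genes, down = genes).
#' @export
significant_sets <- function(de) {
  if (!nrow(de)) return(stats::setNames(list(), character()))
  lapply(split(de, de$inducer), function(d)
    list(up = d$gene[d$direction == "up"],
         down = d$gene[d$direction == "down"]))
}

#' Write / read a differential-expression table as TSV
#'
#' @param de the table.
#' @param path file path.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(gene = "character", inducer = "character",
                                   direction = "character"))
}
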