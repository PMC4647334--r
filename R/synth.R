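# Synthetic study generator: expression matrices, annotation catalogs,
# metabolic networks and descriptor matrices with planted ground truth.
# Every downstream stage of the pipeline is validated against the structure
# planted here.

#' Configuration for the synthetic-data generators
#'
#' Defaults emulate the study design the pipeline targets: ten chemically
#' defined oligosaccharide inducers plus a glucose reference, three
#' biological replicates, log2-scale intensities with Gaussian replicate
#' noise, and an annotation universe of 58 GO terms, 66 metabolic pathways
#' and CAZy families over a subset of genes.
#'
#' @param n_genes number of genes.
#' @param inducers character vector of inducer condition names.
#' @param reference name of the reference carbon source.
#' @param n_replicates replicates per condition (>= 2).
#' @param de_fraction_per_inducer fraction of genes planted as differentially
#'   expressed per inducer, in [0, 1].
#' @param effect_size_logfc mean absolute log2 fold-change of planted genes.
#' @param noise_sd replicate noise standard deviation on the log2 scale (> 0).
#' @param n_go_terms,n_pathways,n_cazy_families annotation universe sizes;
#'   the pathway default is 66 at full scale, scaled down for small gene
#'   universes so every pathway stays nonempty.
#' @param n_pathway_genes number of genes partitioned among pathways.
#' @param cazy_fraction fraction of genes assigned a CAZy family.
#' @param extracellular_fraction fraction of genes flagged extracellular.
#' @param seed integer seed; identical seeds give bit-identical outputs.
#' @return object of class \code{synth_config}.
#' @export
synth_config <- function(n_genes = 2000,
                         inducers = c("O-BGHEXA", "O-GMH", "O-XPE", "O-AHP",
                                      "O-GM3", "SOP", "TYR", "O-MHE",
                                      "O-CHE", "O-X3G4R"),
                         reference = "Glucose",
                         n_replicates = 3,
                         de_fraction_per_inducer = 0.1,
                         effect_size_logfc = 2,
                         noise_sd = 0.25,
                         n_go_terms = 58,
                         n_pathways = NULL,
                         n_cazy_families = 10,
                         n_pathway_genes = NULL,
                         cazy_fraction = 0.05,
                         extracellular_fraction = 0.1,
                         seed = 1L) {
  if (n_genes < 1 || n_replicates < 2) {
    stop("n_genes must be positive and n_replicates >= 2")
  }
  if (de_fraction_per_inducer < 0 || de_fraction_per_inducer > 1) {
    stop("de_fraction_per_inducer must lie in [0, 1]")
  }
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (extracellular_fraction < 0 || extracellular_fraction > 1) {
    stop("extracellular_fraction must lie in [0, 1]")
  }
  if (is.null(n_pathways)) {
    # 66 pathways at full scale; small gene universes get fewer so that
    # pathways stay nonempty at ~8 genes each
    n_pathways <- max(1L, min(66L, n_genes %/% 10L))
  }
  if (any(c(n_go_terms, n_pathways, n_cazy_families) < 1)) {
    stop("annotation universe sizes must be positive")
  }
  if (is.null(n_pathway_genes)) {
    n_pathway_genes <- min(n_genes, n_pathways * 8L)
  }
  if (n_pathway_genes < n_pathways) {
    stop("n_pathway_genes must be at least n_pathways (nonempty pathways)")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    inducers = inducers,
    reference = reference,
    n_replicates = as.integer(n_replicates),
    de_fraction_per_inducer = de_fraction_per_inducer,
    effect_size_logfc = effect_size_logfc,
    noise_sd = noise_sd,
    n_go_terms = as.integer(n_go_terms),
    n_pathways = as.integer(n_pathways),
    n_cazy_families = as.integer(n_cazy_families),
    n_pathway_genes = as.integer(n_pathway_genes),
    cazy_fraction = cazy_fraction,
    extracellular_fraction = extracellular_fraction,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# Run code under a seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

synth_gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' Generate a replicated log2 expression matrix with planted effects
#'
#' Non-planted genes share the same expected mean across all conditions;
#' a planted gene is shifted by its signed log2 fold-change in the named
#' inducer only. Replicate noise is independent Gaussian on the log2 scale.
#'
#' @param config a \code{synth_config}.
#' @param forced_de optional named list (inducer -> data.frame with columns
#'   \code{gene}, \code{logfc}) of effects planted verbatim in addition to
#'   the random ones; overrides a random planting for the same gene.
#' @param exclude_from_random genes never selected for random planting
#'   (used when a study scenario reserves genes for structured planting).
#' @return list with \code{matrix} (genes x samples, colnames
#'   \code{<condition>_r<rep>}, attribute \code{reference}) and
#'   \code{truth} (a \code{ground_truth} object with \code{planted_de}).
#' @export
generate_expression <- function(config, forced_de = NULL,
                                exclude_from_random = character()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    genes <- synth_gene_ids(config$n_genes)
    conditions <- c(config$reference, config$inducers)
    samples <- as.vector(vapply(conditions, function(cn)
      paste0(cn, "_r", seq_len(config$n_replicates)),
      character(config$n_replicates)))
    baseline <- stats::rnorm(config$n_genes, mean = 8, sd = 2)

    n_de <- floor(config$de_fraction_per_inducer * config$n_genes)
    eligible <- setdiff(genes, exclude_from_random)
    planted <- list()
    for (ind in config$inducers) {
      if (n_de > 0 && length(eligible)) {
        pick <- sample(eligible, min(n_de, length(eligible)))
        sign <- sample(c(-1, 1), length(pick), replace = TRUE)
        planted[[ind]] <- data.frame(
          gene = pick, logfc = sign * config$effect_size_logfc,
          stringsAsFactors = FALSE)
      } else {
        planted[[ind]] <- data.frame(gene = character(), logfc = numeric(),
                                     stringsAsFactors = FALSE)
      }
    }
    if (!is.null(forced_de)) {
      for (ind in names(forced_de)) {
        fd <- forced_de[[ind]]
        if (any(fd$logfc == 0)) stop("forced logFC must be nonzero")
        keep <- planted[[ind]]$gene[!planted[[ind]]$gene %in% fd$gene]
        planted[[ind]] <- rbind(
          planted[[ind]][planted[[ind]]$gene %in% keep, , drop = FALSE], fd)
      }
    }

    m <- matrix(0, nrow = config$n_genes, ncol = length(samples),
                dimnames = list(genes, samples))
    cond_of <- sub("_r[0-9]+$", "", samples)
    for (j in seq_along(samples)) {
      mu <- baseline
      ind <- cond_of[j]
      if (ind %in% names(planted) && nrow(planted[[ind]])) {
        idx <- match(planted[[ind]]$gene, genes)
        mu[idx] <- mu[idx] + planted[[ind]]$logfc
      }
      m[, j] <- mu + stats::rnorm(config$n_genes, sd = config$noise_sd)
    }
    attr(m, "reference") <- config$reference
    truth <- ground_truth(planted_de = planted)
    list(matrix = m, truth = truth)
  })
}

#' Container for the planted structure of a synthetic study
#'
#' @param planted_de named list (inducer -> data.frame gene/logfc).
#' @param planted_clusters named integer vector (item -> cluster id).
#' @param planted_associations data.frame with columns \code{cazy_gene},
#'   \code{partner_gene}.
#' @param planted_pathway list with \code{pathway} and \code{inducer}, or NULL.
#' @return object of class \code{ground_truth}.
#' @export
ground_truth <- function(planted_de = list(), planted_clusters = integer(),
                         planted_associations = NULL, planted_pathway = NULL) {
  for (fd in planted_de) {
    if (nrow(fd) && any(fd$logfc == 0)) stop("planted logFC must never be 0")
  }
  structure(list(planted_de = planted_de,
                 planted_clusters = planted_clusters,
                 planted_associations = planted_associations,
                 planted_pathway = planted_pathway),
            class = "ground_truth")
}

#' Generate an annotation catalog for a gene list
#'
#' Each gene receives zero or more GO terms (each term carries one of the
#' three ontology classes), pathway memberships partition a configured
#' subset of genes, a CAZy family is assigned to a configured subset, and
#' every gene carries an extracellular flag.
#'
#' @param config a \code{synth_config}.
#' @param genes character vector of unique gene ids.
#' @return object of class \code{annotation_catalog} with elements
#'   \code{genes}, \code{go} (gene -> term ids), \code{go_terms}
#'   (data.frame term/ontology_class), \code{pathways} (pathway -> gene set),
#'   \code{cazy} (gene -> family, NA if none), \code{extracellular}
#'   (named logical).
#' @export
generate_annotations <- function(config, genes) {
  stopifnot(inherits(config, "synth_config"))
  if (!length(genes)) stop("genes must be nonempty")
  if (anyDuplicated(genes)) stop("duplicate gene ids in input")
  with_seed(config$seed + 1L, {
    classes <- c("biological_process", "cellular_component",
                 "molecular_function")
    terms <- sprintf("GO:%07d", seq_len(config$n_go_terms))
    go_terms <- data.frame(
      term = terms,
      ontology_class = classes[(seq_len(config$n_go_terms) - 1L) %% 3L + 1L],
      stringsAsFactors = FALSE
    )
    n_terms_per_gene <- stats::rpois(length(genes), lambda = 2)
    go <- lapply(n_terms_per_gene, function(k)
      if (k == 0) character() else sample(terms, min(k, length(terms))))
    names(go) <- genes

    n_pw_genes <- min(config$n_pathway_genes, length(genes))
    pw_genes <- sample(genes, n_pw_genes)
    # partition: every pathway nonempty, remainder spread randomly
    assignment <- c(seq_len(config$n_pathways),
                    sample(config$n_pathways, n_pw_genes - config$n_pathways,
                           replace = TRUE))
    pathways <- split(pw_genes, sprintf("PWY%03d", assignment))

    fam_pool <- paste0(
      rep(c("GH", "GT", "PL", "CE", "AA"), length.out = config$n_cazy_families),
      seq_len(config$n_cazy_families))
    cazy <- rep(NA_character_, length(genes))
    names(cazy) <- genes
    n_cazy <- floor(config$cazy_fraction * length(genes))
    if (n_cazy > 0) {
      cz_genes <- sample(genes, n_cazy)
      cazy[cz_genes] <- sample(fam_pool, n_cazy, replace = TRUE)
    }
    extracellular <- stats::runif(length(genes)) < config$extracellular_fraction
    names(extracellular) <- genes

    structure(list(genes = genes, go = go, go_terms = go_terms,
                   pathways = pathways, cazy = cazy,
                   extracellular = extracellular),
              class = "annotation_catalog")
  })
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat("annotation_catalog:", length(x$genes), "genes,",
      nrow(x$go_terms), "GO terms,", length(x$pathways), "pathways,",
      sum(!is.na(x$cazy)), "CAZy genes,",
      sum(x$extracellular), "extracellular\n")
  invisible(x)
}

#' Generate a toy genome-scale metabolic network
#'
#' Reactions draw reactants and products from a metabolite pool; a subset of
#' reactions carries gene associations; designated probe metabolites are
#' guaranteed to occur in at least one gene-associated reaction. Pathway
#' labels group reactions, and pathway gene sets are the unions of their
#' reactions' gene associations.
#'
#' @param config a \code{synth_config}.
#' @param genes gene id pool for associations.
#' @param n_reactions number of reactions (>= 1).
#' @param n_metabolites metabolite pool size.
#' @param probe_metabolites metabolite ids guaranteed a gene-associated
#'   reaction.
#' @return a \code{metabolic_network}.
#' @export
generate_metabolic_network <- function(config, genes, n_reactions = 100,
                                       n_metabolites = 60,
                                       probe_metabolites = character()) {
  stopifnot(inherits(config, "synth_config"))
  if (n_reactions < 1) stop("n_reactions must be >= 1")
  with_seed(config$seed + 2L, {
    mets <- c(sprintf("M%03d", seq_len(n_metabolites)), probe_metabolites)
    reactions <- vector("list", n_reactions)
    for (i in seq_len(n_reactions)) {
      nr <- sample(1:3, 1); np <- sample(1:3, 1)
      picked <- sample(mets, nr + np)
      reactants <- picked[seq_len(nr)]
      products <- picked[nr + seq_len(np)]
      reversible <- stats::runif(1) < 0.2
      rx_genes <- if (stats::runif(1) < 0.7)
        sample(genes, sample(1:2, 1)) else character()
      arrow <- if (reversible) "<=>" else "=>"
      reactions[[i]] <- list(
        id = sprintf("R%04d", i),
        equation = paste(paste(reactants, collapse = " + "), arrow,
                         paste(products, collapse = " + ")),
        reactants = reactants, products = products, reversible = reversible,
        enzyme = sprintf("enzyme_%04d", i), genes = rx_genes,
        pathway = sprintf("PWY%03d",
                          sample(seq_len(config$n_pathways), 1))
      )
    }
    names(reactions) <- vapply(reactions, `[[`, "", "id")
    # guarantee each probe metabolite a gene-associated reaction
    for (pm in probe_metabolites) {
      hit <- any(vapply(reactions, function(r)
        length(r$genes) > 0 && pm %in% c(r$reactants, r$products), logical(1)))
      if (!hit) {
        j <- which(vapply(reactions, function(r) length(r$genes) > 0,
                          logical(1)))[1]
        if (is.na(j)) {
          j <- 1L
          reactions[[j]]$genes <- sample(genes, 1)
        }
        reactions[[j]]$reactants <- union(reactions[[j]]$reactants, pm)
        arrow <- if (reactions[[j]]$reversible) "<=>" else "=>"
        reactions[[j]]$equation <- paste(
          paste(reactions[[j]]$reactants, collapse = " + "), arrow,
          paste(reactions[[j]]$products, collapse = " + "))
      }
    }
    pathways <- list()
    for (r in reactions) {
      if (length(r$genes)) {
        pathways[[r$pathway]] <- union(pathways[[r$pathway]], r$genes)
      }
    }
    metabolic_network(reactions, pathways)
  })
}

#' Generate an item-by-descriptor matrix with planted cluster structure
#'
#' Items are drawn from k well-separated Gaussian centers. Centers are
#' placed orthogonally, each offset along its own coordinate axis by
#' \code{separation * noise_sd}, so nearest-center classification recovers
#' the planted labels whenever \code{separation} is large relative to the
#' per-coordinate noise.
#'
#' @param config a \code{synth_config} (supplies the seed).
#' @param n_items number of items (>= 2).
#' @param n_descriptors number of descriptor columns (>= 1).
#' @param k number of planted clusters (<= n_items).
#' @param separation center offset in units of \code{noise_sd}.
#' @param noise_sd per-coordinate Gaussian noise.
#' @return list with \code{matrix} (items x descriptors) and \code{truth}
#'   (a \code{ground_truth} with \code{planted_clusters}).
#' @export
generate_descriptor_table <- function(config, n_items = 10,
                                      n_descriptors = 186, k = 3,
                                      separation = 10, noise_sd = 1) {
  stopifnot(inherits(config, "synth_config"))
  if (n_items < 2 || n_descriptors < 1) stop(">=2 items and >=1 descriptor required")
  if (k > n_items) stop("k must not exceed the number of items")
  with_seed(config$seed + 3L, {
    centers <- matrix(0, nrow = k, ncol = n_descriptors)
    for (j in seq_len(k)) centers[j, j] <- separation * noise_sd
    labels <- rep(seq_len(k), length.out = n_items)
    m <- centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(n_items * n_descriptors, sd = noise_sd),
             nrow = n_items)
    rownames(m) <- sprintf("item%02d", seq_len(n_items))
    colnames(m) <- sprintf("D%03d", seq_len(n_descriptors))
    truth <- ground_truth(planted_clusters = stats::setNames(labels,
                                                             rownames(m)))
    list(matrix = m, truth = truth)
  })
}

#' Generate a coherent synthetic study for end-to-end validation
#'
#' Orchestrates expression, annotations and network generation so that the
#' planted structure is recoverable by construction rather than by chance:
#' random differential expression avoids pathway-member and association
#' genes; one designated pathway has all its genes planted down-regulated in
#' one designated inducer (the unique highly-affected pathway-inducer pair
#' when the significance threshold is half the pathway); and a set of
#' CAZy-flagged extracellular genes each share an identical planted
#' significance profile with a non-CAZy extracellular partner gene.
#'
#' @param config a \code{synth_config}.
#' @param n_association_pairs planted guilt-by-association pairs.
#' @param probe_metabolites probe metabolites for the network.
#' @param n_reactions,n_metabolites network sizing.
#' @return list with \code{expression}, \code{catalog}, \code{network},
#'   \code{truth}.
#' @export
generate_study <- function(config, n_association_pairs = 5,
                           probe_metabolites = c("TAUR", "SLF"),
                           n_reactions = 100, n_metabolites = 60) {
  stopifnot(inherits(config, "synth_config"))
  genes <- synth_gene_ids(config$n_genes)
  catalog <- generate_annotations(config, genes)

  planted_pathway <- names(catalog$pathways)[1]
  planted_inducer <- config$inducers[1]
  pathway_genes <- unique(unlist(catalog$pathways))

  assoc <- with_seed(config$seed + 4L, {
    pool <- setdiff(genes, pathway_genes)
    pick <- sample(pool, 2 * n_association_pairs)
    cazy_genes <- pick[seq_len(n_association_pairs)]
    partner_genes <- pick[n_association_pairs + seq_len(n_association_pairs)]
    profiles <- lapply(seq_len(n_association_pairs), function(i) {
      support <- sample(config$inducers, sample(2:4, 1))
      signs <- sample(c(-1, 1), length(support), replace = TRUE)
      stats::setNames(signs, support)
    })
    list(cazy = cazy_genes, partner = partner_genes, profiles = profiles)
  })

  # structured planting: fully-down pathway + shared association profiles
  forced <- stats::setNames(
    lapply(config$inducers, function(i)
      data.frame(gene = character(), logfc = numeric(),
                 stringsAsFactors = FALSE)),
    config$inducers)
  pp_genes <- catalog$pathways[[planted_pathway]]
  forced[[planted_inducer]] <- rbind(
    forced[[planted_inducer]],
    data.frame(gene = pp_genes, logfc = -config$effect_size_logfc,
               stringsAsFactors = FALSE))
  for (i in seq_along(assoc$cazy)) {
    prof <- assoc$profiles[[i]]
    for (ind in names(prof)) {
      forced[[ind]] <- rbind(
        forced[[ind]],
        data.frame(gene = c(assoc$cazy[i], assoc$partner[i]),
                   logfc = prof[[ind]] * config$effect_size_logfc,
                   stringsAsFactors = FALSE))
    }
  }

  reserved <- unique(c(pathway_genes, assoc$cazy, assoc$partner))
  expr <- generate_expression(config, forced_de = forced,
                              exclude_from_random = reserved)

  # catalog flags consistent with the planted association pairs
  fam_pool <- paste0(rep(c("GH", "GT", "PL", "CE", "AA"),
                         length.out = config$n_cazy_families),
                     seq_len(config$n_cazy_families))
  catalog$cazy[assoc$cazy] <- fam_pool[seq_along(assoc$cazy) %% length(fam_pool) + 1L]
  catalog$cazy[assoc$partner] <- NA_character_
  catalog$extracellular[c(assoc$cazy, assoc$partner)] <- TRUE
  catalog$extracellular[pp_genes] <- FALSE

  network <- generate_metabolic_network(config, genes,
                                        n_reactions = n_reactions,
                                        n_metabolites = n_metabolites,
                                        probe_metabolites = probe_metabolites)
  network$pathways <- catalog$pathways

  truth <- ground_truth(
    planted_de = expr$truth$planted_de,
    planted_associations = data.frame(cazy_gene = assoc$cazy,
                                      partner_gene = assoc$partner,
                                      stringsAsFactors = FALSE),
    planted_pathway = list(pathway = planted_pathway,
                           inducer = planted_inducer))
  list(expression = expr$matrix, catalog = catalog, network = network,
       truth = truth)
}

#' Write an annotation catalog to TSV (plus GMT gene sets)
#'
#' @param catalog an \code{annotation_catalog}.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_annotation_catalog <- function(catalog, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pw_of <- stats::setNames(rep("", length(catalog$genes)), catalog$genes)
  for (pw in names(catalog$pathways)) {
    g <- catalog$pathways[[pw]]
    pw_of[g] <- ifelse(nzchar(pw_of[g]), paste(pw_of[g], pw, sep = ";"), pw)
  }
  df <- data.frame(
    gene = catalog$genes,
    go_terms = vapply(catalog$go[catalog$genes], paste, "", collapse = ";"),
    pathways = pw_of[catalog$genes],
    cazy_family = ifelse(is.na(catalog$cazy[catalog$genes]), "",
                         catalog$cazy[catalog$genes]),
    extracellular = catalog$extracellular[catalog$genes],
    stringsAsFactors = FALSE
  )
  catalog_path <- file.path(dir, "catalog.tsv")
  utils::write.table(df, catalog_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  terms_path <- file.path(dir, "go_terms.tsv")
  utils::write.table(catalog$go_terms, terms_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gmt_path <- file.path(dir, "pathways.gmt")
  write_gmt(catalog$pathways, gmt_path)
  invisible(c(catalog_path, terms_path, gmt_path))
}

#' Read an annotation catalog written by \code{write_annotation_catalog}
#'
#' @param dir directory holding \code{catalog.tsv} and \code{go_terms.tsv}.
#' @return an \code{annotation_catalog}.
#' @export
read_annotation_catalog <- function(dir) {
  df <- utils::read.delim(file.path(dir, "catalog.tsv"), check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = c(gene = "character",
                                         go_terms = "character",
                                         pathways = "character",
                                         cazy_family = "character"))
  if (anyDuplicated(df$gene)) stop("duplicate gene ids in catalog")
  go <- lapply(strsplit(df$go_terms, ";", fixed = TRUE),
               function(x) x[nzchar(x)])
  names(go) <- df$gene
  pathways <- list()
  for (i in seq_len(nrow(df))) {
    for (pw in strsplit(df$pathways[i], ";", fixed = TRUE)[[1]]) {
      if (nzchar(pw)) pathways[[pw]] <- c(pathways[[pw]], df$gene[i])
    }
  }
  go_terms <- utils::read.delim(file.path(dir, "go_terms.tsv"),
                                stringsAsFactors = FALSE)
  cazy <- stats::setNames(ifelse(nzchar(df$cazy_family), df$cazy_family,
                                 NA_character_), df$gene)
  structure(list(genes = df$gene, go = go, go_terms = go_terms,
                 pathways = pathways, cazy = cazy,
                 extracellular = stats::setNames(as.logical(df$extracellular),
                                                 df$gene)),
            class = "annotation_catalog")
}

#' Write planted ground truth as JSON
#'
#' @param truth a \code{ground_truth}.
#' @param path output path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
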