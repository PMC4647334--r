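test_that("generator validates its configuration", {
  expect_error(synth_config(n_replicates = 1), "n_replicates")
  expect_error(synth_config(de_fraction_per_inducer = 1.2), "de_fraction")
  expect_error(synth_config(noise_sd = 0), "noise_sd")
  expect_error(synth_config(n_genes = 0), "positive")
})

test_that("expression matrix has the configured shape and planted effects", {
  cfg <- synth_config(n_genes = 100, n_replicates = 3, seed = 11)
  ex <- generate_expression(cfg)
  expect_equal(dim(ex$matrix), c(100, 33))
  expect_setequal(unique(sub("_r[0-9]+$", "", colnames(ex$matrix))),
                  c("Glucose", cfg$inducers))

  # no effects planted when de_fraction is zero
  cfg0 <- synth_config(n_genes = 50, de_fraction_per_inducer = 0,
                       noise_sd = 0.1, seed = 1)
  ex0 <- generate_expression(cfg0)
  expect_true(all(vapply(ex0$truth$planted_de, nrow, integer(1)) == 0))

  # planted signed logFC recovered from the emitted matrix itself
  cfg2 <- synth_config(n_genes = 200, effect_size_logfc = 2,
                       noise_sd = 0.01, seed = 3)
  ex2 <- generate_expression(cfg2)
  cond <- sub("_r[0-9]+$", "", colnames(ex2$matrix))
  ref_mean <- rowMeans(ex2$matrix[, cond == "Glucose"])
  for (ind in cfg2$inducers[1:3]) {
    planted <- ex2$truth$planted_de[[ind]]
    obs <- rowMeans(ex2$matrix[planted$gene, cond == ind, drop = FALSE]) -
      ref_mean[planted$gene]
    expect_true(all(abs(obs - planted$logfc) < 0.1))
    expect_true(all(planted$logfc != 0))
  }
})

test_that("identical seeds give bit-identical outputs", {
  cfg <- synth_config(n_genes = 60, seed = 42)
  a <- generate_expression(cfg); b <- generate_expression(cfg)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth, b$truth)
  g <- rownames(a$matrix)
  expect_identical(generate_annotations(cfg, g), generate_annotations(cfg, g))
  expect_identical(generate_metabolic_network(cfg, g, n_reactions = 20),
                   generate_metabolic_network(cfg, g, n_reactions = 20))
  expect_identical(generate_descriptor_table(cfg),
                   generate_descriptor_table(cfg))
})

test_that("annotation catalog has the promised structure", {
  cfg <- synth_config(n_genes = 200, n_pathways = 5, n_pathway_genes = 50,
                      extracellular_fraction = 0, seed = 5)
  genes <- rownames(generate_expression(cfg)$matrix)
  cat <- generate_annotations(cfg, genes)
  expect_error(generate_annotations(cfg, c("a", "a")), "duplicate")
  # closed ontology vocabulary
  expect_true(all(cat$go_terms$ontology_class %in%
                    c("biological_process", "cellular_component",
                      "molecular_function")))
  # pathway sizes sum to the partitioned subset
  expect_equal(sum(lengths(cat$pathways)), 50)
  expect_length(cat$pathways, 5)
  expect_true(all(lengths(cat$pathways) >= 1))
  # extracellular_fraction = 0 flags nobody
  expect_false(any(cat$extracellular))
})

test_that("metabolic network guarantees probe metabolites and counts", {
  cfg <- synth_config(n_genes = 50, seed = 9)
  genes <- sprintf("g%05d", 1:50)
  net <- generate_metabolic_network(cfg, genes, n_reactions = 10,
                                    probe_metabolites = "TAUR")
  expect_length(net$reactions, 10)
  rx <- reactions_of("TAUR", net)
  expect_gt(length(rx), 0)
  expect_true(any(vapply(net$reactions[rx], function(r) length(r$genes) > 0,
                         logical(1))))
  # unique reactant count equals brute-force union over emitted sets
  all_mets <- unique(unlist(lapply(net$reactions, function(r)
    c(r$reactants, r$products))))
  brute <- character()
  for (r in net$reactions) brute <- union(brute, c(r$reactants, r$products))
  expect_setequal(all_mets, brute)
})

test_that("descriptor matrix plants recoverable clusters", {
  cfg <- synth_config(seed = 21)
  expect_error(generate_descriptor_table(cfg, n_items = 5, k = 6), "k must")
  d1 <- generate_descriptor_table(cfg, n_items = 6, k = 1)
  expect_true(all(d1$truth$planted_clusters == 1))
  d <- generate_descriptor_table(cfg, n_items = 10, n_descriptors = 186,
                                 k = 3, separation = 10, noise_sd = 1)
  expect_equal(dim(d$matrix), c(10, 186))
  # nearest-center reassignment recovers planted labels exactly
  centers <- t(vapply(1:3, function(j)
    colMeans(d$matrix[d$truth$planted_clusters == j, , drop = FALSE]),
    numeric(186)))
  nearest <- apply(d$matrix, 1, function(x)
    which.min(rowSums(sweep(centers, 2, x)^2)))
  expect_equal(unname(nearest), unname(d$truth$planted_clusters))
})

test_that("null generator is type-I calibrated through the DE stage", {
  cfg <- synth_config(n_genes = 10000, inducers = "IND",
                      de_fraction_per_inducer = 0, seed = 101)
  ex <- generate_expression(cfg)
  rate <- mean(pairwise_de(ex$matrix, "IND", alpha = 0.05)$significant)
  band <- 0.05 + c(-1, 1) * stats::qnorm(0.995) *
    sqrt(0.05 * 0.95 / 10000)
  expect_gt(rate, band[1])
  expect_lt(rate, band[2])
})

test_that("planted signs are recovered for effects >= 5x noise", {
  cfg <- synth_config(n_genes = 1000, effect_size_logfc = 1.5,
                      noise_sd = 0.25, de_fraction_per_inducer = 0.1,
                      seed = 31)
  ex <- generate_expression(cfg)
  de <- de_table(ex$matrix)
  hits <- 0L; total <- 0L
  for (ind in cfg$inducers) {
    planted <- ex$truth$planted_de[[ind]]
    sub <- de[de$inducer == ind, ]
    obs <- sub[match(planted$gene, sub$gene), ]
    ok <- obs$significant & sign(obs$logFC) == sign(planted$logfc)
    hits <- hits + sum(ok); total <- total + nrow(planted)
  }
  expect_gte(hits / total, 0.99)
})

test_that("study scenario writers round-trip", {
  cfg <- synth_config(n_genes = 120, n_pathways = 4, n_pathway_genes = 24,
                      seed = 13)
  st <- generate_study(cfg, n_association_pairs = 2, n_reactions = 30)
  dir <- withr::local_tempdir()
  write_matrix_tsv(st$expression, file.path(dir, "expr.tsv"), id_col = "gene")
  m2 <- read_matrix_tsv(file.path(dir, "expr.tsv"))
  expect_equal(unname(m2), unname(st$expression[, ]), tolerance = 1e-12)
  write_annotation_catalog(st$catalog, dir)
  cat2 <- read_annotation_catalog(dir)
  expect_setequal(names(cat2$pathways), names(st$catalog$pathways))
  for (pw in names(cat2$pathways)) {
    expect_setequal(cat2$pathways[[pw]], st$catalog$pathways[[pw]])
  }
  expect_equal(cat2$cazy, st$catalog$cazy)
  expect_equal(cat2$extracellular, st$catalog$extracellular)
  write_reaction_table(st$network, file.path(dir, "net.tsv"))
  net2 <- read_reaction_table(file.path(dir, "net.tsv"))
  expect_equal(length(net2$reactions), length(st$network$reactions))
  r1 <- st$network$reactions[[5]]; r2 <- net2$reactions[[r1$id]]
  expect_equal(r2$reactants, r1$reactants)
  expect_equal(r2$products, r1$products)
  expect_equal(r2$genes, r1$genes)
  write_ground_truth(st$truth, file.path(dir, "truth.json"))
  expect_true(file.exists(file.path(dir, "truth.json")))
})
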