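toy_network <- function() {
  metabolic_network(list(
    R1 = list(id = "R1", equation = "A + B => M", reactants = c("A", "B"),
              products = "M", reversible = FALSE, enzyme = "enz1",
              genes = c("g1", "g2"), pathway = "PW1"),
    R2 = list(id = "R2", equation = "M + C <=> D", reactants = c("M", "C"),
              products = "D", reversible = TRUE, enzyme = "enz2",
              genes = "g3", pathway = "PW1"),
    R3 = list(id = "R3", equation = "E => F", reactants = "E",
              products = "F", reversible = FALSE, enzyme = "enz3",
              genes = character(), pathway = "PW2")))
}

test_that("reactions_of finds substrate-or-product membership", {
  net <- toy_network()
  expect_setequal(reactions_of("M", net), c("R1", "R2"))
  expect_warning(r <- reactions_of("ZZZ", net), "not found")
  expect_length(r, 0)
  # linear-scan oracle over all reactions
  for (met in c("A", "C", "D", "F", "M")) {
    brute <- names(net$reactions)[vapply(net$reactions, function(r)
      met %in% c(r$reactants, r$products), logical(1))]
    expect_setequal(suppressWarnings(reactions_of(met, net)), brute)
  }
})

test_that("equation parsing strips coefficients and flags reversibility", {
  eq <- parse_equation("H2SO3 + 3 NADPH => H2S + 3 NADP + 3 H2O")
  expect_equal(eq$reactants, c("H2SO3", "NADPH"))
  expect_equal(eq$products, c("H2S", "NADP", "H2O"))
  expect_false(eq$reversible)
  expect_true(parse_equation("A <=> B")$reversible)
  expect_error(parse_equation("A + B"), "malformed")
})

test_that("association table joins metabolite, reaction, gene and logFC", {
  net <- toy_network()
  de <- rbind(de_rows("g1", paste0("I", 1:7), rep(-1.5, 7)),
              de_rows("g1", paste0("I", 8:10), rep(0.5, 3),
                      significant = FALSE),
              de_rows("g2", paste0("I", 1:10), rep(2, 10)),
              de_rows("g3", paste0("I", 1:10), rep(-1, 10),
                      significant = FALSE))
  tab <- build_metabolite_table(c("A", "M"), net, de)
  # A: R1 only with 2 genes; M: R1 (2 genes) + R2 (1 gene)
  expect_equal(nrow(tab), 5)
  expect_equal(sum(tab$metabolite == "A"), 2)
  # significant in 7 of 10 inducers: 7 filled cells, 3 missing
  row_g1 <- tab[tab$metabolite == "A" & tab$gene == "g1", paste0("I", 1:10)]
  expect_equal(sum(!is.na(row_g1)), 7)
  expect_equal(sum(is.na(row_g1)), 3)
  check_membership(tab, net)
  # single metabolite, single reaction, single gene: one row, 10 cells
  tab1 <- build_metabolite_table("C", net, de)
  expect_equal(nrow(tab1), 1)
  expect_length(unlist(tab1[1, paste0("I", 1:10)]), 10)
})

test_that("consistency classification follows the sign rules", {
  net <- toy_network()
  de <- rbind(de_rows("g1", c("I1", "I2"), c(-1, -2)),
              de_rows("g2", c("I1", "I2"), c(-3, -0.5)),
              de_rows("g3", c("I1", "I2"), c(1, 2)))
  tab <- build_metabolite_table(c("A", "C", "E"), net, de)
  cc <- classify_consistency(tab)
  expect_equal(cc$call[cc$metabolite == "A"], "down_consistent")
  expect_equal(cc$call[cc$metabolite == "C"], "up_consistent")
  expect_equal(cc$call[cc$metabolite == "E"], "no_data")
  # one positive among negatives flips to mixed
  de2 <- de; de2$logFC[de2$gene == "g2" & de2$inducer == "I2"] <- 0.5
  de2$direction[de2$gene == "g2" & de2$inducer == "I2"] <- "up"
  cc2 <- classify_consistency(build_metabolite_table("A", net, de2))
  expect_equal(cc2$call, "mixed")
  # invariant to row and column order
  tab_perm <- tab[rev(seq_len(nrow(tab))),
                  c("metabolite", "reaction", "enzyme", "gene",
                    sample(paste0("I", 1:2)))]
  attr(tab_perm, "inducers") <- NULL
  attr(tab_perm, "metabolites") <- attr(tab, "metabolites")
  class(tab_perm) <- c("metabolite_gene_table", "data.frame")
  cc3 <- classify_consistency(tab_perm)
  expect_equal(cc3$call[match(cc$metabolite, cc3$metabolite)], cc$call)
})

test_that("row statistics recount the non-missing cells", {
  net <- toy_network()
  de <- de_rows("g3", "I1", -1.5)
  tab <- build_metabolite_table("C", net, de)
  s <- row_stats(tab, "g3")
  expect_equal(s, list(min = -1.5, max = -1.5, mean = -1.5,
                       n_nonmissing = 1L))
  expect_error(row_stats(tab, "nope"), "not present")
})

test_that("the packaged strong-binder table matches its reference values", {
  tab <- load_strong_binder_table()
  expect_length(unique(tab$metabolite), 6)
  cc <- classify_consistency(tab)
  calls <- stats::setNames(cc$call, cc$metabolite)
  expect_equal(unname(calls[c("H2SO3", "SLF", "UPGIII", "TAUR")]),
               rep("down_consistent", 4))
  expect_equal(unname(calls[c("PETHM", "T3P1")]), rep("up_consistent", 2))

  frozen <- list(
    AO090001000571 = list(min = -4.61, max = -1.74, n = 10L),
    AO090003000798 = list(min = -4.26, max = -1.52, n = 9L),
    AO090020000339 = list(min = -3.18, max = -1.37, n = 10L),
    AO090103000073 = list(min = 0.74, max = 1.28, n = 10L),
    AO090023000345 = list(min = 0.98, max = 1.33, n = 8L),
    AO090023000531 = list(min = -2.1, max = -1.4, n = 7L))
  for (gene in names(frozen)) {
    s <- row_stats(tab, gene)
    expect_equal(s$min, frozen[[gene]]$min)
    expect_equal(s$max, frozen[[gene]]$max)
    expect_equal(s$n_nonmissing, frozen[[gene]]$n)
    # brute-force recount directly over the parsed cells
    cells <- unlist(tab[tab$gene == gene,
                        setdiff(colnames(tab), c("metabolite", "reaction",
                                                 "enzyme", "gene"))])
    cells <- cells[!is.na(cells)]
    expect_equal(s$min, min(cells))
    expect_equal(s$max, max(cells))
    expect_equal(s$mean, mean(cells))
  }

  # every (metabolite, reaction) pair satisfies reaction membership
  for (i in seq_len(nrow(tab))) {
    eq <- parse_equation(tab$reaction[i])
    expect_true(tab$metabolite[i] %in% c(eq$reactants, eq$products))
  }
})

test_that("metabolite tables round-trip through TSV with '-' markers", {
  tab <- load_strong_binder_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metabolite_table(tab, path)
  back <- read_metabolite_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
  raw <- readLines(path)
  expect_true(any(grepl("\t-\t", raw)))  # missing cells stay dashes
})
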