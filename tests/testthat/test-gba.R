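test_that("signed profiles encode direction ternary and completely", {
  de <- rbind(de_rows("cz", c("I1", "I2", "I3"), c(1, -1, 2)),
              de_rows("cz", c("I4", "I5"), c(1, 1), significant = FALSE),
              de_rows("quiet", paste0("I", 1:5), rep(0.5, 5),
                      significant = FALSE))
  p <- signed_profiles(de)
  expect_equal(unname(p["cz", paste0("I", 1:5)]), c(1L, -1L, 1L, 0L, 0L))
  expect_true(all(p["quiet", ] == 0))  # never significant: all-zero
  expect_true(all(p %in% c(-1L, 0L, 1L)))
  # recount oracle: re-derive every cell from the DE rows
  for (g in rownames(p)) {
    for (ind in colnames(p)) {
      d <- de[de$gene == g & de$inducer == ind, ]
      want <- if (!nrow(d) || d$direction == "none") 0L
              else if (d$direction == "up") 1L else -1L
      expect_identical(p[g, ind], want)
    }
  }
})

test_that("association requires exact match on the full support set", {
  inducers <- paste0("I", 1:6)
  de <- rbind(
    de_rows("cz", inducers[1:5], c(1, 1, -1, 1, -1)),
    de_rows("match", inducers[1:5], c(2, 0.5, -2, 1.5, -0.3)),
    de_rows("fourof5", inducers[1:4], c(1, 1, -1, 1)),   # missing I5
    de_rows("flipped", inducers[1:5], c(1, 1, -1, 1, 1)),
    de_rows("wide", inducers, c(1, 1, -1, 1, -1, 2)))    # extra inducer ok
  p <- signed_profiles(de)
  expect_error(associate_profiles("cz", "match", p, min_support = 0),
               "min_support")
  e <- associate_profiles("cz", c("match", "fourof5", "flipped", "wide"), p)
  expect_setequal(e$candidate_gene, c("match", "wide"))
  expect_true(all(e$support == 5))
  # support below min_support yields no edges
  de2 <- rbind(de_rows("c1", "I1", 1), de_rows("g1", "I1", 1))
  expect_equal(nrow(associate_profiles("c1", "g1", signed_profiles(de2),
                                       min_support = 2)), 0)
  expect_equal(nrow(associate_profiles("c1", "g1", signed_profiles(de2),
                                       min_support = 1)), 1)
})

test_that("edges equal an exhaustive all-pairs comparison", {
  set.seed(14)
  inducers <- paste0("I", 1:10)
  genes <- paste0("g", 1:50)
  profiles <- matrix(sample(c(-1L, 0L, 1L), 500, replace = TRUE,
                            prob = c(0.2, 0.6, 0.2)),
                     nrow = 50, dimnames = list(genes, inducers))
  cazy <- genes[1:15]; cand <- genes[16:50]
  for (ms in c(1, 2, 3)) {
    e <- associate_profiles(cazy, cand, profiles, min_support = ms)
    brute <- list()
    for (cz in cazy) {
      s <- which(profiles[cz, ] != 0)
      if (length(s) < ms) next
      for (g in cand) {
        if (all(profiles[g, s] == profiles[cz, s])) {
          brute[[length(brute) + 1L]] <- paste(cz, g)
        }
      }
    }
    expect_setequal(paste(e$cazy_gene, e$candidate_gene), unlist(brute))
  }
  # edge count is monotone non-increasing in min_support
  counts <- vapply(1:4, function(ms)
    nrow(associate_profiles(cazy, cand, profiles, min_support = ms)),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("role reversal with identical profiles mirrors the edge set", {
  de <- rbind(de_rows("a", c("I1", "I2"), c(1, -1)),
              de_rows("b", c("I1", "I2"), c(1.5, -0.2)))
  p <- signed_profiles(de)
  fwd <- associate_profiles("a", "b", p)
  rev <- associate_profiles("b", "a", p)
  expect_equal(nrow(fwd), 1); expect_equal(nrow(rev), 1)
  expect_equal(fwd$cazy_gene, rev$candidate_gene)
  expect_equal(fwd$candidate_gene, rev$cazy_gene)
})

test_that("network typing is consistent with the DE table", {
  de <- rbind(de_rows("cz", c("I1", "I2"), c(1, -1)),
              de_rows("cand", c("I1", "I2"), c(1, -1)))
  edges <- associate_profiles("cz", "cand", signed_profiles(de))
  g <- build_association_network(edges, de)
  types <- igraph::V(g)$type
  names(types) <- igraph::V(g)$name
  expect_equal(types[["cz"]], "cazy_gene")
  expect_equal(types[["cand"]], "associated_gene")
  expect_equal(types[["I1"]], "inducer")
  el <- igraph::as_data_frame(g)
  # gene-inducer edge exists iff the gene is significant in that inducer
  gi <- el[el$type == "significant_in", ]
  expect_equal(nrow(gi), 4)
  for (i in seq_len(nrow(gi))) {
    expect_true(any(de$gene == gi$from[i] & de$inducer == gi$to[i] &
                      de$significant))
  }
  # no gene-gene edges: only significance edges remain
  g0 <- build_association_network(edges[0, ], de,
                                  cazy_genes = "cz",
                                  candidate_genes = "cand")
  el0 <- igraph::as_data_frame(g0)
  expect_true(all(el0$type == "significant_in"))
})

test_that("GraphML and SIF exports re-import isomorphically", {
  de <- rbind(de_rows("cz", c("I1", "I2"), c(1, -1)),
              de_rows("cand", c("I1", "I2"), c(1, -1)))
  g <- build_association_network(
    associate_profiles("cz", "cand", signed_profiles(de)), de)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, gml)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_true(igraph::isomorphic(g, g2))
  sif <- withr::local_tempfile(fileext = ".sif")
  write_sif(g, sif)
  parts <- strsplit(readLines(sif), "\t")
  expect_true(all(lengths(parts) == 3))
  el <- igraph::as_data_frame(g)
  expect_setequal(vapply(parts, function(x) paste(x[1], x[3]), ""),
                  paste(el$from, el$to))
})

test_that("correlation mode associates matching logFC patterns", {
  de <- rbind(de_rows("cz", paste0("I", 1:4), c(1, 2, -1, -2)),
              de_rows("good", paste0("I", 1:4), c(1.1, 2.2, -0.9, -1.8)),
              de_rows("anti", paste0("I", 1:4), c(-1, -2, 1, 2)))
  e <- associate_correlation("cz", c("good", "anti"), de, r_min = 0.9,
                             min_support = 3)
  expect_equal(e$candidate_gene, "good")
  expect_gt(e$r, 0.9)
})
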