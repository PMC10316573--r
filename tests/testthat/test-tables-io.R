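test_that("TSV round trip preserves tables in both orientations", {
  tab <- random_table(3, 4, seed = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(tab, f)
  back <- read_abundance_table(f, orientation = "rows-are-samples")
  expect_equal(dim(back), c(3, 4))
  expect_equal(back$values, tab$values, tolerance = 1e-12)

  # transposed file with explicit orientation gives the identical table
  ft <- withr::local_tempfile(fileext = ".tsv")
  tdf <- data.frame(taxon_id = colnames(tab$values), t(tab$values), check.names = FALSE)
  write.table(tdf, ft, sep = "\t", quote = FALSE, row.names = FALSE)
  back_t <- read_abundance_table(ft, orientation = "rows-are-taxa")
  expect_equal(back_t$values, tab$values, tolerance = 1e-12)
})

test_that("malformed tables are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tdup\tdup2", "duprow\t1\t2", "duprow\t3\t4"), f)
  expect_error(read_abundance_table(f), "duprow")
  writeLines(c("id\ta\tb", "s1\t1\tx", "s2\t3\t4"), f)
  expect_error(read_abundance_table(f), "non-numeric")
  m <- matrix(c(1, -1, 2, 3), 2, 2, dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_error(abundance_table(m), "negative")
})

test_that("normalize_relative closes rows, keeps zeros, and is idempotent", {
  tab <- make_table(matrix(c(2, 2, 0, 4), nrow = 1))
  norm <- normalize_relative(tab)
  expect_equal(unname(norm$values[1, ]), c(0.25, 0.25, 0, 0.5))
  expect_equal(normalize_relative(norm)$values, norm$values)
  for (seed in 1:5) {
    r <- random_table(6, 8, seed)
    expect_equal(rowSums(normalize_relative(r)$values), rep(1, 6),
                 ignore_attr = TRUE, tolerance = 1e-9)
    expect_equal(normalize_relative(normalize_relative(r))$values,
                 normalize_relative(r)$values)
  }
  zero <- make_table(matrix(c(0, 0, 0, 1, 2, 3), nrow = 2, byrow = TRUE))
  expect_error(normalize_relative(zero), "s1")
})

test_that("prevalence filter applies strict 'more than' thresholds", {
  m <- matrix(0, nrow = 4, ncol = 3,
              dimnames = list(paste0("s", 1:4), c("keep", "drop", "rare")))
  m[1:3, "keep"] <- 0.002   # 3/4 samples > 0.001: retained
  m[1:2, "drop"] <- 0.002   # 2/4 = exactly 50%: dropped (strict)
  m[1, "rare"] <- 0.0005    # never above threshold
  tab <- abundance_table(m)
  filt <- prevalence_filter(tab, 0.001, 0.5)
  expect_identical(taxon_ids(filt), "keep")
  expect_identical(sample_ids(filt), sample_ids(tab))
  all0 <- prevalence_filter(tab, 0, 0)
  expect_setequal(taxon_ids(all0), c("keep", "drop", "rare"))
  expect_error(prevalence_filter(tab, -0.1, 0.5), "0, 1")
})

test_that("lineage parsing round-trips and aggregation conserves mass", {
  lin <- c("d__Bacteria;p__Firmicutes;c__Bacilli;o__Lactobacillales;f__Lactobacillaceae;g__Lactobacillus;s__Lactobacillus johnsonii",
           "d__Bacteria;p__Firmicutes;c__Clostridia;o__Lachnospirales;f__Lachnospiraceae;g__Dorea;s__",
           "d__Bacteria;p__Firmicutes;c__Clostridia;o__Lachnospirales;f__Lachnospiraceae;g__Dorea;s__Dorea sp002160985")
  expect_identical(format_lineage(parse_lineage(lin)), unname(lin))

  m <- matrix(c(0.5, 0.01, 0.02, 0.47,
                0.3, 0.30, 0.10, 0.30), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), paste0("mag", 1:4)))
  tab <- abundance_table(m, lineages = c(lin[1], lin[2], lin[3],
                                         "d__Bacteria;p__Proteobacteria;c__;o__;f__Enterobacteriaceae;g__;s__"))
  gen <- aggregate_at_rank(tab, "genus")
  expect_equal(gen$values[, "Dorea"], c(s1 = 0.03, s2 = 0.40))
  expect_equal(rowSums(gen$values), rowSums(m), ignore_attr = TRUE, tolerance = 1e-9)
  for (rk in c("domain", "phylum", "family", "species"))
    expect_equal(rowSums(aggregate_at_rank(tab, rk)$values), rowSums(m),
                 ignore_attr = TRUE, tolerance = 1e-9)
  expect_error(aggregate_at_rank(tab, "tribe"), "rank")
})

test_that("species-level aggregation pools unassigned and keeps named species", {
  lin <- c("d__Bacteria;p__A;c__;o__;f__;g__;s__Sp one",
           "d__Bacteria;p__A;c__;o__;f__;g__;s__")
  m <- matrix(c(0.7, 0.3), nrow = 1, dimnames = list("s1", c("m1", "m2")))
  agg <- aggregate_at_rank(abundance_table(m, lineages = lin), "species")
  expect_setequal(taxon_ids(agg), c("Sp one", "Unassigned"))
})

test_that("graph export round-trips through GraphML and edge lists count rows", {
  b <- generate_benchmark_graph("two-cliques", clique_size = 3)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_network(b$network, f)
  back <- read_network(f)
  expect_true(igraph::isomorphic(b$network$graph, back$graph))
  expect_setequal(igraph::V(back$graph)$name, igraph::V(b$network$graph)$name)
  expect_equal(sort(igraph::E(back$graph)$rho), sort(igraph::E(b$network$graph)$rho))
  expect_setequal(igraph::E(back$graph)$sign, "+")

  fe <- withr::local_tempfile(fileext = ".tsv")
  g <- igraph::make_graph(c("a", "b", "b", "c"), directed = FALSE)
  g <- igraph::set_edge_attr(g, "rho", value = c(0.9, -0.8))
  g <- igraph::set_edge_attr(g, "sign", value = c("+", "-"))
  write_network(cooc_network(g), fe, format = "edgelist")
  rows <- read.table(fe, header = TRUE, sep = "\t")
  expect_equal(nrow(rows), 2)
  expect_setequal(rows$sign, c("+", "-"))

  empty <- cooc_network(igraph::make_empty_graph(3, directed = FALSE))
  fz <- withr::local_tempfile(fileext = ".tsv")
  expect_warning(write_network(empty, fz, format = "edgelist"), "0 edges")
  expect_equal(nrow(read.table(fz, header = TRUE, sep = "\t")), 0)
})

test_that("trait tables read and write with missing values preserved", {
  m <- matrix(c(1.5, NA, 2.5, 3.5, 4.5, 5.5), nrow = 3,
              dimnames = list(paste0("s", 1:3), c("acetate", "ghrelin")))
  tt <- trait_table(m)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trait_table(tt, f)
  back <- read_trait_table(f)
  expect_equal(back$values, m)
  expect_error(trait_table(matrix(Inf, 1, 1, dimnames = list("s", "t"))), "finite")
})
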