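test_that("edge-list parsing collapses duplicates and drops self-loops", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tA", "A\tA"), f)
  expect_warning(net <- read_edge_list(f), "self-loop")
  expect_setequal(net$nodes, c("A", "B"))
  expect_equal(n_edges(net), 1)

  f2 <- withr::local_tempfile(fileext = ".sif")
  writeLines("TP53\tpp\tMDM2\tEP300", f2)
  sif <- read_edge_list(f2, dialect = "sif")
  expect_equal(n_edges(sif), 2)
  expect_setequal(sif$edges$to[sif$edges$from == "MDM2"], "TP53")
  expect_true(all(c("TP53", "MDM2", "EP300") %in% sif$nodes))

  f3 <- withr::local_tempfile(fileext = ".tsv")
  pairs <- c("A\tB", "C\tD", "E\tF", "G\tH", "I\tJ", "K\tL", "M\tN", "O\tP")
  writeLines(c("# comment one", pairs[1:4], "# comment two", pairs[5:8]), f3)
  expect_equal(n_edges(read_edge_list(f3)), 8)
})

test_that("malformed edge lines are reported with their line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "oops"), f)
  expect_error(read_edge_list(f), "line 2")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  file.create(f2)
  empty <- read_edge_list(f2)
  expect_equal(n_nodes(empty), 0)
  expect_equal(n_edges(empty), 0)
})

test_that("network writing is canonical and round-trips exactly", {
  tri <- network(edges = data.frame(c("B", "C", "B"), c("A", "A", "C")))
  prefix <- withr::local_tempfile()
  write_network(tri, prefix)
  edges <- readLines(paste0(prefix, ".edges.tsv"))
  expect_equal(edges, c("# from\tto", "A\tB", "A\tC", "B\tC"))

  empty <- network()
  prefix2 <- withr::local_tempfile()
  write_network(empty, prefix2)
  expect_equal(length(readLines(paste0(prefix2, ".nodes.tsv"))), 1)
  expect_equal(length(readLines(paste0(prefix2, ".edges.tsv"))), 1)

  set.seed(11)
  for (rep in 1:5) {
    net <- random_network(100, 0.05)
    net$node_attrs <- data.frame(node = net$nodes,
                                 score = round(stats::runif(100), 3),
                                 stringsAsFactors = FALSE)
    prefix3 <- withr::local_tempfile()
    write_network(net, prefix3)
    back <- read_network(prefix3)
    expect_identical(back$nodes, net$nodes)
    expect_identical(back$edges, net$edges)
    expect_equal(back$node_attrs$score, net$node_attrs$score)
  }
})

test_that("GMT parsing enforces structure and round-trips", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc\tA\tB\tA", "T2\tother\tC\tD"), f)
  lib <- read_gmt(f)
  expect_length(lib, 2)
  expect_setequal(lib[["T1"]]$genes, c("A", "B"))

  f2 <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc\tA", "T1\tdesc\tB"), f2)
  expect_error(read_gmt(f2), "duplicate term id: T1")
  f3 <- withr::local_tempfile(fileext = ".gmt")
  writeLines("T1\tdesc-only", f3)
  expect_error(read_gmt(f3), ">= 3 fields")

  set.seed(5)
  pool <- sprintf("G%03d", 1:200)
  terms <- lapply(1:50, function(i) {
    list(description = paste("term", i),
         genes = sample(pool, sample(3:20, 1)))
  })
  names(terms) <- sprintf("T%02d", 1:50)
  lib2 <- gene_set_library(terms)
  f4 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(lib2, f4)
  back <- read_gmt(f4)
  expect_identical(names(back), names(lib2))
  for (id in names(lib2)) {
    expect_setequal(back[[id]]$genes, lib2[[id]]$genes)
  }
})

test_that("expression matrices read with duplicate-gene and label rules", {
  f <- withr::local_tempfile(fileext = ".tsv")
  lf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2\ts3\ts4",
               "Gene1\t1\t2\t3\t4",
               "Gene2\t5\t5\t5\t5",
               "Gene2\t7\t7\t7\t7",
               "Gene3\t0\t1\t0\t1"), f)
  writeLines(c("s1\tcase", "s2\tcase", "s3\tcontrol", "s4\tcontrol"), lf)
  expect_message(ds <- read_expression_matrix(f, lf), "duplicate")
  expect_equal(nrow(ds$values), 3)
  expect_equal(unname(ds$values["Gene2", 1]), 7)

  lf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tcase", "s2\tcase", "s3\tcontrol"), lf2)
  expect_error(read_expression_matrix(f, lf2), "missing from labels")

  lf3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tcase", "s2\tcontrol", "s3\tcontrol", "s4\tcontrol"), lf3)
  expect_error(suppressMessages(read_expression_matrix(f, lf3)),
               ">= 2 samples")
})

test_that("expression round-trip preserves values exactly", {
  set.seed(21)
  vals <- matrix(stats::rnorm(40, 8), 10, 4,
                 dimnames = list(sprintf("g%02d", 1:10),
                                 c("a1", "a2", "b1", "b2")))
  ds <- expression_dataset(vals, c(a1 = "case", a2 = "case",
                                   b1 = "control", b2 = "control"))
  f <- withr::local_tempfile(fileext = ".tsv")
  lf <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(ds, f, lf)
  back <- read_expression_matrix(f, lf)
  expect_equal(back$values, ds$values)
  expect_identical(back$groups, ds$groups)
})

test_that("mapping tables dedupe pairs and reject conflicts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Il17a\tIL17A", "Il17a\tIL17A", "Mmp9\tMMP9"), f)
  map <- read_mapping_table(f)
  expect_length(map, 2)
  expect_equal(unname(map["Il17a"]), "IL17A")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Mmp9\tMMP9", "Mmp9\tMMP2"), f2)
  expect_error(read_mapping_table(f2), "Mmp9")
})

test_that("symbol normalization is idempotent and enforced by the parser", {
  raw <- c("  tp53 ", "Mdm2", "EP300  ")
  once <- normalize_symbols(raw)
  expect_identical(normalize_symbols(once), once)
  expect_identical(once, c("TP53", "MDM2", "EP300"))

  set.seed(31)
  for (rep in 1:10) {
    n <- sample(2:30, 1)
    pairs <- matrix(sample(sprintf(" g%02d ", 1:12), 2 * n, replace = TRUE),
                    ncol = 2)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(paste(pairs[, 1], pairs[, 2], sep = "\t"), f)
    net <- suppressWarnings(read_edge_list(f))
    expect_false(any(net$edges$from == net$edges$to))
    expect_true(all(net$edges$from < net$edges$to))
    key <- paste(net$edges$from, net$edges$to)
    expect_false(any(duplicated(key)))
    expect_true(all(c(net$edges$from, net$edges$to) %in% net$nodes))
    expect_identical(net$nodes, normalize_symbols(net$nodes))
  }
})
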