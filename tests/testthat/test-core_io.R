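test_that("expression matrices round-trip through TSV and enforce invariants", {
  set.seed(1)
  x <- rand_expr(3L, 4L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(x, path)
  y <- read_expression(path)
  expect_equal(unclass(y), unclass(x))

  # comma dialect is sniffed from the header
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene_id,s1,s2,s3", "a,1,2,3", "b,4,5,6"), csv)
  z <- read_expression(csv)
  expect_equal(dim(z), c(2L, 3L))
  expect_equal(unname(unclass(z)["b", ]), c(4, 5, 6))

  # transposed layout
  tpath <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(sample_id = colnames(x), t(unclass(x)), check.names = FALSE)
  write.table(df, tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  w <- read_expression(tpath, samples_as_rows = TRUE)
  expect_equal(unclass(w), unclass(x))
})

test_that("expression loader rejects degenerate files with named errors", {
  dup <- withr::local_tempfile()
  writeLines(c("gene_id\ts1\ts2\ts3", "a\t1\t2\t3", "a\t4\t5\t6"), dup)
  expect_error(read_expression(dup), "duplicated gene id.*a")

  nonnum <- withr::local_tempfile()
  writeLines(c("gene_id\ts1\ts2\ts3", "a\t1\tx\t3", "b\t4\t5\t6"), nonnum)
  expect_error(read_expression(nonnum), "non-numeric cell")

  missing <- withr::local_tempfile()
  writeLines(c("gene_id\ts1\ts2\ts3", "a\t1\tNA\t3", "b\t4\t5\t6"), missing)
  expect_error(read_expression(missing), "non-finite value.*'a'")

  narrow <- withr::local_tempfile()
  writeLines(c("gene_id\ts1\ts2", "a\t1\t2", "b\t4\t5"), narrow)
  expect_error(read_expression(narrow), "at least 3 samples")

  # minimal legal size: 2 genes x 3 samples
  minimal <- withr::local_tempfile()
  writeLines(c("gene_id\ts1\ts2\ts3", "a\t1\t2\t3", "b\t4\t5\t6"), minimal)
  m <- read_expression(minimal)
  expect_equal(dim(m), c(2L, 3L))
})

test_that("split_by_stage partitions samples and preserves gene order", {
  set.seed(2)
  x <- expression_matrix(matrix(rnorm(12), 2, 6,
                                dimnames = list(c("a", "b"), sprintf("s%d", 1:6))))
  sm <- setNames(rep(c("A", "B"), each = 3), sprintf("s%d", 1:6))
  ds <- split_by_stage(x, sm, c("A", "B"))
  expect_s3_class(ds, "staged_dataset")
  expect_equal(vapply(ds$blocks, ncol, integer(1)), c(A = 3L, B = 3L))
  expect_equal(rownames(ds$blocks$B), c("a", "b"))
  # the blocks' samples are a disjoint cover of the input samples
  got <- unlist(lapply(ds$blocks, colnames), use.names = FALSE)
  expect_setequal(got, colnames(x))
  expect_equal(anyDuplicated(got), 0L)

  # permuting input columns leaves per-stage sample sets unchanged
  xp <- expression_matrix(unclass(x)[, sample(6)])
  dsp <- split_by_stage(xp, sm, c("A", "B"))
  for (st in c("A", "B")) {
    expect_setequal(colnames(dsp$blocks[[st]]), colnames(ds$blocks[[st]]))
  }

  sm_small <- setNames(c("A", "A", "A", "A", "B", "B"), sprintf("s%d", 1:6))
  expect_error(split_by_stage(x, sm_small, c("A", "B")), "stage 'B' has 2")
  expect_error(split_by_stage(x, sm[1:5], c("A", "B")), "missing from the stage map.*s6")
  expect_error(split_by_stage(x, sm, c("A")), "not in stage_order")
})

test_that("edge lists round-trip, dedupe undirected pairs, and reject self-loops", {
  genes <- letters[1:5]
  dag <- directed_network(genes, rbind(c("a", "b"), c("b", "c"), c("a", "d"),
                                       c("d", "e"), c("c", "e")))
  p <- withr::local_tempfile()
  write_edge_list(dag, p)
  back <- read_edge_list(p, directed = TRUE, gene_ids = genes)
  expect_equal(back$edges, dag$edges)

  # undirected read collapses both orientations to one edge
  u <- withr::local_tempfile()
  writeLines(c("a\tb", "b\ta"), u)
  un <- read_edge_list(u, directed = FALSE)
  expect_equal(nrow(un$edges), 1L)
  expect_equal(unname(un$edges[1L, ]), c("a", "b"))

  sl <- withr::local_tempfile()
  writeLines("g1\tg1", sl)
  expect_error(read_edge_list(sl), "self-loop")

  expect_error(read_edge_list(p, directed = TRUE, gene_ids = c("a", "b")),
               "not in gene universe")

  # empty network round-trips
  e <- withr::local_tempfile()
  write_edge_list(directed_network(genes, NULL), e)
  expect_equal(nrow(read_edge_list(e, gene_ids = genes)$edges), 0L)
})

test_that("stage maps round-trip and scored networks enforce additivity", {
  sm <- setNames(c("I", "I", "II"), c("s1", "s2", "s3"))
  p <- withr::local_tempfile()
  write_stage_map(sm, p)
  expect_equal(read_stage_map(p), sm)

  net <- directed_network(c("a", "b"), rbind(c("a", "b")))
  expect_error(scored_network(net, 5, c(a = 1, b = 2)), "sum of local scores")
  ok <- scored_network(net, 3, c(a = 1, b = 2))
  expect_equal(ok$h_score, sum(ok$local_scores))
})
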