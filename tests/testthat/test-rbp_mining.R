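test_that("GenBank flat files yield one record per translated CDS", {
  gb <- withr::local_tempfile(fileext = ".gb")
  write_test_genbank(gb, with_untranslated = TRUE)
  expect_warning(recs <- read_protein_records(gb), "skipped")
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$phage_id, rep("TEST0001", 3))
  expect_equal(recs$product,
               c("tail fiber protein", "portal protein", "hypothetical protein"))
  expect_equal(unique(recs$length), 50L)
  expect_false(any(grepl("\\s|\"", recs$sequence)))
})

test_that("annotated FASTA headers carry phage and product metadata", {
  fa <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">p1 phage=X product=tail fiber protein", "MKVLL",
               ">p2 phage=X product=portal protein", "MASTG"), fa)
  recs <- read_protein_records(fa)
  expect_equal(recs$protein_id, c("p1", "p2"))
  expect_equal(recs$phage_id, c("X", "X"))
  expect_equal(recs$product[1], "tail fiber protein")

  empty <- withr::local_tempfile(fileext = ".faa")
  writeLines(character(0), empty)
  expect_equal(nrow(read_protein_records(empty)), 0L)
  expect_error(read_protein_records("no/such/file.faa"), "no such file")
})

test_that("FASTA round trip through write_protein_fasta preserves records", {
  recs <- protein_records(c("a1", "a2"), c("pA", "pB"),
                          c("tail spike protein", "hypothetical protein"),
                          c("MKVL", "MAST"))
  fa <- withr::local_tempfile(fileext = ".faa")
  write_protein_fasta(recs, fa)
  back <- read_protein_records(fa)
  expect_equal(back[, c("protein_id", "phage_id", "product", "sequence")],
               recs[, c("protein_id", "phage_id", "product", "sequence")])
})

test_that("annotation rules keep RBP products and let exclusion dominate", {
  recs <- protein_records(
    paste0("p", 1:6), rep("ph", 6),
    c("tail fiber protein", "Tailspike  protein", "tail fiber assembly protein",
      "hypothetical protein", "receptor-binding protein", "portal protein"),
    rep("MKVL", 6)
  )
  sel <- select_rbps(recs)
  expect_equal(sel$protein_id, c("p1", "p2", "p5"))
  # idempotence
  expect_equal(select_rbps(sel), sel)
  # exclusion dominates even when an inclusion pattern also matches
  both <- protein_records("q1", "ph", "tail fiber assembly protein", "MKVL")
  expect_equal(nrow(select_rbps(both)), 0L)
  # invalid rule sets are rejected
  expect_error(rbp_rules(inclusion = character(0)), "non-empty")
  expect_error(rbp_rules(inclusion = "("), "compile")
})

test_that("sequences with undetermined residues are dropped", {
  recs <- protein_records(paste0("p", 1:3), rep("ph", 3),
                          rep("tail fiber protein", 3),
                          c("MKXLL", "MKLL", "XXX"))
  kept <- drop_undetermined(recs)
  expect_equal(kept$protein_id, "p2")
})

test_that("length bounds match an independent type-7 quartile computation", {
  b <- compute_length_bounds(c(100, 200, 300, 400, 500))
  expect_equal(c(b$q1, b$q3, b$lower, b$upper), c(200, 400, -100, 700))

  b2 <- compute_length_bounds(1:4)
  expect_equal(c(b2$q1, b2$q3), c(1.75, 3.25))
  expect_equal(c(b2$lower, b2$upper), c(-0.5, 5.5))

  # random vectors against the order-statistic interpolation oracle
  set.seed(11)
  for (i in 1:20) {
    x <- sample(50:2000, sample(2:40, 1), replace = TRUE)
    b3 <- compute_length_bounds(x)
    expect_equal(b3$q1, type7_quartile(x, 0.25))
    expect_equal(b3$q3, type7_quartile(x, 0.75))
  }

  b4 <- compute_length_bounds(c(300, 300, 300))
  expect_equal(c(b4$lower, b4$upper), c(300, 300))
  expect_error(compute_length_bounds(5), "at least two")
})

test_that("length filtering is a closed interval and keeps equal lengths", {
  recs <- protein_records(paste0("p", 1:3), rep("ph", 3),
                          rep("tail fiber protein", 3),
                          vapply(c(10, 20, 30), function(n) {
                            paste(rep("A", n), collapse = "")
                          }, character(1)))
  bounds <- structure(list(q1 = 10, q3 = 20, iqr = 10, lower = 10, upper = 20),
                      class = "length_bounds")
  expect_equal(filter_by_length(recs, bounds)$protein_id, c("p1", "p2"))
  expect_equal(nrow(filter_by_length(recs[0, ], bounds)), 0L)

  # all-equal lengths are never removed by their own fence
  eq <- protein_records(paste0("q", 1:5), rep("ph", 5),
                        rep("tail fiber protein", 5),
                        rep(paste(rep("A", 40), collapse = ""), 5))
  expect_equal(filter_by_length(eq, compute_length_bounds(eq$length)), eq)
})

test_that("mine_rbps catalogs every input with a kept/dropped reason", {
  recs <- protein_records(
    paste0("p", 1:5), rep("ph", 5),
    c("tail fiber protein", "tail fiber protein", "portal protein",
      "tail fiber protein", "tail fiber protein"),
    c(strrep("A", 100), strrep("A", 110), strrep("A", 100),
      paste0(strrep("A", 99), "X"), strrep("A", 105))
  )
  res <- mine_rbps(recs)
  expect_setequal(res$catalog$status[res$catalog$protein_id %in%
                                       c("p1", "p2", "p5")], "kept")
  expect_equal(res$catalog$status[3], "dropped:annotation")
  expect_equal(res$catalog$status[4], "dropped:undetermined")
  expect_equal(sort(res$rbps$protein_id), c("p1", "p2", "p5"))
})
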