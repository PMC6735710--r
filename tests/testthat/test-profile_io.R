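test_that("read_profile parses a plain CSV and applies the fill rules", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("protein_id,s1,s2,s3,s4",
               "A,1.0,1.0,1.0,1.0",
               "B,1.0,1.0,1.0,1.0",
               "C,1.0,1.0,1.0,1.0"), f)
  p <- read_profile(f)
  expect_s3_class(p, "cx_profile")
  expect_identical(p$protein_ids, c("A", "B", "C"))
  expect_equal(sum(p$intensities), 12)
  expect_equal(ncol(p$intensities), 4L)

  # empty cell reads as 0, everything else untouched
  writeLines(c("protein_id,s1,s2", "A,1,", "B,2,3"), f)
  p <- read_profile(f)
  expect_equal(p$intensities["A", 2], 0)
  expect_equal(p$intensities["B", 2], 3)

  # explicit NaN -> 0 with a warning counting replacements
  writeLines(c("protein_id,s1,s2", "A,NaN,1", "B,2,3"), f)
  expect_warning(p <- read_profile(f), "1 NaN")
  expect_equal(p$intensities["A", 1], 0)
})

test_that("read_profile rejects bad input with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  expect_error(read_profile(file.path(tempdir(), "nope.csv")), "not found")

  writeLines(c("protein_id,s1,s2", "A,1,2", "B,3,-4"), f)
  expect_error(read_profile(f), "negative intensity.*s2.*B")

  writeLines(c("protein_id,s1,s2", "A,1,2", "A,3,4"), f)
  expect_error(read_profile(f), "duplicate protein id.*A")

  writeLines(c("protein_id,s1,s2", "A,1,oops", "B,3,4"), f)
  expect_error(read_profile(f), "non-numeric.*oops")

  writeLines(c("protein_id,s1", "A,1"), f)
  expect_error(read_profile(f), "at least 2 slice")
})

test_that("annotation columns and gene-level collapse work", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("protein_id,gene,s1,s2",
               "A1,G1,1,1",
               "A2,G1,5,5",   # higher total: kept for G1
               "B1,G2,2,2"), f)
  p <- read_profile(f, annotation_columns = "gene")
  expect_equal(ncol(p$intensities), 2L)
  expect_identical(p$annotations$gene, c("G1", "G1", "G2"))

  q <- read_profile(f, annotation_columns = "gene", collapse_by = "gene")
  expect_identical(q$protein_ids, c("G1", "G2"))
  expect_equal(unname(q$intensities["G1", ]), c(5, 5))
})

test_that("write_profile / read_profile round-trips ids and intensities", {
  p <- toy_profile("rt", p = 4L, s = 6L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_profile(p, f)
  q <- read_profile(f, sample_id = "rt")
  expect_identical(q$protein_ids, p$protein_ids)
  expect_equal(q$intensities, p$intensities)
})

test_that("build_profile_set harmonizes rosters with union and zero fill", {
  a <- new_profile("a", matrix(1, 2, 3, dimnames = list(c("A", "B"), NULL)))
  b <- new_profile("b", matrix(2, 2, 3, dimnames = list(c("B", "C"), NULL)))
  ps <- build_profile_set(list(a, b))
  expect_identical(ps$protein_ids, c("A", "B", "C"))
  expect_equal(unname(ps$profiles$a$intensities["C", ]), c(0, 0, 0))
  expect_equal(unname(ps$profiles$b$intensities["A", ]), c(0, 0, 0))
  # identical row order everywhere
  for (p in ps$profiles)
    expect_identical(rownames(p$intensities), ps$protein_ids)

  # subset restriction and the no-overlap error
  ps_b <- build_profile_set(list(a, b), subset = "B")
  expect_identical(ps_b$protein_ids, "B")
  expect_equal(nrow(ps_b$profiles$a$intensities), 1L)
  expect_error(build_profile_set(list(a, b), subset = "Z"),
               "shares no proteins")

  # idempotence: harmonizing the harmonized set changes nothing
  ps2 <- build_profile_set(ps$profiles)
  expect_equal(ps2, ps)

  expect_error(build_profile_set(list(a)), "at least 2")
  expect_error(build_profile_set(list(a, a)), "duplicate sample")
})

test_that("read_groups parses two-column files and validates labels", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tcase", "s2\tcase", "s3\tcontrol"), f)
  g <- read_groups(f)
  expect_identical(g$case, c("s1", "s2"))
  expect_identical(g$control, "s3")

  writeLines(c("s1\tcase", "s2\tweird"), f)
  expect_error(read_groups(f), "unknown group label.*weird")
  writeLines(c("s1\tcase", "s1\tcontrol"), f)
  expect_error(read_groups(f), "more than once")
  expect_error(new_groups("s1", c("s1", "s2")), "both groups")
})

test_that("read_gene_sets handles GMT and two-column formats", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("MICOS\tdesc\tMIC60\tMIC19",
               "MIB\tdesc\tMIC60\tSAMM50\tMTX2"), f)
  sets <- read_gene_sets(f)
  expect_named(sets, c("MICOS", "MIB"))
  expect_length(sets$MICOS, 2L)

  writeLines(c("MICOS\td\tA", "MICOS\td\tB"), f)
  expect_error(read_gene_sets(f), "duplicate set name")
  writeLines(character(0), f)
  expect_error(read_gene_sets(f), "empty gene set file")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("S1\tA", "S1\tB", "S2\tC"), f2)
  sets2 <- read_gene_sets(f2, format = "two_column")
  expect_identical(sets2$S1, c("A", "B"))
})

test_that("write_alignment writes warped matrices, gaps and costs", {
  m <- toy_matrix(3L, 5L)
  pset <- build_profile_set(list(new_profile("a", m), new_profile("b", m)))
  aln <- progressive_align(pset)
  out <- withr::local_tempdir()
  write_alignment(aln, out)

  # identity alignment: per-sample files equal the inputs, L columns each
  mats <- read_aligned_dir(out)
  expect_named(mats, c("a", "b"))
  for (w in mats) {
    expect_equal(ncol(w), aln$L)
    expect_equal(unname(w), unname(m))
  }
  ins <- data.table::fread(file.path(out, "insertions.csv"),
                           data.table = FALSE)
  expect_equal(nrow(ins), 0L)
  cm <- data.table::fread(file.path(out, "pairwise_costs.csv"),
                          data.table = FALSE)
  expect_equal(unname(as.matrix(cm[-1])), matrix(0, 2, 2))
  expect_true(file.exists(file.path(out, "guide_tree.nwk")))
  expect_error(write_alignment(aln, out, format = "xlsx"), "not supported")
})

test_that("insertion table round-trips through write_alignment", {
  x <- toy_profile("x", p = 2L, s = 6L)
  y <- new_profile("y", apply_warp(x, insert_at = 3L)$intensities)
  pset <- build_profile_set(list(x, y))
  aln <- progressive_align(pset)
  out <- withr::local_tempdir()
  write_alignment(aln, out)
  ins <- data.table::fread(file.path(out, "insertions.csv"),
                           data.table = FALSE)
  expect_equal(ins$sample, insertion_report(aln)$sample)
  expect_equal(ins$position, insertion_report(aln)$position)
})
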