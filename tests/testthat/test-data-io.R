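test_that("FASTA records are parsed with order, ids and uppercasing preserved", {
  fa <- writeTempFasta(c("ACGT"), "s1")
  recs <- readFastaRecords(fa)
  expect_length(recs, 1)
  expect_equal(names(recs), "s1")
  expect_equal(as.character(recs[[1]]), "ACGT")

  fa2 <- writeTempFasta(c(strrep("A", 200), strrep("a", 200)), c("p1", "p2"))
  recs2 <- readFastaRecords(fa2)
  expect_length(recs2, 2)
  expect_equal(unique(Biostrings::width(recs2)), 200)
  expect_equal(as.character(recs2[[2]]), strrep("A", 200))
})

test_that("invalid FASTA input is rejected with informative errors", {
  fa <- writeTempFasta("ACGN", "s1")
  expect_error(readFastaRecords(fa), "s1")
  expect_error(readFastaRecords(fa), "N")

  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(readFastaRecords(empty), "empty")

  malformed <- tempfile(fileext = ".fa")
  writeLines(c("ACGT", ">s1"), malformed)
  expect_error(readFastaRecords(malformed), "malformed")

  expect_error(readFastaRecords(tempfile()), "not found")
})

test_that("write/read FASTA round trip reproduces ids and sequences exactly", {
  withr::with_seed(11, {
    seqs <- vapply(1:7, function(i) randomSeq(40), character(1))
  })
  names(seqs) <- paste0("rec", 1:7)
  path <- tempfile(fileext = ".fa")
  writeFastaRecords(seqs, path)
  back <- readFastaRecords(path)
  expect_equal(names(back), names(seqs))
  expect_equal(as.character(back), seqs, ignore_attr = TRUE)
})

test_that("loadBenchmark labels positives and negatives and records the task", {
  withr::with_seed(5, {
    pos <- vapply(1:10, function(i) randomSeq(200), character(1))
    neg <- vapply(1:10, function(i) randomSeq(200), character(1))
  })
  fp <- writeTempFasta(pos, paste0("e", 1:10))
  fn <- writeTempFasta(neg, paste0("n", 1:10))
  ds <- loadBenchmark(fp, fn, task = "identification")
  expect_s4_class(ds, "EnhancerSet")
  expect_length(ds, 20)
  expect_equal(sum(classLabels(ds) == 1), 10)
  expect_equal(sum(classLabels(ds) == 0), 10)
  expect_equal(taskType(ds), "identification")
})

test_that("benchmark mode enforces 200 bp and disambiguates duplicate ids", {
  short <- writeTempFasta("ACGTACGT", "s1")
  short2 <- writeTempFasta("GGGGCCCC", "s2")
  ok <- writeTempFasta(strrep("ACGT", 50), "s3")
  expect_error(loadBenchmark(short, ok, task = "identification"), "200")
  # without the benchmark length requirement any common length is accepted
  ds <- loadBenchmark(short, short2, task = "identification",
                      expectedLength = NULL)
  expect_length(ds, 2)

  dupA <- writeTempFasta(strrep("A", 200), "same")
  dupB <- writeTempFasta(strrep("G", 200), "same")
  expect_warning(ds2 <- loadBenchmark(dupA, dupB, task = "identification"),
                 "duplicated")
  expect_false(anyDuplicated(names(ds2)) > 0)
})

test_that("stratified folds are exact, exhaustive and deterministic", {
  ds <- tinyDataset(10, seed = 2)
  f <- stratifiedPartition(ds, k = 5, seed = 3)
  tab <- table(foldIndices(f), classLabels(ds))
  expect_true(all(tab == 2))  # 10 per class into 5 folds

  # partition property: every record in exactly one fold
  expect_setequal(names(foldIndices(f)), names(ds))
  expect_length(foldIndices(f), length(ds))

  f2 <- stratifiedPartition(ds, k = 5, seed = 3)
  expect_identical(foldIndices(f), foldIndices(f2))
  f3 <- stratifiedPartition(ds, k = 5, seed = 4)
  expect_false(identical(foldIndices(f), foldIndices(f3)))
})

test_that("benchmark-sized stratification gives four folds of 297 and one of 296 per class", {
  # 1,484 = 4 * 297 + 296; sequences only need to exist, so keep them short
  withr::with_seed(8, {
    seqs <- vapply(seq_len(2 * 1484), function(i) randomSeq(4), character(1))
  })
  names(seqs) <- paste0("r", seq_along(seqs))
  ds <- EnhancerSet(seqs, label = rep(c(1L, 0L), each = 1484))
  f <- stratifiedPartition(ds, k = 5, seed = 3)
  tab <- table(foldIndices(f), classLabels(ds))
  for (cls in c("0", "1"))
    expect_setequal(as.integer(tab[, cls]), c(297L, 297L, 297L, 297L, 296L))
  # stratification invariant: per-class fold sizes differ by at most 1
  expect_true(all(apply(tab, 2, function(x) diff(range(x))) <= 1))
})

test_that("a class smaller than k is refused", {
  ds <- tinyDataset(3, seed = 1)
  expect_error(stratifiedPartition(ds, k = 5, seed = 1), "fewer than k")
})

test_that("fold assignments export as a two-column table", {
  ds <- tinyDataset(5, seed = 1)
  f <- stratifiedPartition(ds, k = 2, seed = 9)
  path <- tempfile(fileext = ".tsv")
  writeFoldAssignment(f, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(names(back), c("id", "fold"))
  expect_setequal(back$id, names(ds))
})
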