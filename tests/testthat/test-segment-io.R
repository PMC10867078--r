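test_that("a well-formed export parses into typed rows", {
  rows <- segs(seg_row("s1", "Gain", "1", 1e6, 2e6, cn = 3),
               seg_row("s1", "Loss", "2", 1e6, 1.5e6, cn = 1),
               seg_row("s2", "LOH", "3", 1e6, 9e6, cn = 2))
  path <- write_export(rows)
  got <- read_segment_table(path, hg19)
  expect_identical(nrow(got), 3L)
  expect_setequal(got$seg_type, c("Gain", "Loss", "LOH"))
  # LOH rows carry no copy-number state
  expect_true(is.na(got$cn[got$seg_type == "LOH"]))
  expect_identical(got$cn[got$seg_type == "Gain"], 3)
})

test_that("invalid rows are rejected with row-numbered diagnostics", {
  rows <- segs(seg_row("s1", "LOH", "1", 5e6, 2e6),       # end < start
               seg_row("s1", "LOH", "99", 1e6, 2e6),      # unknown chromosome
               seg_row("s1", "Weird", "1", 1e6, 2e6),     # unknown type
               seg_row("s1", "LOH", "1", 1e6, 2e6))
  path <- write_export(rows)
  expect_warning(got <- read_segment_table(path, hg19), "rejected")
  expect_identical(nrow(got), 1L)
  rej <- attr(got, "rejected")
  expect_setequal(rej$row, 1:3)
  expect_match(rej$reason[rej$row == 1], "start greater than end")
})

test_that("a missing mandatory column is an error naming the column", {
  rows <- seg_row("s1", "LOH", "1", 1e6, 2e6)
  path <- write_export(rows)
  x <- utils::read.delim(path, check.names = FALSE)
  x$Chromosome <- NULL
  p2 <- tempfile(fileext = ".tsv")
  utils::write.table(x, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_segment_table(p2, hg19), "Chromosome")
})

test_that("parsing is order-independent after grouping", {
  set.seed(21)
  rows <- do.call(rbind, lapply(1:30, function(i)
    loh_row(sample(c("a", "b", "c"), 1), sample(1:22, 1),
            runif(1, 1, 20), start = sample.int(1e7, 1))))
  p1 <- write_export(rows)
  p2 <- write_export(rows[sample(nrow(rows)), ])
  key <- function(x) {
    x <- x[order(x$sample_id, x$chrom, x$start), ]
    rownames(x) <- NULL
    x
  }
  expect_equal(key(read_segment_table(p1, hg19)),
               key(read_segment_table(p2, hg19)))
})

test_that("phenotype tables parse indicator columns into term sets", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,sex,age_years,ASD,DD,ID",
               "s1,male,4,1,1,0", "s2,female,9,0,1,1",
               "s3,male,2,0,0,0", "s4,female,6,1,0,0",
               "s5,male,1,1,1,1", "s6,male,8,0,0,1"), csv)
  phe <- read_phenotype_table(csv)
  expect_identical(nrow(phe), 6L)
  expect_setequal(phe$phenotype_terms[[1]], c("asd", "dd"))
  expect_identical(phe$phenotype_terms[[3]], character(0))
  expect_setequal(phe$phenotype_terms[[5]], c("asd", "dd", "id"))
})

test_that("duplicate sample ids in phenotypes are fatal, orphans are not", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,dd", "s1,1", "s1,0"), csv)
  expect_error(read_phenotype_table(csv), "s1")

  csv2 <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,dd", "s1,1", "s9,0"), csv2)
  phe <- read_phenotype_table(csv2)
  coh <- match_cohort(seg_row("s1", "LOH", "1", 1e6, 2e6), phe)
  expect_identical(coh$orphans$phenotypes_only, "s9")
})

test_that("BED output is 0-based half-open and round-trips exactly", {
  path <- tempfile(fileext = ".bed")
  write_bed(seg_row("s1", "LOH", "1", 1, 10), path)
  line <- readLines(path)[2]
  expect_identical(line, "chr1\t0\t10\ts1:LOH\t0\t.")

  # empty input: header only
  p2 <- tempfile(fileext = ".bed")
  write_bed(seg_row("x", "LOH", "1", 1, 1)[0, ], p2)
  expect_identical(length(readLines(p2)), 1L)

  set.seed(22)
  rows <- do.call(rbind, lapply(1:100, function(i) {
    ch <- sample(c(1:22, "X"), 1)
    start <- sample.int(1e7, 1)
    seg_row(paste0("s", sample(1:5, 1)), "LOH", ch, start,
            start + sample.int(2e7, 1))
  }))
  p3 <- tempfile(fileext = ".bed")
  write_bed(rows, p3)
  back <- read_bed(p3)
  key <- function(x) {
    x <- x[order(x$sample_id, x$chrom, x$start),
           c("sample_id", "chrom", "start", "end")]
    rownames(x) <- NULL
    x
  }
  expect_equal(key(back), key(rows))
})

test_that("the multi-segment worked example parses to an 88.8 Mbp LOH sum", {
  ex <- upd_worked_examples()
  e <- ex[ex$case == "147", ]
  path <- write_export(seg_row("case147", "LOH", e$chrom, e$start, e$end))
  got <- read_segment_table(path, hg19)
  expect_identical(nrow(got), 3L)
  expect_true(all(got$seg_type == "LOH"))
  expect_equal(round(sum(interval_length_mbp(got$start, got$end)), 1), 88.8)
})
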