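test_that("the 3 Mbp analysis threshold is inclusive", {
  rows <- segs(loh_row("s1", 1, 2.9),
               loh_row("s1", 2, 3.0),
               loh_row("s1", "X", 8))
  l <- filter_lcsh(rows)
  expect_identical(l$masked_reason,
                   c("below-threshold", "none", "none"))
  expect_identical(l$is_autosomal, c(TRUE, TRUE, FALSE))
  a <- analyzable_lcsh(l)
  expect_identical(nrow(a), 2L)
  expect_error(filter_lcsh(rows, min_size_mbp = 0), "positive")
})

test_that("hemizygous LOH over single-copy losses is masked by fraction", {
  # 12 Mbp LOH fully inside a 15 Mbp copy-number-1 loss: masked
  rows <- loh_row("s1", 4, 12, start = 10e6)
  loss <- as_cnv_calls(seg_row("s1", "Loss", 4, 9e6, 24e6, cn = 1))
  l <- mask_hemizygous(filter_lcsh(rows), loss)
  expect_identical(l$masked_reason, "hemizygous-overlap")

  # no overlapping loss: kept
  loss2 <- as_cnv_calls(seg_row("s1", "Loss", 5, 9e6, 24e6, cn = 1))
  expect_identical(mask_hemizygous(filter_lcsh(rows), loss2)$masked_reason,
                   "none")

  # 10 Mbp LOH overlapping a deletion by 3 Mbp (30%): kept under 50% rule
  rows3 <- loh_row("s1", 4, 10, start = 10e6)
  loss3 <- as_cnv_calls(seg_row("s1", "Loss", 4, 7e6, 12999999, cn = 1))
  frac <- overlap_bp("4", 10e6, 10e6 + 10e6 - 1, "4", 7e6, 12999999) / 10e6
  expect_equal(frac, 0.3)
  expect_identical(mask_hemizygous(filter_lcsh(rows3), loss3)$masked_reason,
                   "none")
  # ... but masked once the configured fraction drops below the overlap
  expect_identical(mask_hemizygous(filter_lcsh(rows3), loss3,
                                   min_overlap_fraction = 0.25)$masked_reason,
                   "hemizygous-overlap")
})

test_that("masking is idempotent, per-sample, and ignores copy-neutral calls", {
  rows <- loh_row("s1", 4, 12, start = 10e6)
  loss_other <- as_cnv_calls(seg_row("s2", "Loss", 4, 9e6, 24e6, cn = 1))
  expect_identical(mask_hemizygous(filter_lcsh(rows), loss_other)$masked_reason,
                   "none")
  gain <- as_cnv_calls(seg_row("s1", "Gain", 4, 9e6, 24e6, cn = 3))
  expect_identical(mask_hemizygous(filter_lcsh(rows), gain)$masked_reason,
                   "none")
  loss <- as_cnv_calls(seg_row("s1", "Loss", 4, 9e6, 24e6, cn = 1))
  once <- mask_hemizygous(filter_lcsh(rows), loss)
  twice <- mask_hemizygous(once, loss)
  expect_identical(once, twice)
  expect_error(mask_hemizygous(filter_lcsh(rows), data.frame(x = 1)),
               "sample_id")
})

test_that("union coverage across several deletions masks jointly", {
  # two 4 Mbp deletions covering 80% of a 10 Mbp LOH only jointly
  rows <- loh_row("s1", 6, 10, start = 10e6)
  losses <- as_cnv_calls(segs(
    seg_row("s1", "Loss", 6, 10e6, 13999999, cn = 1),
    seg_row("s1", "Loss", 6, 15e6, 18999999, cn = 1)))
  expect_identical(mask_hemizygous(filter_lcsh(rows), losses)$masked_reason,
                   "hemizygous-overlap")
})

test_that("masking and filtering commute on the analyzable set", {
  set.seed(31)
  rows <- do.call(rbind, lapply(1:40, function(i)
    loh_row("s1", sample(1:22, 1), runif(1, 1, 15),
            start = sample.int(2e7, 1))))
  losses <- as_cnv_calls(segs(seg_row("s1", "Loss", 3, 1e6, 2e7, cn = 1),
                              seg_row("s1", "Loss", 9, 1e6, 3e7, cn = 1)))
  a1 <- analyzable_lcsh(mask_hemizygous(filter_lcsh(rows), losses))
  # mask first at the full (unthresholded) set, then filter
  l0 <- filter_lcsh(rows, min_size_mbp = 1e-9)
  l0 <- mask_hemizygous(l0, losses)
  keep <- l0$masked_reason == "none" & l0$size_mbp >= 3
  a2 <- l0[keep, ]
  key <- function(x) {
    x <- x[order(x$chrom, x$start), c("chrom", "start", "end", "size_mbp")]
    rownames(x) <- NULL
    x
  }
  expect_equal(key(a1), key(a2))
})

test_that("per-sample summaries report the sub-5/ge-5 pattern", {
  expect_equal(
    per_sample_lcsh_summary(filter_lcsh(loh_row("s1", 1, 2)[0, ]),
                            sample_ids = "s1"),
    data.frame(sample_id = "s1", n = 0L, largest_mbp = 0, sum_mbp = 0,
               has_only_sub5 = FALSE, has_ge5 = FALSE,
               stringsAsFactors = FALSE))
  s <- per_sample_lcsh_summary(filter_lcsh(segs(
    loh_row("s1", 1, 3.2), loh_row("s1", 5, 4.9))))
  expect_true(s$has_only_sub5); expect_false(s$has_ge5)

  s2 <- per_sample_lcsh_summary(filter_lcsh(segs(
    loh_row("s1", 2, 9.9, 1e6), loh_row("s1", 2, 33, 20e6),
    loh_row("s1", 2, 45.9, 60e6))))
  expect_equal(round(s2$sum_mbp, 1), 88.8)
  expect_true(s2$has_ge5)
  # sex-chromosome LCSH never enter the summary
  s3 <- per_sample_lcsh_summary(filter_lcsh(segs(
    loh_row("s1", 2, 9.9, 1e6), loh_row("s1", 2, 33, 20e6),
    loh_row("s1", 2, 45.9, 60e6), loh_row("s1", "X", 20))))
  expect_equal(s3$sum_mbp, s2$sum_mbp)
})

test_that("per-sample sums are invariant under row order", {
  set.seed(32)
  rows <- do.call(rbind, lapply(1:25, function(i)
    loh_row("s1", sample(1:22, 1), runif(1, 3, 12),
            start = sample.int(2e7, 1))))
  s1 <- per_sample_lcsh_summary(filter_lcsh(rows))
  s2 <- per_sample_lcsh_summary(filter_lcsh(rows[sample(nrow(rows)), ]))
  expect_equal(s1$sum_mbp, s2$sum_mbp)
  expect_equal(s1$n, s2$n)
})
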