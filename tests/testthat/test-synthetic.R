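test_that("config validation rejects inconsistent mixtures", {
  expect_error(sim_config(class_mixture = c(first = 0.6, second = 0.5)),
               "exceeds 1")
  expect_error(sim_config(mu_mbp = c(first = 2, second = 33, third = 25,
                                     fourth = 20, fifth = 17)),
               "3 Mbp")
  expect_s3_class(sim_config(n_samples = 5), "sim_config")
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(n_samples = 15, seed = 99)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  s1 <- simulate_cohort(cfg, out_dir = d1)
  s2 <- simulate_cohort(cfg, out_dir = d2)
  expect_identical(s1$segments, s2$segments)
  expect_identical(s1$truth, s2$truth)
  for (f in c("segments.tsv", "phenotypes.csv", "truth.json"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  # a different seed changes the data
  s3 <- simulate_cohort(sim_config(n_samples = 15, seed = 100))
  expect_false(identical(s1$segments, s3$segments))
})

test_that("all-outbred, event-free cohorts contain no >=5 Mbp LCSH", {
  cfg <- sim_config(n_samples = 10, seed = 3, class_mixture = c(first = 0),
                    upd = list(fraction = 0, types = c(`whole-iso` = 1)),
                    common_regions = data.frame()[0, ],
                    hemizygous = list(fraction = 0))
  sim <- simulate_cohort(cfg)
  expect_identical(unique(sim$truth$kinship_degree), "outbred")
  parsed <- parse_segment_frame(sim$segments)
  l <- analyzable_lcsh(filter_lcsh(parsed))
  expect_true(all(l$size_mbp[l$is_autosomal] < 5))
})

test_that("simulated files parse cleanly through the segment reader", {
  cfg <- sim_config(n_samples = 25, seed = 8)
  d <- file.path(tempdir(), "sim_parse")
  sim <- simulate_cohort(cfg, out_dir = d)
  got <- read_segment_table(file.path(d, "segments.tsv"), hg19)
  expect_identical(nrow(got), nrow(sim$segments))
  expect_identical(nrow(attr(got, "rejected")), 0L)
  phe <- read_phenotype_table(file.path(d, "phenotypes.csv"))
  expect_identical(nrow(phe), 25L)
  expect_length(match_cohort(got, phe)$orphans$phenotypes_only, 0)
})

test_that("inbred block totals follow the compound-Poisson expectation", {
  # first-cousin offspring (third degree): expected total about 2881/16 Mbp
  set.seed(71)
  totals <- replicate(400, {
    b <- simulate_inbred_autozygosity("third", hg19)
    if (nrow(b)) sum(interval_length_mbp(b$start, b$end)) else 0
  })
  expect_lt(abs(mean(totals) - 2881 / 16) / (2881 / 16), 0.10)
  expect_identical(nrow(simulate_inbred_autozygosity("outbred", hg19)), 0L)
  expect_error(simulate_inbred_autozygosity("ninth", hg19), "degree")
})

test_that("UPD pattern generators honor their size contracts", {
  set.seed(72)
  for (i in 1:25) {
    w <- simulate_upd_sample("whole-iso", "15", hg19)
    expect_identical(nrow(w), 1L)
    expect_gte((w$end - w$start + 1) / hg19$chromosomes[["15"]], 0.90)
    m <- simulate_upd_sample("iso-het-mix", "9", hg19)
    sz <- interval_length_mbp(m$start, m$end)
    expect_true(all(sz >= 5 - 1e-6))
    expect_gte(sum(sz), 10 - 1e-6)
    s <- simulate_upd_sample("segmental", "4", hg19)
    len <- interval_length_mbp(s$start, s$end)
    expect_gte(len, 10 - 1e-6); expect_lte(len, 20 + 1e-6)
    expect_true(s$start == 1 || s$end == hg19$chromosomes[["4"]])
  }
  expect_error(simulate_upd_sample("whole-iso", "X", hg19), "autosome")
  # a sub-10 Mbp terminal stretch is a negative control for the caller
  neg <- seg_row("s", "LOH", "4", 1, 8e6)
  expect_identical(nrow(call_upd_candidates(filter_lcsh(neg))), 0L)
})

test_that("truth labels align with emitted segments", {
  cfg <- sim_config(n_samples = 40, seed = 12,
                    upd = list(fraction = 0.2, types = c(`whole-iso` = 1)),
                    common_regions = data.frame()[0, ],
                    hemizygous = list(fraction = 0))
  sim <- simulate_cohort(cfg)
  parsed <- parse_segment_frame(sim$segments)
  l <- filter_lcsh(parsed)
  upd_true <- sim$truth[!is.na(sim$truth$upd_type), ]
  expect_gt(nrow(upd_true), 0)
  for (i in seq_len(nrow(upd_true))) {
    a <- analyzable_lcsh(l)
    seg <- a[a$sample_id == upd_true$sample_id[i] &
               a$chrom == upd_true$upd_chrom[i], ]
    expect_gte(sum(seg$size_mbp), 10)
  }
})

test_that("hemizygous artifacts are co-emitted and masked by the pipeline", {
  cfg <- sim_config(n_samples = 6, seed = 21,
                    class_mixture = c(first = 0),
                    upd = list(fraction = 0, types = c(`whole-iso` = 1)),
                    common_regions = data.frame()[0, ],
                    hemizygous = list(fraction = 1))
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$truth$hemizygous_artifact))
  fit <- lcsh_analysis(parse_segment_frame(sim$segments))
  expect_gte(fit$counts[["hemizygous_masked"]], 6)
  # no artifact survives into UPD calling
  expect_identical(nrow(fit$upd$candidates), 0L)
})

test_that("the sub-5 / ge-5 sample pattern is calibratable to cohort scale", {
  # a lighter background (mean 1.55 blocks) with the default event rates
  # targets the observed clinical pattern of roughly 59% of samples with
  # only sub-5 Mbp LCSH and roughly 31% with at least one >=5 Mbp LCSH
  cfg <- sim_config(n_samples = 953, seed = 31,
                    background = list(mean_count = 1.55,
                                      size_mean_excess = 0.6))
  sim <- simulate_cohort(cfg)
  fit <- lcsh_analysis(parse_segment_frame(sim$segments),
                       sample_ids = sim$truth$sample_id)
  s <- fit$lcsh_summary
  expect_lt(abs(mean(s$has_only_sub5) - 0.59), 0.05)
  expect_lt(abs(mean(s$has_ge5) - 0.31), 0.05)
})
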