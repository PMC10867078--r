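test_that("Fisher exact p and sample OR on worked tables", {
  r <- fisher_exact_2x2(5, 5, 5, 5)
  expect_equal(r$p_value, 1)
  expect_equal(r$odds_ratio, 1)
  # value frozen from the exhaustive hypergeometric enumeration oracle
  r2 <- fisher_exact_2x2(1, 9, 11, 3)
  expect_equal(r2$p_value, 0.002759456, tolerance = 1e-6)
  expect_equal(r2$p_value, fisher_oracle(1, 9, 11, 3), tolerance = 1e-12)
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("zero cells get the Haldane-Anscombe correction, flagged", {
  r <- fisher_exact_2x2(0, 10, 5, 5)
  expect_true(r$haldane)
  expect_equal(r$odds_ratio, (0.5 * 5.5) / (10.5 * 5.5))
  expect_false(fisher_exact_2x2(1, 10, 5, 5)$haldane)
})

test_that("published 2x2 counts reproduce the printed significance bands", {
  # developmental delay: 377/706 negatives vs 119/175 pathogenic carriers
  dd <- fisher_exact_2x2(377, 706 - 377, 119, 175 - 119)
  expect_lte(dd$p_value, 0.0005)
  expect_equal(dd$odds_ratio, (377 * 56) / (329 * 119))
  expect_true(dd$odds_ratio > 0.53 && dd$odds_ratio < 0.54)
  # autism spectrum disorder: 255/706 vs 34/175
  asd <- fisher_exact_2x2(255, 706 - 255, 34, 175 - 34)
  expect_lte(asd$p_value, 0.0005)
  expect_gt(asd$odds_ratio, 1)   # enriched in the negative group
})

test_that("Fisher p agrees with enumeration across random small tables", {
  set.seed(61)
  for (i in 1:200) {
    a <- sample(0:30, 1); b <- sample(0:(30 - a), 1)
    c <- sample(0:30, 1); d <- sample(0:(30 - c), 1)
    if (a + b + c + d == 0) next
    expect_equal(fisher_exact_2x2(a, b, c, d)$p_value,
                 fisher_oracle(a, b, c, d), tolerance = 1e-9)
  }
})

test_that("transposing the groups inverts the OR and preserves p", {
  set.seed(62)
  for (i in 1:50) {
    x <- sample(1:20, 4, replace = TRUE)
    r1 <- fisher_exact_2x2(x[1], x[2], x[3], x[4])
    r2 <- fisher_exact_2x2(x[3], x[4], x[1], x[2])
    expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
    expect_equal(r1$odds_ratio, 1 / r2$odds_ratio, tolerance = 1e-12)
  }
})

test_that("association table excludes inconclusive samples and orients ORs", {
  classes <- data.frame(
    sample_id = sprintf("s%03d", 1:100),
    class = c(rep("none", 60), rep("benign", 10), rep("VUS", 10),
              rep("PCNV", 20)))
  set.seed(63)
  phe <- data.frame(sample_id = classes$sample_id, stringsAsFactors = FALSE)
  carrier <- classes$class == "PCNV"
  phe$phenotype_terms <- I(lapply(seq_len(100), function(i) {
    t <- character()
    if (runif(1) < ifelse(carrier[i], 0.8, 0.4)) t <- c(t, "dd")
    if (i == 1) t <- c(t, "ghost")   # term absent elsewhere still counted
    t
  }))
  tab <- phenotype_association_table(classes, phe)
  dd <- tab[tab$term == "dd", ]
  # denominators: 70 negatives, 20 pathogenic (VUS excluded)
  expect_identical(dd$a + dd$b, 70L)
  expect_identical(dd$c + dd$d, 20L)
  expect_equal(dd$or_negative_vs_pathogenic,
               1 / dd$or_pathogenic_vs_negative)
  expect_true(all(c("p_bh", "significant") %in% names(tab)))
  # a term carried by nobody in either group is skipped
  phe2 <- phe
  phe2$phenotype_terms <- I(lapply(phe$phenotype_terms, setdiff, "ghost"))
  tab2 <- phenotype_association_table(classes, phe2)
  expect_false("ghost" %in% tab2$term)
})

test_that("label-shuffled cohorts give near-uniform small-p rates", {
  set.seed(64)
  n_neg <- 250; n_pat <- 60
  pheno <- rbinom(n_neg + n_pat, 1, 0.5)
  hits <- replicate(200, {
    shuffled <- sample(pheno)
    a <- sum(shuffled[1:n_neg]); c <- sum(shuffled[-(1:n_neg)])
    fisher_exact_2x2(a, n_neg - a, c, n_pat - c)$p_value <= 0.05
  })
  expect_gte(mean(hits), 0.02)
  expect_lte(mean(hits), 0.09)
})

test_that("Tukey comparisons separate shifted groups and not identical ones", {
  set.seed(67)
  vals <- rnorm(15)
  same <- class_mean_comparison(c(vals, vals), rep(c("a", "b"), each = 15))
  expect_gte(same$p_adj, 0.99)
  set.seed(65)
  shift <- class_mean_comparison(c(rnorm(50, 0), rnorm(50, 5)),
                                 rep(c("a", "b"), each = 50))
  expect_lt(shift$p_adj, 0.001)
  # degenerate groups are excluded and listed
  out <- class_mean_comparison(c(rnorm(20), rnorm(20, 3), 7),
                               c(rep("a", 20), rep("b", 20), "single"))
  expect_identical(attr(out, "excluded"), "single")
  expect_error(class_mean_comparison(1:3, c("a", "b", "c")), "two classes")
})

test_that("simulated class-size contrasts reach Tukey significance", {
  # pathogenic calls are drawn far larger than benign ones, as in clinical
  # cohorts; the PCNV-benign comparison must flag
  set.seed(66)
  sizes <- c(rlnorm(60, log(8000), 1), rlnorm(200, log(300), 1),
             rlnorm(60, log(800), 1))
  cls <- c(rep("PCNV", 60), rep("benign", 200), rep("VUS", 60))
  out <- class_mean_comparison(sizes, cls)
  pb <- out$p_adj[out$comparison %in% c("PCNV-benign", "benign-PCNV")]
  expect_lt(pb, 0.001)
})
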