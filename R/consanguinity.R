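# Inbreeding coefficient from summed autosomal LCSH and kinship degree.

#' Kinship degree classes
#'
#' The degree-of-kinship classes form a geometric series of expected
#' identity-by-descent fractions (first degree F = 1/4, second 1/8, ...,
#' seventh-or-more 1/128). Class boundaries are the geometric means of
#' adjacent nominal values, with a floor of 0.005 below which no inbreeding
#' is called; the boundaries are exposed here as configurable constants.
#'
#' @return data.frame with `class`, `nominal_f`, `expected_ibd_percent`,
#'   `lower` (inclusive lower F boundary of the class).
#' @export
kinship_classes <- function() {
  nominal <- c(first = 1/4, second = 1/8, third = 1/16, fourth = 1/32,
               fifth = 1/64, `seventh-or-more` = 1/128)
  lower <- c(sqrt(nominal[-length(nominal)] * nominal[-1]), 0.005)
  data.frame(
    class = c(names(nominal), "none"),
    nominal_f = c(unname(nominal), 0),
    expected_ibd_percent = c(25, 12.5, 6, 3, 1.5, 0.5, 0),
    lower = c(unname(lower), 0),
    stringsAsFactors = FALSE
  )
}

#' Inbreeding coefficient from summed autosomal LCSH
#'
#' `F = sum_mbp / genome_mbp`, with the denominator the constant 2881 Mbp
#' autosomal genome (GRCh37). The value is returned at full precision;
#' reports round to 3 decimals. Sex-chromosome LCSH must not be included in
#' the sum. This is a crude genomic estimate: the >= 3 Mbp threshold and
#' SNP-sparse regions make it an underestimate of true autozygosity.
#'
#' @param sum_mbp summed autosomal analyzable LCSH in Mbp (vectorized).
#' @param genome_mbp autosomal genome size constant in Mbp.
#' @return numeric vector of F values.
#' @examples
#' round(inbreeding_coefficient(760), 3) # 0.264
#' @export
inbreeding_coefficient <- function(sum_mbp, genome_mbp = 2881) {
  if (any(sum_mbp < 0)) stop_domain("LCSH sum cannot be negative")
  sum_mbp / genome_mbp
}

#' Classify an inbreeding coefficient into a kinship degree
#'
#' Nearest class on a log scale: boundaries are geometric means between the
#' halving nominal class values (see [kinship_classes()]).
#'
#' @param f inbreeding coefficient(s) in `[0, 1]`.
#' @param classes boundary table, by default [kinship_classes()].
#' @return character vector of class labels.
#' @examples
#' classify_kinship(c(0.264, 0.116, 0.032, 0)) # first second fourth none
#' @export
classify_kinship <- function(f, classes = kinship_classes()) {
  if (any(is.na(f)) || any(f < 0 | f > 1))
    stop_domain("F must lie in [0, 1]")
  idx <- vapply(f, function(x) which(x >= classes$lower)[1], 1L)
  classes$class[idx]
}

#' Per-sample consanguinity reports
#'
#' Sums autosomal analyzable LCSH per sample, computes F and the kinship
#' class. Samples whose analyzable autosomal LCSH are confined to a single
#' chromosome that triggered a UPD candidate are flagged `upd_only`; their
#' homozygosity pattern suggests a disomy event rather than inbreeding and
#' they are excluded from cohort inbreeding fractions.
#'
#' @param lcsh LCSH table ([filter_lcsh()] / [mask_hemizygous()]).
#' @param sample_ids samples to report (default: all in `lcsh`).
#' @param upd_candidates optional UPD candidate table from
#'   [call_upd_candidates()] used to set the `upd_only` flag.
#' @param genome_mbp autosomal genome constant in Mbp.
#' @return data.frame: `sample_id`, `sum_mbp`, `f_hat`, `f_reported`
#'   (3 decimals), `kinship_class`, `expected_ibd_percent`, `upd_only`.
#' @export
consanguinity_report <- function(lcsh, sample_ids = NULL,
                                 upd_candidates = NULL, genome_mbp = 2881) {
  summ <- per_sample_lcsh_summary(lcsh, sample_ids)
  f <- inbreeding_coefficient(summ$sum_mbp, genome_mbp)
  cls <- classify_kinship(pmin(f, 1))
  k <- kinship_classes()
  upd_only <- rep(FALSE, nrow(summ))
  if (!is.null(upd_candidates) && nrow(upd_candidates)) {
    a <- analyzable_lcsh(lcsh)
    a <- a[a$is_autosomal, , drop = FALSE]
    for (i in seq_len(nrow(summ))) {
      cand <- upd_candidates[upd_candidates$sample_id == summ$sample_id[i], ]
      if (!nrow(cand)) next
      chroms <- unique(a$chrom[a$sample_id == summ$sample_id[i]])
      upd_only[i] <- length(chroms) == 1 && chroms == cand$chrom[1]
    }
  }
  data.frame(
    sample_id = summ$sample_id,
    sum_mbp = summ$sum_mbp,
    f_hat = f,
    f_reported = round(f, 3),
    kinship_class = cls,
    expected_ibd_percent = k$expected_ibd_percent[match(cls, k$class)],
    upd_only = upd_only,
    stringsAsFactors = FALSE
  )
}

#' Cohort consanguinity profile
#'
#' Per-class counts and fractions over the analyzable samples, excluding
#' UPD-only samples, plus the clinically more relevant first-to-fifth degree
#' aggregate.
#'
#' @param reports output of [consanguinity_report()].
#' @return list with `n` (denominator), `by_class` (count and fraction per
#'   class), `inbred_fraction` (any class other than `none`) and
#'   `first_to_fifth_fraction`.
#' @export
cohort_consanguinity_profile <- function(reports) {
  r <- reports[!reports$upd_only, , drop = FALSE]
  n <- nrow(r)
  classes <- kinship_classes()$class
  counts <- vapply(classes, function(cl) sum(r$kinship_class == cl), 1L)
  by_class <- data.frame(class = classes, count = unname(counts),
                         fraction = if (n) unname(counts) / n else rep(0, length(counts)),
                         stringsAsFactors = FALSE)
  first_to_fifth <- c("first", "second", "third", "fourth", "fifth")
  list(
    n = n,
    by_class = by_class,
    inbred_fraction = if (n) sum(r$kinship_class != "none") / n else 0,
    first_to_fifth_fraction =
      if (n) sum(r$kinship_class %in% first_to_fifth) / n else 0
  )
}
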