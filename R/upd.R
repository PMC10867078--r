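# Rule-based calling of potential uniparental disomy from LCSH patterns.

#' Chromosomes with clinically relevant imprinted regions
#' @export
IMPRINTED_CHROMOSOMES <- c("6", "7", "11", "14", "15", "20")

.imprinting_notes <- c(
  `6` = "transient neonatal diabetes mellitus (UPD(6)pat)",
  `7` = "Silver-Russell syndrome (UPD(7)mat)",
  `11` = "Beckwith-Wiedemann syndrome (UPD(11)pat); Silver-Russell-like (UPD(11)mat)",
  `14` = "Temple syndrome (UPD(14)mat); Kagami-Ogata syndrome (UPD(14)pat)",
  `15` = "Prader-Willi syndrome (UPD(15)mat); Angelman syndrome (UPD(15)pat)",
  `20` = "growth restriction/Mulchandani syndrome (UPD(20)mat); pseudohypoparathyroidism 1B (UPD(20)pat)"
)

#' Flag a chromosome for imprinting disorders
#'
#' @param chrom chromosome name.
#' @return list with `flag` (TRUE for chromosomes 6, 7, 11, 14, 15, 20) and
#'   `note` naming the canonical imprinting syndromes, or NA.
#' @export
flag_imprinted <- function(chrom) {
  ch <- normalize_chrom(chrom)
  flag <- ch %in% IMPRINTED_CHROMOSOMES
  list(flag = flag,
       note = ifelse(flag, unname(.imprinting_notes[ch]), NA_character_))
}

#' Call potential UPD candidates from single-chromosome homozygosity
#'
#' Isodisomy leaves long homozygous stretches confined to one chromosome.
#' Two rules, applied to the analyzable (masked, >= 3 Mbp) autosomal LCSH of
#' each sample:
#'
#' * Rule B: exactly one autosome carries LCSH over `ge_threshold_mbp`
#'   (strictly), and that autosome's LCSH total is at least `min_total_mbp` -
#'   a candidate regardless of smaller LCSH elsewhere. If two or more
#'   autosomes carry LCSH over the threshold, no candidate is called
#'   (multiple chromosomes with large LCSH suggest inbreeding instead).
#' * Rule A: no LCSH anywhere reaches `ge_threshold_mbp`, but one autosome
#'   accumulates two or more LCSH summing to at least `min_total_mbp`
#'   (a recombined isodisomy split into several sub-threshold stretches).
#'   Note two segments each under 5 Mbp cannot reach 10 Mbp, so in practice
#'   rule A needs at least three segments; the rule is kept literal.
#'
#' At most one candidate is emitted per sample; if several autosomes qualify
#' under rule A the largest total wins. Sex chromosomes never yield
#' candidates. Input must already be hemizygosity-masked: a table without a
#' `masked_reason` column is a usage error.
#'
#' @param lcsh LCSH table ([filter_lcsh()], after [mask_hemizygous()]).
#' @param min_total_mbp minimum single-chromosome LCSH total (default 10,
#'   inclusive).
#' @param ge_threshold_mbp the "large segment" threshold (default 5; the
#'   trigger and the multi-chromosome disqualifier both use strictly
#'   "over" this value).
#' @return data.frame with one row per candidate: `sample_id`, `chrom`,
#'   `n_segments`, `total_mbp`, `rule` (`"A"` or `"B"`), `imprinted`,
#'   `imprinting_note`, `segments` (list-column of member intervals).
#' @export
call_upd_candidates <- function(lcsh, min_total_mbp = 10,
                                ge_threshold_mbp = 5) {
  if (!("masked_reason" %in% names(lcsh)))
    stop_domain("call_upd_candidates needs masked LCSH input ",
                "(run filter_lcsh()/mask_hemizygous() first)")
  a <- analyzable_lcsh(lcsh)
  out <- lapply(unique(a$sample_id), function(id) {
    s <- a[a$sample_id == id, , drop = FALSE]
    auto <- s[s$is_autosomal, , drop = FALSE]
    if (!nrow(auto)) return(NULL)
    big <- s$size_mbp > ge_threshold_mbp          # genome-wide, incl. sex chroms
    big_auto_chroms <- unique(auto$chrom[auto$size_mbp > ge_threshold_mbp])
    totals <- tapply(auto$size_mbp, auto$chrom, sum)
    pick <- NULL; rule <- NULL
    if (length(big_auto_chroms) == 1) {
      ch <- big_auto_chroms
      if (totals[[ch]] >= min_total_mbp) { pick <- ch; rule <- "B" }
    } else if (length(big_auto_chroms) == 0 && !any(big)) {
      counts <- tapply(auto$size_mbp, auto$chrom, length)
      ok <- names(totals)[totals >= min_total_mbp & counts >= 2]
      if (length(ok)) { pick <- ok[which.max(totals[ok])]; rule <- "A" }
    }
    if (is.null(pick)) return(NULL)
    seg <- auto[auto$chrom == pick, c("chrom", "start", "end", "size_mbp")]
    imp <- flag_imprinted(pick)
    data.frame(sample_id = id, chrom = pick,
               n_segments = nrow(seg), total_mbp = sum(seg$size_mbp),
               rule = rule, imprinted = imp$flag,
               imprinting_note = imp$note,
               segments = I(list(seg)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(sample_id = character(), chrom = character(),
                      n_segments = integer(), total_mbp = numeric(),
                      rule = character(), imprinted = logical(),
                      imprinting_note = character(),
                      segments = I(list()), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cohort UPD candidate rate
#'
#' @param candidates output of [call_upd_candidates()].
#' @param n_samples number of analyzable samples (denominator).
#' @return fraction of samples with a candidate.
#' @export
cohort_upd_rate <- function(candidates, n_samples) {
  if (n_samples <= 0) return(0)
  length(unique(candidates$sample_id)) / n_samples
}

#' Bundled worked examples of UPD-suggestive LCSH patterns
#'
#' Curated per-case LCSH segment lists (GRCh37 coordinates) in which one
#' autosome accumulates >= 10 Mbp of homozygosity - the textbook pattern
#' for a potential isodisomy. Fed as single-sample inputs with clean
#' backgrounds, each case yields exactly one UPD candidate; the set also
#' exercises multi-segment totals and imprinted-chromosome flagging.
#'
#' @return data.frame with `case`, `chrom`, `start`, `end`.
#' @export
upd_worked_examples <- function() {
  path <- system.file("extdata", "upd_worked_examples.tsv",
                      package = "lcshkit", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(case = "character", chrom = "character"))
}
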