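# LCSH selection: size threshold, autosomal/sex split, hemizygosity masking.

#' Select analyzable LCSH from parsed segment rows
#'
#' Keeps LOH rows and tags each with its size in Mbp, whether it is
#' autosomal, and a masking reason. Segments below the clinical size
#' threshold get `masked_reason = "below-threshold"`; sex-chromosome LCSH are
#' retained but flagged `is_autosomal = FALSE` (they are excluded later from
#' consanguinity sums and UPD calling). The threshold comparison is
#' inclusive (>=).
#'
#' @param rows parsed segment table (see [read_segment_table()]).
#' @param min_size_mbp analysis threshold in Mbp (default 3, the clinical
#'   convention; population studies use far lower cut-offs).
#' @return data.frame of LCSH segments with columns `sample_id`, `chrom`,
#'   `start`, `end`, `size_mbp`, `is_autosomal`, `masked_reason`.
#' @export
filter_lcsh <- function(rows, min_size_mbp = 3) {
  if (min_size_mbp <= 0) stop_domain("min_size_mbp must be positive")
  loh <- rows[rows$seg_type == "LOH", , drop = FALSE]
  out <- data.frame(
    sample_id = loh$sample_id,
    chrom = loh$chrom,
    start = loh$start,
    end = loh$end,
    stringsAsFactors = FALSE
  )
  out$size_mbp <- if (nrow(out)) interval_length_mbp(out$start, out$end) else numeric()
  out$is_autosomal <- out$chrom %in% AUTOSOMES
  out$masked_reason <- ifelse(out$size_mbp >= min_size_mbp,
                              "none", "below-threshold")
  rownames(out) <- NULL
  out
}

#' Mask hemizygous LOH artifacts over deletions
#'
#' Array software reports absence of heterozygosity, which includes
#' hemizygosity over a deletion, not only true homozygosity. Any LCSH whose
#' overlap with the union of same-sample single-copy (copy number <= 1) loss
#' intervals reaches `min_overlap_fraction` of the LCSH length is masked with
#' reason `"hemizygous-overlap"`. The operation is idempotent and compares
#' segments only within a sample.
#'
#' @param lcsh LCSH table from [filter_lcsh()].
#' @param losses CNV calls (see [as_cnv_calls()]) restricted to losses; calls
#'   with copy number > 1 or of type gain are ignored.
#' @param min_overlap_fraction fraction of the LCSH length that must be
#'   covered by deletions to mask it (default 0.5).
#' @return the LCSH table with `masked_reason` updated.
#' @export
mask_hemizygous <- function(lcsh, losses, min_overlap_fraction = 0.5) {
  if (!("sample_id" %in% names(losses)))
    stop_domain("losses must carry sample_id; cross-sample masking is not defined")
  del <- losses[losses$type %in% "loss" & !is.na(losses$cn) & losses$cn <= 1, ,
                drop = FALSE]
  if (!nrow(del) || !nrow(lcsh)) return(lcsh)
  for (i in seq_len(nrow(lcsh))) {
    if (lcsh$masked_reason[i] == "hemizygous-overlap") next
    d <- del[del$sample_id == lcsh$sample_id[i] &
             del$chrom == lcsh$chrom[i], , drop = FALSE]
    if (!nrow(d)) next
    cov <- interval_union_overlap(lcsh$start[i], lcsh$end[i], d$start, d$end)
    len <- lcsh$end[i] - lcsh$start[i] + 1
    if (cov / len >= min_overlap_fraction)
      lcsh$masked_reason[i] <- "hemizygous-overlap"
  }
  lcsh
}

## bp of [start,end] covered by the union of intervals (starts, ends)
interval_union_overlap <- function(start, end, starts, ends) {
  s <- pmax(starts, start); e <- pmin(ends, end)
  keep <- s <= e
  if (!any(keep)) return(0)
  s <- s[keep]; e <- e[keep]
  ord <- order(s)
  s <- s[ord]; e <- e[ord]
  total <- 0; cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= cur_e + 1) cur_e <- max(cur_e, e[i])
    else { total <- total + (cur_e - cur_s + 1); cur_s <- s[i]; cur_e <- e[i] }
  }
  total + (cur_e - cur_s + 1)
}

#' Analyzable LCSH
#'
#' The subset of LCSH that enters every downstream analysis: unmasked and at
#' or above the size threshold.
#'
#' @param lcsh LCSH table from [filter_lcsh()] / [mask_hemizygous()].
#' @return subset of `lcsh` with `masked_reason == "none"`.
#' @export
analyzable_lcsh <- function(lcsh) {
  lcsh[lcsh$masked_reason == "none", , drop = FALSE]
}

#' Per-sample LCSH summary
#'
#' Counts, largest and summed sizes, and the sub-5 / >= 5 Mbp pattern flags,
#' computed from autosomal analyzable LCSH only.
#'
#' @param lcsh LCSH table (whole cohort).
#' @param sample_ids samples to report; defaults to those present in `lcsh`.
#' @return data.frame with one row per sample: `sample_id`, `n`,
#'   `largest_mbp`, `sum_mbp`, `has_only_sub5`, `has_ge5`.
#' @export
per_sample_lcsh_summary <- function(lcsh, sample_ids = NULL) {
  a <- analyzable_lcsh(lcsh)
  a <- a[a$is_autosomal, , drop = FALSE]
  sample_ids <- sample_ids %||% unique(lcsh$sample_id)
  if (!length(sample_ids))
    return(data.frame(sample_id = character(), n = integer(),
                      largest_mbp = numeric(), sum_mbp = numeric(),
                      has_only_sub5 = logical(), has_ge5 = logical(),
                      stringsAsFactors = FALSE))
  res <- lapply(sample_ids, function(id) {
    s <- a$size_mbp[a$sample_id == id]
    data.frame(sample_id = id, n = length(s),
               largest_mbp = if (length(s)) max(s) else 0,
               sum_mbp = sum(s),
               has_only_sub5 = length(s) > 0 && all(s < 5),
               has_ge5 = any(s >= 5), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
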