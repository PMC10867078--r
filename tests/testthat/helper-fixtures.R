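# Shared builders for in-code fixtures.

hg19 <- genome_build()

## a parsed segment row (the shape read_segment_table() returns)
seg_row <- function(sample, type, chrom, start, end,
                    markers = 100L, cn = NA_real_,
                    classification = "unclassified") {
  data.frame(sample_id = sample, seg_type = type, chrom = as.character(chrom),
             start = start, end = end, markers = as.integer(markers),
             cn = cn, classification = classification,
             stringsAsFactors = FALSE)
}

## an LOH row spanning `size_mbp` starting at `start`
loh_row <- function(sample, chrom, size_mbp, start = 1e6) {
  seg_row(sample, "LOH", chrom, start, start + round(size_mbp * 1e6) - 1)
}

segs <- function(...) do.call(rbind, list(...))

## write a parsed-shape data.frame as an export-dialect TSV and return path
write_export <- function(rows, path = tempfile(fileext = ".tsv")) {
  dial <- chas_dialect()$columns
  x <- rows
  names(x) <- unname(dial[names(rows)])
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

## exhaustive two-sided Fisher oracle: sum of hypergeometric table
## probabilities not exceeding the observed one
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

## the bundled worked examples as one-sample parsed tables
worked_example_rows <- function() {
  ex <- upd_worked_examples()
  lapply(split(ex, ex$case), function(e)
    seg_row(paste0("case", e$case[1]), "LOH", e$chrom, e$start, e$end))
}
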