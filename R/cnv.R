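# CNV filtering, per-sample most-relevant class, diagnostic yield.

CNV_CLASSES <- c("PCNV", "LPCNV", "VUS", "benign", "none")

#' Convert parsed segment rows to CNV calls
#'
#' Gain/Loss rows become CNV calls with sizes in Kbp. Classification labels
#' (benign/VUS/LPCNV/PCNV) are input annotations, never computed here.
#'
#' @param rows parsed segment table ([read_segment_table()]).
#' @return data.frame with `sample_id`, `chrom`, `start`, `end`, `type`
#'   (`gain`/`loss`), `cn`, `markers`, `size_kbp`, `classification`.
#' @export
as_cnv_calls <- function(rows) {
  x <- rows[rows$seg_type %in% c("Gain", "Loss"), , drop = FALSE]
  out <- data.frame(
    sample_id = x$sample_id, chrom = x$chrom, start = x$start, end = x$end,
    type = ifelse(x$seg_type == "Gain", "gain", "loss"),
    cn = x$cn, markers = x$markers,
    size_kbp = if (nrow(x)) (x$end - x$start + 1) / 1e3 else numeric(),
    classification = x$classification %||% rep("unclassified", nrow(x)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Filter CNV calls by size and marker support
#'
#' Research mode keeps calls larger than 10 Kbp (strictly) supported by at
#' least ten markers, for deletions and duplications alike. Clinical mode
#' applies the conventional diagnostic thresholds: losses larger than
#' 100 Kbp, gains larger than 150 Kbp, both with at least 50 markers.
#' Research-mode survivors are therefore a superset of clinical-mode
#' survivors. Calls with unknown marker counts are rejected with a
#' diagnostic (attribute `"rejected"`).
#'
#' @param calls CNV call table ([as_cnv_calls()]).
#' @param mode `"research"` or `"clinical"`.
#' @return the surviving calls; rejected-for-missing-markers rows in
#'   `attr(, "rejected")`.
#' @export
filter_cnvs <- function(calls, mode = c("research", "clinical")) {
  mode <- match.arg(mode)
  no_markers <- is.na(calls$markers)
  rejected <- calls[no_markers, , drop = FALSE]
  x <- calls[!no_markers, , drop = FALSE]
  keep <- if (mode == "research") {
    x$size_kbp > 10 & x$markers >= 10
  } else {
    ifelse(x$type == "loss", x$size_kbp > 100, x$size_kbp > 150) &
      x$markers >= 50
  }
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Most clinically relevant CNV class of a sample
#'
#' Precedence PCNV > LPCNV > VUS > benign > none; invariant to call order
#' and duplication.
#'
#' @param classifications character vector of per-call classes for one
#'   sample (unrecognized labels are ignored).
#' @return a single class label.
#' @export
most_relevant_class <- function(classifications) {
  hits <- CNV_CLASSES[CNV_CLASSES %in% classifications]
  if (length(hits)) hits[1] else "none"
}

#' Per-sample most-relevant class over a cohort
#'
#' @param calls CNV call table.
#' @param sample_ids full sample list (samples without calls get `"none"`).
#' @return data.frame `sample_id`, `class`.
#' @export
sample_classes <- function(calls, sample_ids = NULL) {
  sample_ids <- sample_ids %||% unique(calls$sample_id)
  cls <- vapply(sample_ids, function(id)
    most_relevant_class(calls$classification[calls$sample_id == id]), "")
  data.frame(sample_id = sample_ids, class = unname(cls),
             stringsAsFactors = FALSE)
}

#' Diagnostic yield of a cohort
#'
#' Fraction of samples whose most relevant finding is a pathogenic CNV, and
#' fraction whose best finding is inconclusive (VUS or LPCNV).
#'
#' @param classes output of [sample_classes()].
#' @return list with `n`, `counts` (per class), `pathogenic_fraction`,
#'   `inconclusive_fraction`.
#' @export
diagnostic_yield <- function(classes) {
  n <- nrow(classes)
  counts <- vapply(CNV_CLASSES, function(cl) sum(classes$class == cl), 1L)
  list(n = n, counts = counts,
       pathogenic_fraction = if (n) counts[["PCNV"]] / n else 0,
       inconclusive_fraction =
         if (n) (counts[["VUS"]] + counts[["LPCNV"]]) / n else 0)
}

#' Per-class summaries of CNV metrics
#'
#' Mean, SD and range of size (and optional gene-count annotations) by
#' classification; missing metric values are excluded pairwise with the
#' retained count reported. A single call yields SD `NA`.
#'
#' @param calls CNV call table; metric columns must be numeric.
#' @param metrics columns to summarize (default `size_kbp` plus
#'   `gene_count`/`omim_gene_count` when present).
#' @return data.frame with one row per class x metric.
#' @export
class_metric_summary <- function(calls,
                                 metrics = intersect(
                                   c("size_kbp", "gene_count",
                                     "omim_gene_count"), names(calls))) {
  out <- list()
  for (cl in intersect(CNV_CLASSES, unique(calls$classification))) {
    x <- calls[calls$classification == cl, , drop = FALSE]
    for (m in metrics) {
      v <- x[[m]]
      v <- v[!is.na(v)]
      out[[length(out) + 1]] <- data.frame(
        classification = cl, metric = m, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) stats::sd(v) else NA_real_,
        min = if (length(v)) min(v) else NA_real_,
        max = if (length(v)) max(v) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out) %||%
    data.frame(classification = character(), metric = character(),
               n = integer(), mean = numeric(), sd = numeric(),
               min = numeric(), max = numeric())
}
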