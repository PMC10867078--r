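# Phenotype-pathogenicity association and multi-class mean comparisons.

#' Fisher's exact test for a 2x2 table, with the sample odds ratio
#'
#' Two-sided p from the exact hypergeometric null (the sum of table
#' probabilities not exceeding the observed table's). The reported odds
#' ratio is the sample OR `(a*d)/(b*c)` - not the conditional-MLE estimate
#' some tools print - with 0.5 added to every cell when any cell is zero
#' (Haldane-Anscombe), flagged in the output.
#'
#' @param a,b,c,d non-negative integer cell counts; rows are the comparison
#'   groups, columns outcome-positive/negative.
#' @return list with `p_value`, `odds_ratio`, `haldane` (logical).
#' @examples
#' fisher_exact_2x2(5, 5, 5, 5) # p = 1, OR = 1
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop_domain("cell counts must be non-negative integers")
  if (all(cells == 0)) stop_domain("all-zero table: odds ratio undefined")
  p <- stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
  haldane <- any(cells == 0)
  if (haldane) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  list(p_value = min(p, 1), odds_ratio = or, haldane = haldane)
}

#' Phenotype-pathogenicity association table
#'
#' One Fisher test per phenotype term, comparing the "negative" group
#' (samples with no CNVs or only benign CNVs) against the "pathogenic"
#' group (samples whose most relevant finding is a PCNV). Samples whose best
#' finding is a VUS or LPCNV are inconclusive and excluded. Both odds-ratio
#' orientations are emitted with explicit labels:
#' `or_negative_vs_pathogenic` is the odds of the phenotype among negatives
#' over its odds among pathogenic carriers (the orientation in which
#' phenotypes enriched with pathogenic CNVs show OR < 1), and
#' `or_pathogenic_vs_negative` its reciprocal. Raw p-values are flagged
#' significant at `alpha` without multiplicity correction (the univariate
#' screening convention); a Benjamini-Hochberg column is emitted alongside.
#'
#' @param classes per-sample classes ([sample_classes()]).
#' @param phenotypes phenotype table ([read_phenotype_table()]).
#' @param alpha significance level for the raw-p flag (default 0.05).
#' @return data.frame: `term`, `a`, `b`, `c`, `d` (a/b = term
#'   present/absent in the negative group, c/d in the pathogenic group),
#'   `p_value`, `or_negative_vs_pathogenic`, `or_pathogenic_vs_negative`,
#'   `haldane`, `significant`, `p_bh`; skipped zero-total terms in
#'   `attr(, "skipped")`.
#' @export
phenotype_association_table <- function(classes, phenotypes, alpha = 0.05) {
  merged <- merge(classes, as_phenotypes(phenotypes), by = "sample_id")
  neg <- merged[merged$class %in% c("none", "benign"), , drop = FALSE]
  pat <- merged[merged$class == "PCNV", , drop = FALSE]
  terms <- sort(unique(unlist(merged$phenotype_terms)))
  has <- function(grp, term)
    vapply(grp$phenotype_terms, function(t) term %in% t, TRUE)
  rows <- list(); skipped <- character()
  for (term in terms) {
    a <- sum(has(neg, term)); b <- nrow(neg) - a
    c <- sum(has(pat, term)); d <- nrow(pat) - c
    if (a + c == 0) { skipped <- c(skipped, term); next }
    ft <- fisher_exact_2x2(a, b, c, d)
    rows[[length(rows) + 1]] <- data.frame(
      term = term, a = a, b = b, c = c, d = d,
      p_value = ft$p_value,
      or_negative_vs_pathogenic = ft$odds_ratio,
      or_pathogenic_vs_negative = 1 / ft$odds_ratio,
      haldane = ft$haldane, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows) %||%
    data.frame(term = character(), a = integer(), b = integer(),
               c = integer(), d = integer(), p_value = numeric(),
               or_negative_vs_pathogenic = numeric(),
               or_pathogenic_vs_negative = numeric(), haldane = logical())
  out$significant <- out$p_value <= alpha
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  attr(out, "skipped") <- skipped
  out
}

#' Pairwise class mean comparisons (one-way ANOVA + Tukey HSD)
#'
#' Compares a metric (CNV size, gene count, ...) across classification
#' groups with one-way ANOVA followed by Tukey's honestly-significant-
#' difference adjusted pairwise comparisons. Groups with fewer than two
#' values are excluded and listed in `attr(, "excluded")`.
#'
#' @param values numeric vector.
#' @param classes group labels, same length as `values`.
#' @return data.frame `comparison`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
class_mean_comparison <- function(values, classes) {
  keep <- !is.na(values) & !is.na(classes)
  values <- values[keep]; classes <- as.character(classes[keep])
  sizes <- table(classes)
  excluded <- names(sizes)[sizes < 2]
  ok <- !(classes %in% excluded)
  values <- values[ok]; classes <- factor(classes[ok])
  if (nlevels(classes) < 2)
    stop_domain("need at least two classes with two or more values")
  fit <- stats::aov(values ~ classes)
  tk <- stats::TukeyHSD(fit)$classes
  out <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
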