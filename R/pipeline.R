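# One front-door orchestrating parse -> mask -> LCSH -> consanguinity ->
# UPD -> common regions -> CNV yield -> association.

#' Analyze a cohort of segment exports
#'
#' Runs the full post-array analysis on a parsed segment table: LCSH
#' selection at the clinical size threshold, hemizygosity masking against
#' single-copy losses (masking always precedes every LCSH consumer),
#' per-sample inbreeding coefficients and kinship classes, rule-based UPD
#' candidates, cohort common-LCSH regions, CNV filtering with per-sample
#' most-relevant class and diagnostic yield, and (when phenotypes are
#' supplied) the phenotype-pathogenicity association table.
#'
#' @param segments parsed segment table from [read_segment_table()], or a
#'   path to a segment TSV.
#' @param phenotypes optional phenotype table from [read_phenotype_table()]
#'   or a path to a CSV.
#' @param build a [genome_build()].
#' @param sample_ids the analyzable sample set (denominator for all cohort
#'   fractions); defaults to the samples present in `segments`.
#' @param min_lcsh_mbp LCSH analysis threshold, Mbp (default 3).
#' @param hemizygous_overlap_fraction deletion-overlap fraction that masks
#'   an LCSH (default 0.5).
#' @param upd_min_total_mbp,upd_ge_threshold_mbp UPD rule thresholds
#'   (defaults 10 and 5 Mbp).
#' @param common_min_frequency recurrence threshold for common regions
#'   (default 0.05).
#' @param cnv_mode `"research"` (>10 Kbp, >=10 markers) or `"clinical"`
#'   (loss >100 / gain >150 Kbp, >=50 markers).
#' @param genome_mbp autosomal genome constant (2881 Mbp).
#' @param alpha significance level for association flags.
#' @return object of class `lcsh_analysis` with elements `lcsh`,
#'   `lcsh_summary`, `consanguinity` (`reports` + `profile`), `upd`
#'   (`candidates` + `rate`), `common_regions`, `cnv` (`calls`, `classes`,
#'   `yield`), `association`, `counts`, `params`.
#' @examples
#' sim <- simulate_cohort(sim_config(n_samples = 20, seed = 7))
#' fit <- lcsh_analysis(parse_segment_frame(sim$segments),
#'                      phenotypes = sim$phenotypes)
#' print(fit)
#' @export
lcsh_analysis <- function(segments, phenotypes = NULL,
                          build = genome_build(), sample_ids = NULL,
                          min_lcsh_mbp = 3,
                          hemizygous_overlap_fraction = 0.5,
                          upd_min_total_mbp = 10, upd_ge_threshold_mbp = 5,
                          common_min_frequency = 0.05,
                          cnv_mode = "research", genome_mbp = 2881,
                          alpha = 0.05) {
  if (is.character(segments))
    segments <- read_segment_table(segments, build)
  if (is.character(phenotypes))
    phenotypes <- read_phenotype_table(phenotypes)
  sample_ids <- sample_ids %||% unique(segments$sample_id)
  n <- length(sample_ids)

  cnv_all <- as_cnv_calls(segments)
  cnv <- filter_cnvs(cnv_all, cnv_mode)
  lcsh <- filter_lcsh(segments, min_lcsh_mbp)
  lcsh <- mask_hemizygous(lcsh, cnv_all, hemizygous_overlap_fraction)
  upd <- call_upd_candidates(lcsh, upd_min_total_mbp, upd_ge_threshold_mbp)
  reports <- consanguinity_report(lcsh, sample_ids, upd, genome_mbp)
  common <- if (n > 0)
    delineate_common_regions(lcsh, build, n, common_min_frequency)
  else NULL
  classes <- sample_classes(cnv, sample_ids)
  assoc <- if (!is.null(phenotypes))
    phenotype_association_table(classes, phenotypes, alpha)
  else NULL

  a <- analyzable_lcsh(lcsh)
  counts <- c(samples = n,
              segment_rows = nrow(segments),
              loh_rows = sum(segments$seg_type == "LOH"),
              below_threshold = sum(lcsh$masked_reason == "below-threshold"),
              hemizygous_masked = sum(lcsh$masked_reason == "hemizygous-overlap"),
              analyzable_lcsh = nrow(a),
              cnv_calls = nrow(cnv_all),
              cnv_pass_filter = nrow(cnv))

  structure(list(
    build = build, sample_ids = sample_ids,
    lcsh = lcsh,
    lcsh_summary = per_sample_lcsh_summary(lcsh, sample_ids),
    consanguinity = list(reports = reports,
                         profile = cohort_consanguinity_profile(reports)),
    upd = list(candidates = upd, rate = cohort_upd_rate(upd, n)),
    common_regions = common,
    cnv = list(calls = cnv, classes = classes,
               yield = diagnostic_yield(classes)),
    association = assoc,
    counts = counts,
    params = list(min_lcsh_mbp = min_lcsh_mbp,
                  hemizygous_overlap_fraction = hemizygous_overlap_fraction,
                  upd_min_total_mbp = upd_min_total_mbp,
                  upd_ge_threshold_mbp = upd_ge_threshold_mbp,
                  common_min_frequency = common_min_frequency,
                  cnv_mode = cnv_mode, genome_mbp = genome_mbp,
                  alpha = alpha)
  ), class = "lcsh_analysis")
}

#' Parse an in-memory export-dialect data.frame
#'
#' Same validation as [read_segment_table()] for a data.frame already in
#' memory (e.g. straight from [simulate_cohort()]).
#'
#' @param x data.frame with export-dialect headers.
#' @param build a [genome_build()].
#' @param dialect dialect from [chas_dialect()].
#' @return parsed segment table.
#' @export
parse_segment_frame <- function(x, build = genome_build(),
                                dialect = chas_dialect()) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(x, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  read_segment_table(tmp, build, dialect)
}

#' @export
print.lcsh_analysis <- function(x, ...) {
  cat("LCSH cohort analysis (", x$build$name, ")\n", sep = "")
  cat(sprintf("  samples: %d   analyzable LCSH: %d   (%.0f%% of samples with >=1)\n",
              x$counts[["samples"]], x$counts[["analyzable_lcsh"]],
              100 * mean(x$lcsh_summary$n > 0)))
  cat(sprintf("  inbreeding suggested: %.1f%%   first-to-fifth degree: %.1f%%\n",
              100 * x$consanguinity$profile$inbred_fraction,
              100 * x$consanguinity$profile$first_to_fifth_fraction))
  cat(sprintf("  potential UPD: %d sample(s), %.1f%%\n",
              nrow(x$upd$candidates), 100 * x$upd$rate))
  cat(sprintf("  pathogenic-CNV yield: %.1f%%   inconclusive (VUS/LPCNV): %.1f%%\n",
              100 * x$cnv$yield$pathogenic_fraction,
              100 * x$cnv$yield$inconclusive_fraction))
  if (!is.null(x$common_regions))
    cat(sprintf("  common LCSH regions (>= %.0f%%): %d\n",
                100 * x$params$common_min_frequency, nrow(x$common_regions)))
  invisible(x)
}

#' @export
summary.lcsh_analysis <- function(object, ...) {
  s <- object$lcsh_summary
  structure(list(
    n = object$counts[["samples"]],
    counts = object$counts,
    lcsh_pattern = c(
      any_lcsh = mean(s$n > 0),
      only_sub5 = mean(s$has_only_sub5),
      ge5 = mean(s$has_ge5)),
    consanguinity = object$consanguinity$profile,
    upd_rate = object$upd$rate,
    yield = object$cnv$yield,
    common_regions = object$common_regions,
    association = object$association
  ), class = "summary.lcsh_analysis")
}

#' @export
print.summary.lcsh_analysis <- function(x, ...) {
  cat("Cohort of", x$n, "samples\n")
  cat(sprintf("  LCSH >= threshold in %.0f%% of samples; %.0f%% only sub-5 Mbp, %.0f%% with >= 5 Mbp\n",
              100 * x$lcsh_pattern[["any_lcsh"]],
              100 * x$lcsh_pattern[["only_sub5"]],
              100 * x$lcsh_pattern[["ge5"]]))
  cat("  Stage counts:\n")
  for (nm in names(x$counts))
    cat(sprintf("    %-18s %d\n", nm, x$counts[[nm]]))
  cat("  Kinship classes:\n")
  bc <- x$consanguinity$by_class
  for (i in seq_len(nrow(bc)))
    cat(sprintf("    %-16s %4d  (%.1f%%)\n", bc$class[i], bc$count[i],
                100 * bc$fraction[i]))
  cat(sprintf("  UPD rate: %.1f%%   pathogenic yield: %.1f%%\n",
              100 * x$upd_rate, 100 * x$yield$pathogenic_fraction))
  if (!is.null(x$common_regions) && nrow(x$common_regions)) {
    cat("  Common regions:\n")
    print(x$common_regions)
  }
  if (!is.null(x$association)) {
    cat("  Association (top rows):\n")
    print(utils::head(x$association[order(x$association$p_value),
                                    c("term", "p_value",
                                      "or_negative_vs_pathogenic",
                                      "significant")], 5))
  }
  invisible(x)
}

#' Plot per-chromosome LCSH burden
#'
#' Barplot of the fraction of samples carrying at least one analyzable LCSH
#' per autosome.
#'
#' @param x an `lcsh_analysis` object.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.lcsh_analysis <- function(x, ...) {
  a <- analyzable_lcsh(x$lcsh)
  a <- a[a$is_autosomal, , drop = FALSE]
  frac <- vapply(AUTOSOMES, function(ch)
    length(unique(a$sample_id[a$chrom == ch])) /
      max(1, x$counts[["samples"]]), 1)
  graphics::barplot(frac, names.arg = AUTOSOMES, las = 2,
                    xlab = "chromosome",
                    ylab = "fraction of samples with LCSH", ...)
  invisible(x)
}

#' Run the pipeline on files and write a report bundle
#'
#' Thin orchestration over [lcsh_analysis()]: reads the inputs, writes TSV
#' reports plus a machine-readable `summary.json`, and returns a run
#' manifest with input/output digests. Rerunning on identical inputs and
#' config reproduces identical digests.
#'
#' @param segments_path segment export TSV.
#' @param phenotypes_path optional phenotype CSV.
#' @param out_dir output directory (created).
#' @param build a [genome_build()].
#' @param ... further parameters passed to [lcsh_analysis()].
#' @return the manifest (list), invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(segments_path, phenotypes_path = NULL, out_dir,
                         build = genome_build(), ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- lcsh_analysis(segments_path, phenotypes_path, build = build, ...)

  out <- list()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    out[[name]] <<- p
  }
  rep <- fit$consanguinity$reports
  rep$f_hat <- NULL   # report the 3-decimal value
  wr(rep, "consanguinity.tsv")
  upd <- fit$upd$candidates
  if (nrow(upd))
    upd$segments <- vapply(upd$segments, function(s)
      paste(sprintf("%s:%d-%d", s$chrom, as.integer(s$start),
                    as.integer(s$end)), collapse = ";"), "")
  else upd$segments <- character()
  wr(upd, "upd_candidates.tsv")
  if (!is.null(fit$common_regions)) {
    cr <- fit$common_regions
    cr$size_mbp <- round(cr$size_mbp, 3)
    wr(cr, "common_regions.tsv")
  }
  wr(fit$cnv$classes, "sample_classes.tsv")
  if (!is.null(fit$association)) wr(fit$association, "association.tsv")
  bed <- file.path(out_dir, "analyzable_lcsh.bed")
  write_bed(analyzable_lcsh(fit$lcsh), bed, "analyzable_lcsh")
  out[["analyzable_lcsh.bed"]] <- bed

  summ <- summary(fit)
  sj <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(
    schema = "lcshkit-summary/1",
    n = summ$n, counts = as.list(summ$counts),
    lcsh_pattern = as.list(summ$lcsh_pattern),
    inbred_fraction = summ$consanguinity$inbred_fraction,
    first_to_fifth_fraction = summ$consanguinity$first_to_fifth_fraction,
    upd_rate = summ$upd_rate,
    pathogenic_fraction = summ$yield$pathogenic_fraction,
    inconclusive_fraction = summ$yield$inconclusive_fraction
  ), sj, auto_unbox = TRUE, digits = NA)
  out[["summary.json"]] <- sj

  manifest <- list(
    tool = paste0("lcshkit ", as.character(utils::packageVersion("lcshkit"))),
    params = fit$params,
    inputs = as.list(tools::md5sum(c(segments_path, phenotypes_path))),
    counts = as.list(fit$counts),
    outputs = as.list(tools::md5sum(unlist(out)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
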