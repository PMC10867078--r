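# Reading and writing segment exports, phenotype tables and BED.

#' Default segment-export dialect
#'
#' Column-name mapping for tab-separated segment export tables as produced by
#' array analysis suites. The export column set is laboratory-configurable, so
#' the mapping is explicit and overridable: `columns` maps internal field
#' names to the column headers expected in the file. `sample_id`, `seg_type`,
#' `chrom`, `start` and `end` are mandatory; `markers`, `cn` and
#' `classification` are optional annotations.
#'
#' @param columns named character vector mapping fields to file headers.
#' @return list with the dialect configuration.
#' @export
chas_dialect <- function(columns = c(sample_id = "Sample",
                                     seg_type = "Type",
                                     chrom = "Chromosome",
                                     start = "Start",
                                     end = "End",
                                     markers = "Marker Count",
                                     cn = "CN State",
                                     classification = "Classification")) {
  list(columns = columns)
}

.mandatory_fields <- c("sample_id", "seg_type", "chrom", "start", "end")

#' Read a segment export table
#'
#' Parses a tab-separated export of called segments (one row per Gain, Loss
#' or LOH segment). Rows failing validation (unknown chromosome, start > end,
#' coordinates beyond the chromosome, unrecognized segment type) are rejected
#' with row-numbered diagnostics available via `attr(x, "rejected")` and a
#' warning; a missing mandatory column is an error naming the column.
#'
#' LOH rows of any size are retained at parse time; size thresholds are
#' applied downstream (see [filter_lcsh()]) so one parsed table serves all
#' stages. Copy-number values on LOH rows are dropped (absence of
#' heterozygosity carries no copy-number state).
#'
#' @param path path to the TSV file.
#' @param build a [genome_build()] used for coordinate validation.
#' @param dialect dialect from [chas_dialect()].
#' @return data.frame with columns `sample_id`, `seg_type` (`Gain`, `Loss`,
#'   `LOH`), `chrom`, `start`, `end`, `markers`, `cn`, `classification`.
#' @export
read_segment_table <- function(path, build = genome_build(),
                               dialect = chas_dialect()) {
  if (!file.exists(path)) stop_domain("segment file not found: ", path)
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  cols <- dialect$columns
  missing <- setdiff(.mandatory_fields, names(cols)[cols %in% names(raw)])
  if (length(missing))
    stop_domain("segment table is missing mandatory column(s): ",
                paste(cols[missing], collapse = ", "))
  get <- function(field) {
    if (field %in% names(cols) && cols[[field]] %in% names(raw))
      raw[[cols[[field]]]] else rep(NA, nrow(raw))
  }
  out <- data.frame(
    sample_id = as.character(get("sample_id")),
    seg_type = as.character(get("seg_type")),
    chrom = normalize_chrom(get("chrom")),
    start = as.numeric(get("start")),
    end = as.numeric(get("end")),
    markers = suppressWarnings(as.integer(get("markers"))),
    cn = suppressWarnings(as.numeric(get("cn"))),
    classification = as.character(get("classification")),
    stringsAsFactors = FALSE
  )
  type_map <- c(gain = "Gain", loss = "Loss", loh = "LOH")
  out$seg_type <- unname(type_map[tolower(out$seg_type)])

  reason <- check_intervals(out$chrom, out$start, out$end, build, error = FALSE)
  reason[is.na(out$seg_type) & reason == ""] <- "unrecognized segment type"
  rejected <- data.frame(row = which(reason != ""),
                         reason = reason[reason != ""])
  if (nrow(rejected))
    warning(sprintf("%d segment row(s) rejected (first: row %d, %s)",
                    nrow(rejected), rejected$row[1], rejected$reason[1]),
            call. = FALSE)
  out <- out[reason == "", , drop = FALSE]
  out$cn[out$seg_type == "LOH"] <- NA_real_
  out$classification[is.na(out$classification)] <- "unclassified"
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Read a phenotype table
#'
#' CSV with one row per sample. A `sample_id` column (or `Sample`) is
#' required; optional `sex` and `age_years` columns are carried through.
#' Phenotype terms may be given either as a `phenotypes` column of
#' `;`-separated tokens, or as additional indicator columns (values
#' 0/1/TRUE/FALSE/yes/no), whose lower-cased names become terms. Terms are
#' normalized to lower-case trimmed tokens.
#'
#' @param path path to the CSV file.
#' @return data.frame with columns `sample_id`, `sex`, `age_years` and a
#'   list-column `phenotype_terms`.
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) stop_domain("phenotype file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  as_phenotypes(raw)
}

#' Coerce a raw phenotype data.frame to the parsed representation
#'
#' Applies the same conventions as [read_phenotype_table()] to an in-memory
#' data.frame (e.g. the one returned by [simulate_cohort()]). A frame that
#' already carries a `phenotype_terms` list-column is returned unchanged.
#'
#' @param raw data.frame with a sample id column and indicator and/or
#'   `phenotypes` columns.
#' @return data.frame with `sample_id`, `sex`, `age_years`,
#'   `phenotype_terms`.
#' @export
as_phenotypes <- function(raw) {
  if ("phenotype_terms" %in% names(raw)) return(raw)
  idcol <- intersect(c("sample_id", "Sample", "sample"), names(raw))[1]
  if (is.na(idcol)) stop_domain("phenotype table needs a sample_id column")
  ids <- as.character(raw[[idcol]])
  if (anyDuplicated(ids))
    stop_domain("duplicate sample_id in phenotype table: ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  norm_term <- function(x) tolower(trimws(x))
  special <- c(idcol, "sex", "age_years", "phenotypes")
  terms <- rep(list(character(0)), length(ids))
  if ("phenotypes" %in% names(raw)) {
    terms <- lapply(strsplit(as.character(raw$phenotypes), "[;|]"), function(x) {
      x <- norm_term(x)
      x[nzchar(x) & !is.na(x)]
    })
  }
  for (col in setdiff(names(raw), special)) {
    v <- raw[[col]]
    flag <- if (is.logical(v)) v else
      tolower(as.character(v)) %in% c("1", "true", "yes", "y")
    for (i in which(flag)) terms[[i]] <- c(terms[[i]], norm_term(col))
  }
  data.frame(
    sample_id = ids,
    sex = if ("sex" %in% names(raw)) tolower(raw$sex) else "unknown",
    age_years = if ("age_years" %in% names(raw))
      suppressWarnings(as.numeric(raw$age_years)) else NA_real_,
    phenotype_terms = I(lapply(terms, unique)),
    stringsAsFactors = FALSE
  )
}

#' Match segment and phenotype tables into a cohort
#'
#' Samples present in only one of the two tables are reported (not fatal) in
#' the `orphans` element.
#'
#' @param segments parsed segment table ([read_segment_table()]).
#' @param phenotypes parsed phenotype table ([read_phenotype_table()]) or NULL.
#' @return list with `segments`, `phenotypes`, `sample_ids` and `orphans`
#'   (list with `segments_only` and `phenotypes_only`).
#' @export
match_cohort <- function(segments, phenotypes = NULL) {
  seg_ids <- unique(segments$sample_id)
  phe_ids <- if (is.null(phenotypes)) character() else phenotypes$sample_id
  list(
    segments = segments,
    phenotypes = phenotypes,
    sample_ids = union(seg_ids, phe_ids),
    orphans = list(segments_only = setdiff(seg_ids, phe_ids),
                   phenotypes_only = setdiff(phe_ids, seg_ids))
  )
}

#' Write segments as BED6
#'
#' Converts the internal 1-based inclusive coordinates to BED's 0-based
#' half-open convention; rows are sorted by chromosome then start. Re-reading
#' the file reproduces the intervals exactly.
#'
#' @param segments data.frame with `sample_id`, `chrom`, `start`, `end` and
#'   optionally `seg_type`.
#' @param path output path.
#' @param track_name name written in the BED track header.
#' @return invisibly, the path.
#' @export
write_bed <- function(segments, path, track_name = "segments") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track name="%s"', track_name), con)
  if (nrow(segments)) {
    ord <- order(match(segments$chrom, c(AUTOSOMES, "X", "Y")), segments$start)
    s <- segments[ord, ]
    name <- paste(s$sample_id,
                  if ("seg_type" %in% names(s)) s$seg_type else "segment",
                  sep = ":")
    writeLines(sprintf("chr%s\t%d\t%d\t%s\t0\t.", s$chrom,
                       as.integer(s$start) - 1L, as.integer(s$end), name), con)
  }
  invisible(path)
}

#' Read a BED6 file back into 1-based inclusive segments
#'
#' Inverse of [write_bed()] (used mainly for round-trip checks).
#'
#' @param path BED file path.
#' @return data.frame with `sample_id`, `seg_type`, `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^track", lines)]
  if (!length(lines))
    return(data.frame(sample_id = character(), seg_type = character(),
                      chrom = character(), start = numeric(), end = numeric()))
  x <- utils::read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  name <- strsplit(x$V4, ":", fixed = TRUE)
  data.frame(
    sample_id = vapply(name, `[`, "", 1),
    seg_type = vapply(name, function(p) p[2] %||% NA_character_, ""),
    chrom = normalize_chrom(x$V1),
    start = x$V2 + 1, end = x$V3,
    stringsAsFactors = FALSE
  )
}
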