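# Coordinate system, genome build and interval arithmetic.
#
# All coordinates are 1-based inclusive internally (the convention of array
# segment exports); BED output converts to 0-based half-open on write.

## GRCh37/hg19 sequence lengths (bp), autosomes 1..22 plus X and Y.
.hg19_lengths <- c(
  `1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
  `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
  `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
  `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
  `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
  `21` = 48129895, `22` = 51304566, X = 155270560, Y = 59373566
)

## Approximate hg19 centromere midpoints (bp), used only to split arms when
## generating the synthetic band tiling below.
.hg19_centromeres <- c(
  `1` = 125000000, `2` = 93300000, `3` = 91000000, `4` = 50400000,
  `5` = 48400000, `6` = 61000000, `7` = 59900000, `8` = 45600000,
  `9` = 49000000, `10` = 40200000, `11` = 53700000, `12` = 35800000,
  `13` = 17900000, `14` = 17600000, `15` = 19000000, `16` = 36600000,
  `17` = 24000000, `18` = 17200000, `19` = 26500000, `20` = 27500000,
  `21` = 13200000, `22` = 14700000, X = 60600000, Y = 12500000
)

AUTOSOMES <- as.character(1:22)

#' Normalize chromosome names
#'
#' Accepts `"chr1"`/`"1"`/`"chrX"`/`"x"` and returns the bare name used
#' internally (`"1"`..`"22"`, `"X"`, `"Y"`).
#'
#' @param chrom character vector of chromosome names.
#' @return character vector without `"chr"` prefix, sex chromosomes upper-case.
#' @export
normalize_chrom <- function(chrom) {
  out <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  toupper(out) -> up
  out[up %in% c("X", "Y")] <- up[up %in% c("X", "Y")]
  out
}

#' Synthetic approximate cytogenetic band tiling
#'
#' Generates a gap-free, non-overlapping band table for a set of chromosomes
#' by splitting each arm (defined by an approximate centromere position) into
#' bands of roughly `band_width_mbp`. Band names follow the cytogenetic
#' numbering direction (p11/q11 nearest the centromere, numbers increasing
#' towards the telomeres) but are *synthetic*: they are not the ISCN bands of
#' any real assembly. Use [read_cytoband()] to load a real UCSC cytoBand file
#' when one is available.
#'
#' @param lengths named vector of chromosome lengths (bp).
#' @param centromeres named vector of centromere positions (bp).
#' @param band_width_mbp target band width in Mbp (default 10).
#' @return data.frame with columns `chrom`, `band`, `start`, `end`, `stain`
#'   (1-based inclusive coordinates).
#' @export
synthetic_cytobands <- function(lengths = .hg19_lengths,
                                centromeres = .hg19_centromeres,
                                band_width_mbp = 10) {
  w <- band_width_mbp * 1e6
  out <- lapply(names(lengths), function(ch) {
    len <- lengths[[ch]]
    cen <- min(centromeres[[ch]], len - 1)
    n_p <- max(1L, round(cen / w))
    n_q <- max(1L, round((len - cen) / w))
    p_bounds <- round(seq(0, cen, length.out = n_p + 1))
    q_bounds <- round(seq(cen, len, length.out = n_q + 1))
    ## p bands numbered outward from the centromere: last p interval is p11
    p <- data.frame(
      chrom = ch,
      band  = paste0("p", 10 + rev(seq_len(n_p))),
      start = p_bounds[-length(p_bounds)] + 1,
      end   = p_bounds[-1]
    )
    q <- data.frame(
      chrom = ch,
      band  = paste0("q", 10 + seq_len(n_q)),
      start = q_bounds[-length(q_bounds)] + 1,
      end   = q_bounds[-1]
    )
    rbind(p, q)
  })
  out <- do.call(rbind, out)
  out$stain <- "gneg"
  rownames(out) <- NULL
  out
}

#' Read a UCSC-format cytoband table
#'
#' Expects the UCSC `cytoBand.txt` layout: tab-separated
#' `chrom, start (0-based), end, band, stain`, no header. Coordinates are
#' converted to the package's 1-based inclusive convention and chromosome
#' names are normalized.
#'
#' @param path path to the file.
#' @return data.frame with columns `chrom`, `band`, `start`, `end`, `stain`.
#' @export
read_cytoband <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "band", "stain"),
                         stringsAsFactors = FALSE)
  data.frame(chrom = normalize_chrom(x$chrom), band = x$band,
             start = x$start + 1, end = x$end, stain = x$stain,
             stringsAsFactors = FALSE)
}

#' Construct a genome build
#'
#' Bundles the chromosome lengths, the constant 2881 Mbp autosomal-genome
#' denominator used for inbreeding-coefficient estimation, and a cytoband
#' table. The default build is GRCh37/hg19 with a synthetic approximate band
#' tiling (see [synthetic_cytobands()]); pass `cytobands` to substitute a real
#' band table.
#'
#' @param name build identifier.
#' @param chromosomes named vector of chromosome lengths in bp.
#' @param autosomal_mbp autosomal genome size constant in Mbp. This is a
#'   convention constant (2881 for GRCh37), deliberately not recomputed from
#'   the chromosome lengths.
#' @param cytobands band table as from [read_cytoband()] or
#'   [synthetic_cytobands()].
#' @return object of class `genome_build`.
#' @examples
#' b <- genome_build()
#' b$chromosomes[["1"]]
#' @export
genome_build <- function(name = "hg19",
                         chromosomes = .hg19_lengths,
                         autosomal_mbp = 2881,
                         cytobands = NULL) {
  names(chromosomes) <- normalize_chrom(names(chromosomes))
  if (!all(c(AUTOSOMES, "X", "Y") %in% names(chromosomes)))
    stop_domain("genome build must define chromosomes 1..22, X and Y")
  cytobands <- cytobands %||% synthetic_cytobands(chromosomes[c(AUTOSOMES, "X", "Y")])
  cytobands$chrom <- normalize_chrom(cytobands$chrom)
  validate_cytobands(cytobands, chromosomes)
  structure(
    list(name = name, chromosomes = chromosomes,
         autosomal_mbp = autosomal_mbp, cytobands = cytobands),
    class = "genome_build"
  )
}

validate_cytobands <- function(cyto, lengths) {
  for (ch in unique(cyto$chrom)) {
    b <- cyto[cyto$chrom == ch, ]
    b <- b[order(b$start), ]
    if (b$start[1] != 1 || b$end[nrow(b)] != lengths[[ch]] ||
        (nrow(b) > 1 && any(b$start[-1] != b$end[-nrow(b)] + 1)))
      stop_domain("cytobands must tile chromosome ", ch,
                  " without gaps or overlaps")
  }
  invisible(TRUE)
}

#' @export
print.genome_build <- function(x, ...) {
  cat("Genome build:", x$name, "\n")
  cat("  chromosomes:", length(x$chromosomes),
      sprintf("(autosomal constant %g Mbp)", x$autosomal_mbp), "\n")
  cat("  cytobands:  ", nrow(x$cytobands), "bands\n")
  invisible(x)
}

## Validate interval columns against a build; returns index of offending rows
## with a reason, or errors when error = TRUE.
check_intervals <- function(chrom, start, end, build, error = TRUE) {
  chrom <- normalize_chrom(chrom)
  reason <- character(length(chrom))
  reason[!(chrom %in% names(build$chromosomes))] <- "unknown chromosome"
  known <- chrom %in% names(build$chromosomes)
  bad_start <- !is.na(start) & start < 1
  reason[known & bad_start & reason == ""] <- "start below 1"
  swapped <- !is.na(start) & !is.na(end) & start > end
  reason[known & swapped & reason == ""] <- "start greater than end"
  too_long <- known & !is.na(end) &
    end > unname(build$chromosomes[chrom]) & reason == ""
  reason[too_long] <- "end beyond chromosome length"
  if (error && any(reason != ""))
    stop_domain("invalid interval (", reason[reason != ""][1], ") at row ",
                which(reason != "")[1])
  reason
}

#' Interval length in megabase pairs
#'
#' Length of a 1-based inclusive interval, `(end - start + 1) / 1e6`.
#' Reporting layers round to the precision of their context (1 decimal for
#' UPD tables, 3 decimals for common-region tables); this function returns
#' full precision.
#'
#' @param start,end 1-based inclusive coordinates (vectorized).
#' @return numeric vector of lengths in Mbp.
#' @examples
#' interval_length_mbp(182537598, 197949082) # 15.41
#' @export
interval_length_mbp <- function(start, end) {
  if (any(is.na(start) | is.na(end)))
    stop_domain("interval coordinates contain missing values (start/end)")
  if (any(start < 1)) stop_domain("invalid interval: start below 1")
  if (any(start > end)) stop_domain("invalid interval: start greater than end")
  (end - start + 1) / 1e6
}

#' Overlap between two intervals in bp
#'
#' Vectorized pairwise overlap under the 1-based inclusive convention;
#' 0 when chromosomes differ or the intervals are disjoint.
#'
#' @param chrom_a,start_a,end_a first interval(s).
#' @param chrom_b,start_b,end_b second interval(s).
#' @return integer vector of overlap lengths in bp (>= 0).
#' @export
overlap_bp <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  same <- normalize_chrom(chrom_a) == normalize_chrom(chrom_b)
  ov <- pmin(end_a, end_b) - pmax(start_a, start_b) + 1
  as.integer(ifelse(same, pmax(ov, 0), 0))
}

#' Cytobands overlapping an interval
#'
#' All bands of the build with at least 1 bp overlap, in genomic order.
#'
#' @param chrom,start,end a single interval.
#' @param build a [genome_build()].
#' @return character vector of band names (e.g. `"16p11"`).
#' @export
bands_overlapping <- function(chrom, start, end, build) {
  if (is.null(build$cytobands) || nrow(build$cytobands) == 0)
    stop_domain("genome build has an empty cytoband table")
  check_intervals(chrom, start, end, build)
  ch <- normalize_chrom(chrom)
  b <- build$cytobands[build$cytobands$chrom == ch, ]
  b <- b[order(b$start), ]
  hit <- b$end >= start & b$start <= end
  b$band[hit]
}
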