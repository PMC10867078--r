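# Synthetic cohort generator with known truth labels.
#
# The generator emulates the segment lists a SNP-array pipeline exports:
# autozygous blocks from parental relatedness, single-chromosome isodisomy
# patterns, recurrent ancestral-haplotype LCSH at set population
# frequencies, sub-5 Mbp background blocks, hemizygous LOH artifacts over
# deletions, and CNV calls with classification labels tied to a phenotype
# model. It does not model recombination maps, SNP genotypes or B-allele
# frequencies: blocks are placed uniformly, so passing recovery tests shows
# the rules and estimators behave as specified, not that real cohorts meet
# the generative assumptions.

.kinship_f <- c(first = 1/4, second = 1/8, third = 1/16, fourth = 1/32,
                fifth = 1/64)

#' Simulation configuration
#'
#' Defaults describe a clinical NDD cohort: mild consanguinity mixture
#' (first 0.2%, second 0.6%, third 1.8%, fourth 1.8%, fifth 7.2% of
#' samples), a 2.8% UPD fraction, mean autozygous block lengths following
#' the 100/m heuristic (about 100 Mbp divided by the number of meioses in
#' the inbreeding loop), sub-5 Mbp background blocks averaging 2.2 per
#' sample, the packaged recurrent-region list at 5-12% population
#' frequencies, and CNV class rates yielding roughly 17% pathogenic
#' carriers.
#'
#' @param n_samples cohort size.
#' @param seed integer seed; together with the config it fully determines
#'   the output (each sample draws from its own stream derived from the
#'   cohort seed and sample index).
#' @param class_mixture named fractions of samples per kinship degree
#'   (remainder outbred).
#' @param mu_mbp mean autozygous block length per degree, Mbp.
#' @param upd list: `fraction`, `types` (named weights over `whole-iso`,
#'   `iso-het-mix`, `segmental`).
#' @param common_regions data.frame of regions with a `frequency` column
#'   (NULL disables); `jitter_mbp` is the mean exponential extension of a
#'   member block beyond each region boundary.
#' @param jitter_mbp see above.
#' @param background list: `mean_count` (Poisson mean of 3-5 Mbp blocks,
#'   placed on distinct chromosomes), `size_mean_excess` (mean of the
#'   exponential size excess above 3 Mbp, capped below 5).
#' @param noise list: `mean_count` of sub-3 Mbp segments (emitted to
#'   exercise threshold filtering).
#' @param hemizygous list: `fraction` of samples given a 10-20 Mbp
#'   single-copy deletion with a co-located LOH artifact.
#' @param cnv list of per-class rates and lognormal size parameters
#'   (`mean_kbp`, `sd_kbp` per class), `pcnv_carrier_prob`, and
#'   `small_benign_rate` for sub-10 Kbp calls that the research filter
#'   must reject.
#' @param phenotypes named list of terms, each `list(prevalence, pcnv_or)`:
#'   a logistic model where carrying a PCNV multiplies the odds of the term
#'   by `pcnv_or`.
#' @param male_fraction fraction of male samples.
#' @return validated config list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 953, seed = 1,
                       class_mixture = c(first = 0.002, second = 0.006,
                                         third = 0.018, fourth = 0.018,
                                         fifth = 0.072),
                       mu_mbp = c(first = 50, second = 33, third = 25,
                                  fourth = 20, fifth = 17),
                       upd = list(fraction = 0.028,
                                  types = c(`whole-iso` = 0.3,
                                            `iso-het-mix` = 0.5,
                                            segmental = 0.2)),
                       common_regions = NULL,
                       jitter_mbp = 0.5,
                       background = list(mean_count = 2.2,
                                         size_mean_excess = 0.6),
                       noise = list(mean_count = 1),
                       hemizygous = list(fraction = 0.01),
                       cnv = list(benign_rate = 6, vus_rate = 0.14,
                                  lpcnv_rate = 0.014,
                                  pcnv_carrier_prob = 0.17,
                                  small_benign_rate = 0.5,
                                  sizes = list(
                                    benign = c(mean_kbp = 298, sd_kbp = 586),
                                    VUS = c(mean_kbp = 802, sd_kbp = 1266),
                                    LPCNV = c(mean_kbp = 802, sd_kbp = 1266),
                                    PCNV = c(mean_kbp = 8365, sd_kbp = 9992))),
                       phenotypes = list(
                         dd = list(prevalence = 0.5, pcnv_or = 2),
                         asd = list(prevalence = 0.33, pcnv_or = 0.5)),
                       male_fraction = 0.6) {
  if (is.null(common_regions)) {
    common_regions <- common_lcsh_reference()
    common_regions$frequency <- c(0.12, 0.08, 0.07, 0.06, 0.06,
                                  0.06, 0.05, 0.08, 0.05, 0.05)
  }
  cfg <- list(n_samples = n_samples, seed = as.integer(seed),
              class_mixture = class_mixture, mu_mbp = mu_mbp, upd = upd,
              common_regions = common_regions, jitter_mbp = jitter_mbp,
              background = background, noise = noise,
              hemizygous = hemizygous, cnv = cnv, phenotypes = phenotypes,
              male_fraction = male_fraction)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_samples < 0) stop_domain("n_samples must be non-negative")
  if (sum(cfg$class_mixture) + cfg$upd$fraction > 1)
    stop_domain("class mixture plus UPD fraction exceeds 1")
  if (any(cfg$class_mixture < 0) || cfg$upd$fraction < 0)
    stop_domain("mixture fractions must be non-negative")
  if (any(cfg$mu_mbp[names(cfg$class_mixture)] <= 3, na.rm = TRUE))
    stop_domain("mean block lengths must exceed the 3 Mbp threshold")
  invisible(TRUE)
}

## place blocks (lengths in Mbp) uniformly on autosomes proportional to
## length, without overlap within the sample; existing is a data.frame of
## already-placed intervals
place_blocks <- function(lengths_mbp, build, existing = NULL,
                         chroms = AUTOSOMES, distinct_chrom = FALSE) {
  placed <- existing %||% data.frame(chrom = character(), start = numeric(),
                                     end = numeric())
  out <- list()
  avail <- chroms
  for (len in lengths_mbp) {
    bp <- round(len * 1e6)
    done <- FALSE
    for (try in 1:100) {
      w <- unname(build$chromosomes[avail])
      ch <- sample(avail, 1, prob = w)
      L <- build$chromosomes[[ch]]
      if (bp >= L) next
      start <- floor(stats::runif(1, 1, L - bp))
      end <- start + bp - 1
      p <- placed[placed$chrom == ch, , drop = FALSE]
      if (nrow(p) && any(p$end >= start & p$start <= end)) next
      row <- data.frame(chrom = ch, start = start, end = end)
      placed <- rbind(placed, row)
      out[[length(out) + 1]] <- row
      if (distinct_chrom) avail <- setdiff(avail, ch)
      done <- TRUE
      break
    }
    if (!done) stop_domain("could not place a ", round(len, 1),
                           " Mbp block; lower the block rate")
  }
  do.call(rbind, out) %||%
    data.frame(chrom = character(), start = numeric(), end = numeric())
}

#' Simulate autozygous blocks for one inbred sample
#'
#' Compound-Poisson model: block count ~ Poisson(F_d * 2881 / mu_d), block
#' lengths exponential with mean `mu_d` truncated below at 0.5 Mbp (the
#' callable-segment floor of array segmentation) and above at 150 Mbp (a
#' block cannot exceed its chromosome), placed uniformly without overlap
#' across autosomes proportional to chromosome length. The expected
#' total is about F_d * 2881 Mbp, so the sum-based inbreeding estimate is
#' recovered regardless of the length/count decomposition. Uses the current
#' RNG state.
#'
#' @param degree `"outbred"` or one of `"first"` ... `"fifth"`.
#' @param build a [genome_build()].
#' @param mu_mbp named mean block lengths per degree (Mbp).
#' @return data.frame `chrom`, `start`, `end`.
#' @export
simulate_inbred_autozygosity <- function(degree, build = genome_build(),
                                         mu_mbp = c(first = 50, second = 33,
                                                    third = 25, fourth = 20,
                                                    fifth = 17)) {
  if (degree == "outbred")
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  if (!degree %in% names(.kinship_f))
    stop_domain("unknown kinship degree: ", degree)
  f <- .kinship_f[[degree]]
  mu <- mu_mbp[[degree]]
  lam <- f * 2881 / mu
  n <- stats::rpois(1, lam)
  if (n == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  ## lengths truncated above at 150 Mbp: a single autozygous block cannot
  ## exceed the chromosome carrying it (negligible mass for all defaults)
  len <- pmin(0.5 + stats::rexp(n, 1 / mu), 150)
  place_blocks(len, build)
}

#' Simulate a UPD-like LCSH pattern on one chromosome
#'
#' * `whole-iso`: a single stretch spanning >= 90% of the chromosome
#'   (monosomy-rescue-like complete isodisomy).
#' * `iso-het-mix`: 1-3 stretches, each >= 5 Mbp, totaling >= 10 Mbp
#'   (meiosis-I rescue after recombination).
#' * `segmental`: one terminal stretch of 10-20 Mbp.
#'
#' Uses the current RNG state.
#'
#' @param type one of `"whole-iso"`, `"iso-het-mix"`, `"segmental"`.
#' @param chromosome autosome name; default: random autosome.
#' @param build a [genome_build()].
#' @return data.frame `chrom`, `start`, `end`.
#' @export
simulate_upd_sample <- function(type = c("whole-iso", "iso-het-mix",
                                         "segmental"),
                                chromosome = NULL, build = genome_build()) {
  type <- match.arg(type)
  ch <- normalize_chrom(chromosome %||% sample(AUTOSOMES, 1))
  if (!ch %in% AUTOSOMES) stop_domain("UPD simulation needs an autosome")
  L <- build$chromosomes[[ch]]
  if (type == "whole-iso") {
    frac <- stats::runif(1, 0.90, 0.98)
    bp <- round(frac * L)
    start <- floor(stats::runif(1, 1, L - bp))
    return(data.frame(chrom = ch, start = start, end = start + bp - 1))
  }
  if (type == "iso-het-mix") {
    k <- sample(1:3, 1)
    sizes <- if (k == 1) stats::runif(1, 10, 20) else stats::runif(k, 5, 12)
    if (sum(sizes) * 1e6 > 0.8 * L)
      stop_domain("chromosome ", ch, " too short for requested segments")
    placed <- data.frame(chrom = character(), start = numeric(),
                         end = numeric())
    out <- list()
    for (s in sizes) {
      bp <- round(s * 1e6)
      repeat {
        start <- floor(stats::runif(1, 1, L - bp))
        end <- start + bp - 1
        if (!nrow(placed) || !any(placed$end >= start & placed$start <= end)) {
          row <- data.frame(chrom = ch, start = start, end = end)
          placed <- rbind(placed, row); out[[length(out) + 1]] <- row
          break
        }
      }
    }
    return(do.call(rbind, out))
  }
  ## segmental: terminal
  bp <- round(stats::runif(1, 10, 20) * 1e6)
  if (bp >= L) stop_domain("chromosome ", ch, " too short for segment")
  if (stats::runif(1) < 0.5)
    data.frame(chrom = ch, start = 1, end = bp)
  else
    data.frame(chrom = ch, start = L - bp + 1, end = L)
}

## lognormal parameters from a target mean and sd
.lnorm_pars <- function(mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

simulate_sample_cnvs <- function(cfg, build) {
  out <- list()
  draw <- function(class, n) {
    if (n == 0) return(NULL)
    p <- .lnorm_pars(cfg$cnv$sizes[[class]][["mean_kbp"]],
                     cfg$cnv$sizes[[class]][["sd_kbp"]])
    size_kbp <- pmax(10.5, stats::rlnorm(n, p[["meanlog"]], p[["sdlog"]]))
    type <- ifelse(stats::runif(n) < 0.55, "loss", "gain")
    pos <- place_blocks(size_kbp / 1000, build)
    data.frame(pos, type = type,
               cn = ifelse(type == "loss", 1, 3),
               markers = pmax(10L, as.integer(round(size_kbp / 5))),
               classification = class, stringsAsFactors = FALSE)
  }
  carrier <- stats::runif(1) < cfg$cnv$pcnv_carrier_prob
  out$pcnv <- draw("PCNV", if (carrier) 1 + stats::rpois(1, 0.2) else 0)
  out$lpcnv <- draw("LPCNV", stats::rpois(1, cfg$cnv$lpcnv_rate))
  out$vus <- draw("VUS", stats::rpois(1, cfg$cnv$vus_rate))
  out$benign <- draw("benign", stats::rpois(1, cfg$cnv$benign_rate))
  ## sub-10 Kbp, low-marker calls that the research filter must drop
  n_small <- stats::rpois(1, cfg$cnv$small_benign_rate)
  if (n_small > 0) {
    size_kbp <- stats::runif(n_small, 2, 9.5)
    type <- ifelse(stats::runif(n_small) < 0.5, "loss", "gain")
    pos <- place_blocks(size_kbp / 1000, build)
    out$small <- data.frame(pos, type = type,
                            cn = ifelse(type == "loss", 1, 3),
                            markers = sample(3:9, n_small, replace = TRUE),
                            classification = "benign",
                            stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, out)
  list(calls = calls %||% NULL, pcnv_carrier = carrier)
}

#' Simulate a cohort with known truth
#'
#' Generates per-sample segment lists (Gain/Loss/LOH rows in the default
#' export dialect), a phenotype table and truth labels. The output is fully
#' determined by the config and seed: each sample uses its own RNG stream
#' derived from the cohort seed and the sample index, so per-sample output
#' is reproducible independently of cohort size.
#'
#' @param config a [sim_config()].
#' @param out_dir if non-NULL, writes `segments.tsv`, `phenotypes.csv` and
#'   `truth.json` there.
#' @return list with `segments` (export-dialect data.frame), `phenotypes`,
#'   `truth` (per-sample data.frame) and `paths`.
#' @export
simulate_cohort <- function(config = sim_config(), out_dir = NULL) {
  validate_sim_config(config)
  build <- genome_build()
  cum <- cumsum(config$class_mixture)
  seg_rows <- list(); truth_rows <- list(); phe_rows <- list()
  terms <- names(config$phenotypes)

  for (i in seq_len(config$n_samples)) {
    set.seed(sample_seed(config$seed, i))
    id <- sprintf("S%04d", i)
    sex <- if (stats::runif(1) < config$male_fraction) "male" else "female"
    u <- stats::runif(1)
    upd_type <- NA_character_; upd_chrom <- NA_character_
    degree <- "outbred"
    loh <- data.frame(chrom = character(), start = numeric(), end = numeric())
    if (u < config$upd$fraction) {
      upd_type <- sample(names(config$upd$types), 1,
                         prob = config$upd$types)
      seg <- simulate_upd_sample(upd_type, build = build)
      upd_chrom <- seg$chrom[1]
      loh <- rbind(loh, seg)
    } else {
      v <- u - config$upd$fraction
      hit <- which(v < cum)
      if (length(hit)) degree <- names(config$class_mixture)[hit[1]]
      loh <- rbind(loh, simulate_inbred_autozygosity(degree, build,
                                                     config$mu_mbp))
    }
    ## recurrent ancestral regions
    n_common <- 0L
    cr <- config$common_regions
    if (!is.null(cr) && nrow(cr)) {
      member <- stats::runif(nrow(cr)) < cr$frequency
      if (any(member)) {
        ext1 <- stats::rexp(sum(member), 1 / config$jitter_mbp) * 1e6
        ext2 <- stats::rexp(sum(member), 1 / config$jitter_mbp) * 1e6
        m <- cr[member, , drop = FALSE]
        loh <- rbind(loh, data.frame(
          chrom = m$chrom,
          start = pmax(1, round(m$start - ext1)),
          end = pmin(unname(build$chromosomes[m$chrom]), round(m$end + ext2))))
        n_common <- sum(member)
      }
    }
    ## sub-5 Mbp background blocks, one chromosome each
    n_bg <- stats::rpois(1, config$background$mean_count)
    if (n_bg > 0) {
      sz <- 3 + pmin(stats::rexp(n_bg, 1 / config$background$size_mean_excess),
                     1.99)
      loh <- rbind(loh, place_blocks(sz, build, existing = loh,
                                     distinct_chrom = TRUE))
    }
    ## sub-threshold noise segments
    n_noise <- stats::rpois(1, config$noise$mean_count)
    if (n_noise > 0)
      loh <- rbind(loh, place_blocks(stats::runif(n_noise, 0.5, 2.9), build,
                                     existing = loh))
    ## occasional X-chromosome LCSH (excluded downstream from F)
    if (stats::runif(1) < 0.05) {
      bp <- round(stats::runif(1, 3, 8) * 1e6)
      start <- floor(stats::runif(1, 1, build$chromosomes[["X"]] - bp))
      loh <- rbind(loh, data.frame(chrom = "X", start = start,
                                   end = start + bp - 1))
    }
    ## CNVs and phenotype model
    cnv <- simulate_sample_cnvs(config, build)
    ## hemizygous artifact: single-copy deletion + co-located LOH call
    hemi <- stats::runif(1) < config$hemizygous$fraction
    if (hemi) {
      art <- place_blocks(stats::runif(1, 10, 20), build, existing = loh)
      loh <- rbind(loh, art)
      cnv$calls <- rbind(cnv$calls, data.frame(
        art, type = "loss", cn = 1,
        markers = as.integer(round((art$end - art$start) / 5000)),
        classification = "benign", stringsAsFactors = FALSE))
    }
    term_flags <- vapply(terms, function(tm) {
      p <- stats::plogis(stats::qlogis(config$phenotypes[[tm]]$prevalence) +
                           log(config$phenotypes[[tm]]$pcnv_or) *
                           as.numeric(cnv$pcnv_carrier))
      stats::runif(1) < p
    }, TRUE)

    rows <- if (nrow(loh)) data.frame(
      sample_id = id,
      seg_type = "LOH", chrom = loh$chrom,
      start = round(loh$start), end = round(loh$end),
      markers = as.integer(round((loh$end - loh$start) / 3000)),
      cn = NA_real_, classification = "", stringsAsFactors = FALSE)
    else NULL
    if (!is.null(cnv$calls) && nrow(cnv$calls))
      rows <- rbind(rows, data.frame(
        sample_id = id,
        seg_type = ifelse(cnv$calls$type == "gain", "Gain", "Loss"),
        chrom = cnv$calls$chrom,
        start = round(cnv$calls$start), end = round(cnv$calls$end),
        markers = cnv$calls$markers, cn = cnv$calls$cn,
        classification = cnv$calls$classification, stringsAsFactors = FALSE))
    seg_rows[[i]] <- rows
    truth_rows[[i]] <- data.frame(
      sample_id = id, sex = sex, kinship_degree = degree,
      true_f = if (degree == "outbred") 0 else .kinship_f[[degree]],
      upd_type = upd_type, upd_chrom = upd_chrom,
      n_common_regions = n_common, pcnv_carrier = cnv$pcnv_carrier,
      hemizygous_artifact = hemi, stringsAsFactors = FALSE)
    phe <- data.frame(sample_id = id, sex = sex,
                      age_years = round(stats::runif(1, 0, 18), 1),
                      stringsAsFactors = FALSE)
    for (tm in terms) phe[[tm]] <- as.integer(term_flags[[tm]])
    phe_rows[[i]] <- phe
  }

  segments <- do.call(rbind, seg_rows) %||%
    data.frame(sample_id = character(), seg_type = character(),
               chrom = character(), start = numeric(), end = numeric(),
               markers = integer(), cn = numeric(),
               classification = character())
  truth <- do.call(rbind, truth_rows) %||% data.frame(sample_id = character())
  phenotypes <- do.call(rbind, phe_rows) %||% data.frame(sample_id = character())
  rownames(segments) <- rownames(truth) <- rownames(phenotypes) <- NULL

  ## export-dialect column headers
  dial <- chas_dialect()$columns
  export <- segments
  names(export) <- unname(dial[names(segments)])

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(segments = file.path(out_dir, "segments.tsv"),
                  phenotypes = file.path(out_dir, "phenotypes.csv"),
                  truth = file.path(out_dir, "truth.json"))
    utils::write.table(export, paths$segments, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.csv(phenotypes, paths$phenotypes, row.names = FALSE,
                     quote = FALSE)
    jsonlite::write_json(list(seed = config$seed,
                              n_samples = config$n_samples,
                              samples = truth),
                         paths$truth, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  }
  list(segments = export, phenotypes = phenotypes, truth = truth,
       paths = paths)
}
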