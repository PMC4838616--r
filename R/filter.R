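# The raw-variant filter cascade. Stage order is pinned:
#   1 nonbiallelic / fixed-alternate record removal
#   2 genotype depth mask (DP < min_genotype_depth)
#   3 imbalanced-heterozygote recoding
#   4 per-sample locus mismatch mask (MM > max_locus_mismatches)
#   5 site call-rate filter, then 6 sample call-rate filter
# Every stage reports what it removed; input - removed = output throughout.

#' Filter cascade configuration
#'
#' @param min_genotype_depth genotypes with fewer reads are masked
#'   (default 4; DP = 4 is kept, "less than 4x" is strict).
#' @param het_imbalance_threshold heterozygous calls whose minor-allele read
#'   fraction falls below this are recoded to the majority-read homozygote
#'   (default 0.2; the underlying rule is a common reduced-representation
#'   heuristic, exposed here because published pipelines rarely pin it).
#' @param max_locus_mismatches genotypes whose sample-specific mismatch
#'   count at the locus exceeds this are masked (default 3; exactly 3 is
#'   kept, "more than three" is strict).
#' @param min_samples_called SNPs called in fewer samples are dropped
#'   (default 30; exactly 30 is kept).
#' @param max_sample_missingness samples missing more than this fraction of
#'   the remaining SNPs are dropped (default 0.80; strictly greater).
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(min_genotype_depth = 4L,
                          het_imbalance_threshold = 0.2,
                          max_locus_mismatches = 3L,
                          min_samples_called = 30L,
                          max_sample_missingness = 0.80) {
  stopifnot(min_genotype_depth >= 0, max_locus_mismatches >= 0,
            min_samples_called >= 0,
            het_imbalance_threshold >= 0, het_imbalance_threshold <= 1,
            max_sample_missingness >= 0, max_sample_missingness <= 1)
  structure(list(min_genotype_depth = as.integer(min_genotype_depth),
                 het_imbalance_threshold = het_imbalance_threshold,
                 max_locus_mismatches = as.integer(max_locus_mismatches),
                 min_samples_called = as.integer(min_samples_called),
                 max_sample_missingness = max_sample_missingness),
            class = "filter_config")
}

report_entry <- function(stage, unit, input, removed) {
  data.frame(stage = stage, unit = unit, input = input, removed = removed,
             output = input - removed, stringsAsFactors = FALSE)
}

is_het <- function(rec) {
  !is.na(rec$gt[1, ]) & !is.na(rec$gt[2, ]) & rec$gt[1, ] != rec$gt[2, ]
}

#' Remove non-biallelic and fixed-alternate records
#'
#' Retains only sites where REF and the single ALT are both one base pair
#' (drops indels and sites with more than two alleles), and drops sites
#' fixed for the alternate allele across all called samples (different from
#' the reference but invariant among samples).
#'
#' @param vr a `variant_records` object.
#' @return list with `records` (filtered `variant_records`) and `report`
#'   (one [report_entry] row with a `detail` attribute of per-reason counts).
#' @export
remove_nonbiallelic <- function(vr) {
  stopifnot(inherits(vr, "variant_records"))
  cls <- vapply(vr$records, function(r) {
    if (length(r$alts) > 1L) return("multiallelic")
    if (nchar(r$ref) != 1L || nchar(r$alts) != 1L) return("indel")
    al <- r$gt[!is.na(r$gt)]
    if (length(al) && all(al == 1L)) return("fixed_alt")
    "keep"
  }, "")
  keep <- cls == "keep"
  rep <- report_entry("nonbiallelic_fixed_alt", "sites",
                      length(vr$records), sum(!keep))
  attr(rep, "detail") <- table(cls[!keep])
  vr$records <- vr$records[keep]
  list(records = vr, report = rep)
}

#' Mask low-depth genotypes
#'
#' Genotypes with `DP < min_genotype_depth` are set missing; the site is
#' retained. Missing DP is treated as depth 0 (masked).
#'
#' @param vr a `variant_records` object.
#' @param config a [filter_config()].
#' @return list with `records` and `report` (genotypes masked).
#' @export
mask_low_depth <- function(vr, config = filter_config()) {
  n_called <- 0L; n_masked <- 0L
  vr$records <- lapply(vr$records, function(r) {
    called <- !is.na(r$gt[1, ])
    n_called <<- n_called + sum(called)
    dp <- ifelse(is.na(r$dp), 0L, r$dp)
    mask <- called & dp < config$min_genotype_depth
    n_masked <<- n_masked + sum(mask)
    r$gt[, mask] <- NA_integer_
    r
  })
  list(records = vr,
       report = report_entry("depth_mask", "genotypes", n_called, n_masked))
}

#' Recode heterozygotes with strong allelic imbalance
#'
#' A heterozygous call whose minor-allele read fraction is below
#' `het_imbalance_threshold` becomes homozygous for the majority-read
#' allele. Balanced heterozygotes are unchanged. A heterozygote without AD
#' is set missing (its imbalance cannot be assessed).
#'
#' @inheritParams mask_low_depth
#' @return list with `records` and `report` (hets recoded; a `detail`
#'   attribute carries the count set missing for absent AD).
#' @export
recode_imbalanced_hets <- function(vr, config = filter_config()) {
  n_het <- 0L; n_recoded <- 0L; n_dropped <- 0L
  thr <- config$het_imbalance_threshold
  vr$records <- lapply(vr$records, function(r) {
    het <- which(is_het(r))
    n_het <<- n_het + length(het)
    for (i in het) {
      a <- r$gt[, i]
      ad <- if (is.null(r$ad)) NULL else r$ad[[i]]
      d <- if (is.null(ad)) NULL else ad[a + 1L]
      if (is.null(d) || any(is.na(d)) || sum(d) == 0L) {
        r$gt[, i] <- NA_integer_
        n_dropped <<- n_dropped + 1L
        next
      }
      frac <- min(d) / sum(d)
      if (frac < thr && d[1] != d[2]) {
        major <- a[which.max(d)]
        r$gt[, i] <- major
        n_recoded <<- n_recoded + 1L
      }
    }
    r
  })
  rep <- report_entry("het_recode", "genotypes", n_het, n_recoded + n_dropped)
  attr(rep, "detail") <- c(recoded = n_recoded, set_missing = n_dropped)
  list(records = vr, report = rep)
}

#' Mask genotypes at high-mismatch loci
#'
#' A (sample, locus) genotype is set missing when that sample's reads at the
#' locus carry more than `max_locus_mismatches` mismatches against the
#' reference (a high density of sample-specific polymorphism indicates
#' alignment error). If no record carries mismatch counts (MM), the stage is
#' skipped with a warning.
#'
#' @inheritParams mask_low_depth
#' @return list with `records` and `report`.
#' @export
drop_mismatch_loci <- function(vr, config = filter_config()) {
  has_mm <- any(vapply(vr$records, function(r) !is.null(r$mm), TRUE))
  if (!has_mm) {
    warning("no per-genotype mismatch counts (MM) present; ",
            "mismatch stage skipped")
    return(list(records = vr,
                report = report_entry("mismatch_mask", "genotypes", 0L, 0L)))
  }
  n_called <- 0L; n_masked <- 0L
  vr$records <- lapply(vr$records, function(r) {
    called <- !is.na(r$gt[1, ])
    n_called <<- n_called + sum(called)
    if (is.null(r$mm)) return(r)
    mask <- called & !is.na(r$mm) & r$mm > config$max_locus_mismatches
    n_masked <<- n_masked + sum(mask)
    r$gt[, mask] <- NA_integer_
    r
  })
  list(records = vr,
       report = report_entry("mismatch_mask", "genotypes", n_called, n_masked))
}

records_to_dosage <- function(vr) {
  s <- length(vr$records)
  dos <- matrix(NA_integer_, length(vr$samples), s)
  for (j in seq_len(s)) {
    gt <- vr$records[[j]]$gt
    dos[, j] <- gt[1, ] + gt[2, ]
  }
  rownames(dos) <- vr$samples
  dos
}

#' Site and sample call-rate filters
#'
#' Drops SNPs called in fewer than `min_samples_called` samples (a call in
#' exactly `min_samples_called` is retained), then drops samples whose
#' missingness across the remaining SNPs exceeds `max_sample_missingness`.
#' Site filtering strictly precedes sample filtering.
#'
#' @inheritParams mask_low_depth
#' @param sample_meta optional data.frame (as from [read_sample_metadata()])
#'   merged into the output's sample table by id.
#' @return list with `matrix` (a `geno_matrix`) and `report` (two rows).
#' @export
apply_site_and_sample_callrate <- function(vr, config = filter_config(),
                                           sample_meta = NULL) {
  dos <- records_to_dosage(vr)
  called <- colSums(!is.na(dos))
  keep_snp <- called >= config$min_samples_called
  rep1 <- report_entry("site_callrate", "sites", ncol(dos), sum(!keep_snp))
  dos <- dos[, keep_snp, drop = FALSE]
  recs <- vr$records[keep_snp]
  if (ncol(dos) == 0L) stop("no SNPs left after the site call-rate filter")
  miss <- rowMeans(is.na(dos))
  keep_sample <- miss <= config$max_sample_missingness
  rep2 <- report_entry("sample_callrate", "samples", nrow(dos),
                       sum(!keep_sample))
  dos <- dos[keep_sample, , drop = FALSE]
  if (nrow(dos) == 0L) stop("no samples left after the sample call-rate filter")
  nonempty <- colSums(!is.na(dos)) > 0L
  dos <- dos[, nonempty, drop = FALSE]
  recs <- recs[nonempty]
  snps <- data.frame(
    id = paste0(vapply(recs, `[[`, "", "chrom"), "_",
                vapply(recs, `[[`, 0L, "pos")),
    chrom = vapply(recs, `[[`, "", "chrom"),
    pos = vapply(recs, `[[`, 0L, "pos"), stringsAsFactors = FALSE)
  samples <- data.frame(id = vr$samples[keep_sample],
                        stringsAsFactors = FALSE)
  if (!is.null(sample_meta)) {
    m <- match(samples$id, sample_meta$id)
    for (col in c("growth_habit", "geography", "subpop"))
      if (!is.null(sample_meta[[col]])) samples[[col]] <- sample_meta[[col]][m]
  }
  gm <- genotype_matrix(dos, snps, samples)
  list(matrix = gm, report = rbind(rep1, rep2))
}

#' Run the full filter cascade
#'
#' Applies, in pinned order: non-biallelic/fixed-alternate removal, depth
#' masking, imbalanced-het recoding, mismatch masking, then the site and
#' sample call-rate filters, and assembles the per-stage report.
#'
#' @param vr a `variant_records` object (from [read_vcf()]).
#' @param config a [filter_config()].
#' @param sample_meta optional sample metadata data.frame.
#' @return list with `matrix` (a `geno_matrix`) and `report` (data.frame of
#'   per-stage counts, input - removed = output in every row).
#' @export
filter_cascade <- function(vr, config = filter_config(), sample_meta = NULL) {
  s1 <- remove_nonbiallelic(vr)
  s2 <- mask_low_depth(s1$records, config)
  s3 <- recode_imbalanced_hets(s2$records, config)
  s4 <- drop_mismatch_loci(s3$records, config)
  s5 <- apply_site_and_sample_callrate(s4$records, config, sample_meta)
  list(matrix = s5$matrix,
       report = rbind(s1$report, s2$report, s3$report, s4$report, s5$report))
}

#' Flag samples whose PCA position disagrees with their label
#'
#' A reporting aid mirroring passport-discordance review: samples whose
#' nearest PC1-PC2 centroid differs from their recorded subpopulation are
#' flagged for human inspection, never auto-removed.
#'
#' @param gm a `geno_matrix` with subpopulation labels.
#' @param q,seed passed to [ppca_fit()].
#' @return the data.frame from [cluster_support()], discordant rows flagged.
#' @export
flag_discordant_samples <- function(gm, q = 10, seed = 1) {
  fit <- ppca_fit(gm, q = min(q, n_samples(gm) - 1L, n_snps(gm) - 1L),
                  seed = seed)
  cluster_support(fit, gm$samples$subpop)
}
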