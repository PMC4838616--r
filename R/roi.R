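# Region-of-interest scanning: flag SNPs whose per-SNP statistic exceeds
# the genome-wide mean + k SD, merge them into regions, and diagnose
# inversion-like PC1 banding inside each region.

#' Flag outlier SNPs on a per-SNP statistic track
#'
#' Flags values greater than mean + `k_sd` * sd, both computed genome-wide
#' on defined values. All-identical tracks flag nothing.
#'
#' @param values numeric vector (NA allowed).
#' @param k_sd threshold in standard deviations (default 3).
#' @return logical vector the length of `values`.
#' @export
outlier_snps <- function(values, k_sd = 3) {
  ok <- !is.na(values)
  if (sum(ok) < 100)
    stop("track has ", sum(ok), " defined values; need at least 100")
  mu <- mean(values[ok]); sdv <- stats::sd(values[ok])
  if (sdv == 0) return(rep(FALSE, length(values)))
  !is.na(values) & values > mu + k_sd * sdv
}

#' Merge flagged SNPs into regions of interest
#'
#' Consecutive flagged SNPs on the same chromosome closer than
#' `max_gap_bp` are merged; regions with fewer than `min_snps` flagged
#' SNPs are dropped. Region boundaries are the first and last member SNP
#' positions (1-based inclusive).
#'
#' @param chrom,pos per-SNP coordinates (same length as `flagged`).
#' @param flagged logical vector from [outlier_snps()].
#' @param max_gap_bp merge gap (default 1 Mb).
#' @param min_snps minimum flagged SNPs per region (default 10).
#' @return data.frame: chrom, start, end, n_snps (possibly 0 rows).
#' @export
merge_regions <- function(chrom, pos, flagged, max_gap_bp = 1e6,
                          min_snps = 10) {
  f <- which(flagged)
  out <- list()
  if (length(f)) {
    d <- data.frame(chrom = chrom[f], pos = pos[f], stringsAsFactors = FALSE)
    d <- d[order(match(d$chrom, chrom_order(d$chrom)), d$pos), ]
    newgrp <- c(TRUE, d$chrom[-1] != d$chrom[-nrow(d)] |
                  diff(d$pos) > max_gap_bp)
    grp <- cumsum(newgrp)
    for (g in unique(grp)) {
      rows <- d[grp == g, ]
      if (nrow(rows) < min_snps) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = rows$chrom[1], start = min(rows$pos), end = max(rows$pos),
        n_snps = nrow(rows), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_snps = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# mean silhouette width of a 1-D clustering
silhouette_1d <- function(x, cl) {
  n <- length(x)
  dmat <- abs(outer(x, x, "-"))
  ks <- sort(unique(cl))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cl == cl[i]
    a <- if (sum(own) > 1L) sum(dmat[i, own]) / (sum(own) - 1L) else 0
    b <- min(vapply(ks[ks != cl[i]], function(k)
      mean(dmat[i, cl == k]), 0))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Diagnose inversion-like PC1 banding within a region
#'
#' Runs PPCA restricted to the region's SNPs (all samples jointly),
#' clusters PC1 with 1-D k-means at k = 2 and 3 (deterministic
#' quantile-seeded centers), and selects k by silhouette subject to a
#' separation requirement: every pair of adjacent clusters must be
#' separated by a gap larger than `separation_ratio` times their average
#' within-cluster spread. Three-band iff k = 3 qualifies and the middle
#' cluster's mean lies between the outer means; k = 2 gives "two-band";
#' otherwise "none". Band occupancies are reported per subpopulation label.
#'
#' @param gm a `geno_matrix`.
#' @param chrom,start,end the region (1-based inclusive bp).
#' @param min_snps minimum usable region SNPs (default 20; fewer returns
#'   diagnosis "none" with a reason).
#' @param min_call_rate region SNPs below this call rate are ignored.
#' @param silhouette_min minimum mean silhouette for a candidate k
#'   (default 0.5).
#' @param separation_ratio required gap / spread ratio (default 0.5).
#' @param seed passed to [ppca_fit()].
#' @return object of class `region_banding`: `diagnosis` ("none",
#'   "two-band", "three-band"), `k`, `bands` (band, mean, n), `occupancy`
#'   (label x band matrix), `pc1` (named scores), `silhouette`, `reason`.
#' @export
region_pca_banding <- function(gm, chrom, start, end, min_snps = 20,
                               min_call_rate = 0.1, silhouette_min = 0.5,
                               separation_ratio = 0.5, seed = 1) {
  in_region <- gm$snps$chrom == chrom & gm$snps$pos >= start &
    gm$snps$pos <= end
  cr <- colMeans(!is.na(gm$dosage))
  usable <- in_region & cr >= min_call_rate
  none <- function(reason) structure(
    list(diagnosis = "none", k = 1L, bands = NULL, occupancy = NULL,
         pc1 = NULL, silhouette = NA_real_, reason = reason),
    class = "region_banding")
  if (sum(usable) < min_snps)
    return(none(sprintf("only %d usable SNPs in region (< %d)",
                        sum(usable), min_snps)))
  sub <- gm
  sub$dosage <- gm$dosage[, usable, drop = FALSE]
  sub$snps <- gm$snps[usable, , drop = FALSE]
  has_obs <- rowSums(!is.na(sub$dosage)) > 0L
  sub$dosage <- sub$dosage[has_obs, , drop = FALSE]
  sub$samples <- sub$samples[has_obs, , drop = FALSE]
  fit <- ppca_fit(sub, q = 2, seed = seed)
  pc1 <- stats::setNames(fit$scores[, 1], sub$samples$id)
  best_k <- 1L; best_sil <- NA_real_; best_cl <- NULL
  for (k in 2:3) {
    # deterministic init: centers spread over the PC1 range (robust to
    # unbalanced band occupancies, unlike quantile seeding)
    centers <- seq(min(pc1), max(pc1), length.out = k)
    if (anyDuplicated(centers)) next
    km <- suppressWarnings(stats::kmeans(pc1, centers = matrix(centers)))
    cl <- km$cluster
    if (length(unique(cl)) < k) next
    means <- vapply(seq_len(k), function(j) mean(pc1[cl == j]), 0)
    ordk <- order(means)
    sep_ok <- TRUE
    for (j in seq_len(k - 1)) {
      lo <- pc1[cl == ordk[j]]; hi <- pc1[cl == ordk[j + 1]]
      gap <- min(hi) - max(lo)
      spread <- mean(c(diff(range(lo)), diff(range(hi))))
      if (!(gap > separation_ratio * spread) || gap <= 0) {
        sep_ok <- FALSE
        break
      }
    }
    if (!sep_ok) next
    sil <- silhouette_1d(pc1, cl)
    if (sil >= silhouette_min && (is.na(best_sil) || sil > best_sil)) {
      best_k <- k; best_sil <- sil; best_cl <- cl
    }
  }
  if (best_k == 1L) {
    res <- none("no k in {2,3} passed the silhouette + separation rule")
    res$pc1 <- pc1
    return(res)
  }
  means <- vapply(seq_len(best_k), function(j) mean(pc1[best_cl == j]), 0)
  ordk <- order(means)
  band <- match(best_cl, ordk)  # 1 = lowest-PC1 band
  bands <- data.frame(band = seq_len(best_k), mean = means[ordk],
                      n = as.integer(table(factor(band,
                                                  seq_len(best_k)))))
  occ <- table(label = sub$samples$subpop, band = band)
  structure(list(
    diagnosis = if (best_k == 3L) "three-band" else "two-band",
    k = best_k, bands = bands, occupancy = occ, pc1 = pc1,
    silhouette = best_sil, reason = NA_character_),
    class = "region_banding")
}

#' @export
print.region_banding <- function(x, ...) {
  cat(sprintf("region_banding: %s (k = %d, silhouette %.2f)\n",
              x$diagnosis, x$k,
              if (is.na(x$silhouette)) NA else x$silhouette))
  if (!is.na(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}

#' Scan a per-SNP track for regions of interest and diagnose banding
#'
#' Convenience wrapper: outlier flagging at `k_sd`, gap merging, then
#' [region_pca_banding()] on each merged region.
#'
#' @param gm a `geno_matrix`.
#' @param track data.frame with columns chrom, pos and the statistic named
#'   by `value_col` (e.g. a [per_snp_fst_track()]).
#' @param value_col column holding the statistic (default "fst").
#' @param k_sd,max_gap_bp,min_snps see [outlier_snps()] / [merge_regions()].
#' @param ... passed to [region_pca_banding()].
#' @return list with `regions` (data.frame + `diagnosis` column) and
#'   `banding` (list of `region_banding` objects).
#' @export
roi_scan <- function(gm, track, value_col = "fst", k_sd = 3,
                     max_gap_bp = 1e6, min_snps = 10, ...) {
  flags <- outlier_snps(track[[value_col]], k_sd)
  regions <- merge_regions(track$chrom, track$pos, flags,
                           max_gap_bp = max_gap_bp, min_snps = min_snps)
  banding <- lapply(seq_len(nrow(regions)), function(i)
    region_pca_banding(gm, regions$chrom[i], regions$start[i],
                       regions$end[i], ...))
  regions$diagnosis <- vapply(banding, `[[`, "", "diagnosis")
  list(regions = regions, banding = banding)
}
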