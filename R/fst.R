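# Hudson-estimator Fst as a ratio of averages, with optional
# inbreeding-deflated chromosome counts and dual ascertainment.

#' Per-SNP Hudson estimator components
#'
#' For sample allele frequencies `p1`, `p2` measured on `n1`, `n2`
#' chromosomes:
#' numerator = (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1);
#' denominator = p1(1-p2) + p2(1-p1).
#' All arguments are vectorized. SNPs with n <= 1 chromosome in either
#' population yield NA components (excluded, reported by callers).
#'
#' @param p1,p2 sample allele frequencies in `[0, 1]`.
#' @param n1,n2 chromosome counts (may be non-integer after inbreeding
#'   deflation).
#' @return list with `num` and `den` vectors.
#' @export
hudson_components <- function(p1, n1, p2, n2) {
  bad <- is.na(p1) | is.na(p2) | n1 <= 1 | n2 <= 1
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  num[bad] <- NA_real_
  den[bad] <- NA_real_
  list(num = num, den = den)
}

#' Inbreeding coefficient from heterozygote deficit
#'
#' F-hat = 1 - sum(H_obs) / sum(H_exp) over SNPs, clipped to `[0, 1]`, with
#' H_exp the small-sample-corrected expected heterozygosity
#' 2p(1-p) n/(n-1) (n = called chromosomes). The ratio of sums is used
#' rather than a mean of per-SNP ratios, which diverges at near-fixed SNPs.
#'
#' @param gm a `geno_matrix`.
#' @param subpop subpopulation label (or vector of row indices).
#' @param snp_idx optional SNP index subset.
#' @return scalar F-hat in `[0, 1]`.
#' @export
inbreeding_coefficient <- function(gm, subpop, snp_idx = NULL) {
  rows <- if (is.character(subpop)) subpop_idx(gm, subpop) else subpop
  dos <- gm$dosage[rows, , drop = FALSE]
  if (!is.null(snp_idx)) dos <- dos[, snp_idx, drop = FALSE]
  called <- colSums(!is.na(dos))
  ok <- called >= 2L
  dos <- dos[, ok, drop = FALSE]
  called <- called[ok]
  if (!length(called)) return(NA_real_)
  h_obs <- colSums(dos == 1L, na.rm = TRUE) / called
  p <- colSums(dos, na.rm = TRUE) / (2 * called)
  nchr <- 2 * called
  h_exp <- 2 * p * (1 - p) * nchr / (nchr - 1)
  if (sum(h_exp) <= 0) return(0)
  min(max(1 - sum(h_obs) / sum(h_exp), 0), 1)
}

# frequencies, chromosome counts and ascertainment predicate for a pair
pair_snp_stats <- function(gm, pop, snp_idx) {
  rows <- subpop_idx(gm, pop)
  if (length(rows) < 2L) stop("subpopulation ", pop, " has < 2 samples")
  dos <- gm$dosage[rows, snp_idx, drop = FALSE]
  called <- colSums(!is.na(dos))
  alt <- colSums(dos, na.rm = TRUE)
  nchr <- 2 * called
  p <- ifelse(nchr > 0, alt / nchr, NA_real_)
  # "ascertained in X": both alleles present in X (minor allele count >= 1)
  poly <- nchr > 0 & alt >= 1 & alt <= nchr - 1
  list(p = p, nchr = nchr, poly = poly)
}

#' Genome-wide Hudson Fst (ratio of averages)
#'
#' Averages per-SNP Hudson numerators and denominators over SNPs of one
#' subgenome that are polymorphic in the ascertainment subpopulation
#' (ratio of averages, not average of ratios). With
#' `inbreeding_adjust = TRUE`, each subpopulation's chromosome count is
#' deflated to `n / (1 + F-hat)` using that subpopulation's heterozygote
#' deficit, correcting the numerator's sampling-variance term for
#' correlated alleles within selfing individuals.
#'
#' @param gm a `geno_matrix` with subpopulation labels.
#' @param pair character vector of two subpopulation labels.
#' @param subgenome "A", "C", or NULL for both.
#' @param ascertainment which member of `pair` defines the polymorphic SNP
#'   set (default the first).
#' @param inbreeding_adjust logical (default TRUE).
#' @param snp_idx optional SNP index subset (applied before the subgenome
#'   and ascertainment filters).
#' @return object of class `fst_result`: `fst`, `pair`, `ascertainment`,
#'   `subgenome`, `n_snps`, `f_hat` (per pop), and per-SNP `num`/`den`
#'   components with their SNP ids.
#' @export
genomewide_fst <- function(gm, pair, subgenome = NULL,
                           ascertainment = pair[1],
                           inbreeding_adjust = TRUE, snp_idx = NULL) {
  stopifnot(length(pair) == 2L, ascertainment %in% pair)
  idx <- seq_len(n_snps(gm))
  if (!is.null(snp_idx)) idx <- idx[snp_idx]
  if (!is.null(subgenome)) idx <- idx[gm$snps$subgenome[idx] %in% subgenome]
  st1 <- pair_snp_stats(gm, pair[1], idx)
  st2 <- pair_snp_stats(gm, pair[2], idx)
  poly <- if (ascertainment == pair[1]) st1$poly else st2$poly
  keep <- poly & st1$nchr >= 2 & st2$nchr >= 2
  if (!any(keep))
    stop("zero qualifying SNPs for pair ", paste(pair, collapse = "-"),
         " ascertained in ", ascertainment)
  f_hat <- c(0, 0)
  n1 <- st1$nchr[keep]; n2 <- st2$nchr[keep]
  if (inbreeding_adjust) {
    f_hat <- c(inbreeding_coefficient(gm, pair[1], idx),
               inbreeding_coefficient(gm, pair[2], idx))
    n1 <- n1 / (1 + f_hat[1])
    n2 <- n2 / (1 + f_hat[2])
  }
  hc <- hudson_components(st1$p[keep], n1, st2$p[keep], n2)
  ok <- !is.na(hc$num)
  fst <- sum(hc$num[ok]) / sum(hc$den[ok])
  structure(list(fst = fst, pair = pair, ascertainment = ascertainment,
                 subgenome = if (is.null(subgenome)) "all" else subgenome,
                 n_snps = sum(ok), f_hat = stats::setNames(f_hat, pair),
                 snp_id = gm$snps$id[idx][keep][ok],
                 num = hc$num[ok], den = hc$den[ok]),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf(
    "Hudson Fst %s (asc. %s, subgenome %s): %.4f over %d SNPs\n",
    paste(x$pair, collapse = "-"), x$ascertainment,
    paste(x$subgenome, collapse = "+"), x$fst, x$n_snps))
  invisible(x)
}

#' Per-SNP Fst track
#'
#' The per-SNP Hudson ratio numerator/denominator in genome order, for
#' plotting and region scanning. SNPs monomorphic in both subpopulations
#' (zero denominator) or with insufficient calls are NA.
#'
#' @param gm a `geno_matrix`.
#' @param pair two subpopulation labels.
#' @param inbreeding_adjust logical (default FALSE: raw per-SNP values).
#' @return data.frame in genome order: id, chrom, pos, subgenome, fst.
#' @export
per_snp_fst_track <- function(gm, pair, inbreeding_adjust = FALSE) {
  idx <- seq_len(n_snps(gm))
  st1 <- pair_snp_stats(gm, pair[1], idx)
  st2 <- pair_snp_stats(gm, pair[2], idx)
  n1 <- st1$nchr; n2 <- st2$nchr
  if (inbreeding_adjust) {
    n1 <- n1 / (1 + inbreeding_coefficient(gm, pair[1]))
    n2 <- n2 / (1 + inbreeding_coefficient(gm, pair[2]))
  }
  hc <- hudson_components(st1$p, n1, st2$p, n2)
  fst <- ifelse(!is.na(hc$den) & hc$den > 0, hc$num / hc$den, NA_real_)
  ord <- genome_order(gm$snps)
  data.frame(id = gm$snps$id, chrom = gm$snps$chrom, pos = gm$snps$pos,
             subgenome = gm$snps$subgenome, fst = fst,
             stringsAsFactors = FALSE)[ord, , drop = FALSE]
}
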