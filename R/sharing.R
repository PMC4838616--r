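# Venn partition of minor-allele presence across the three major
# subpopulations, per subgenome, with size-matched downsampling replicates.

#' Define the per-SNP minor allele over pooled subpopulations
#'
#' The minor allele is the one at lower frequency when the listed
#' subpopulations' called genotypes are pooled; exact 0.5 ties go to the
#' alternate allele (fixed, documented rule). SNPs uncalled in every listed
#' subpopulation are NA (excluded downstream).
#'
#' @param gm a `geno_matrix`.
#' @param subpops subpopulation labels to pool (default WE, WA, SP; WAm is
#'   excluded throughout this analysis for its small sample size).
#' @return character vector per SNP: "alt", "ref" or NA.
#' @export
define_minor_allele <- function(gm, subpops = c("WE", "WA", "SP")) {
  rows <- subpop_idx(gm, subpops)
  ac <- allele_counts(gm, rows)
  freq_alt <- ifelse(ac$chrom > 0, ac$alt / ac$chrom, NA_real_)
  out <- ifelse(is.na(freq_alt), NA_character_,
                ifelse(freq_alt <= 0.5, "alt", "ref"))
  stats::setNames(out, gm$snps$id)
}

VENN_CELLS <- c("WE_only", "WA_only", "SP_only", "WE_WA", "WE_SP", "WA_SP",
                "WE_WA_SP")

# presence (>= 1 copy of the minor allele among called genotypes) per pop
minor_presence <- function(gm, subpops, minor) {
  pres <- sapply(subpops, function(k) {
    dos <- gm$dosage[subpop_idx(gm, k), , drop = FALSE]
    has_alt <- colSums(dos >= 1L, na.rm = TRUE) > 0L
    has_ref <- colSums(dos <= 1L, na.rm = TRUE) > 0L
    ifelse(minor == "alt", has_alt, has_ref)
  })
  pres <- matrix(pres, ncol = length(subpops))
  pres[is.na(minor), ] <- FALSE
  pres
}

#' Venn partition of minor-allele presence
#'
#' Counts, per subgenome, the SNPs whose minor allele is present (>= 1
#' copy, a heterozygote counting as one) in each of the 7 subpopulation
#' combinations. Cells partition exactly the SNPs present in at least one
#' subpopulation.
#'
#' @param gm a `geno_matrix`.
#' @param subgenome "A" or "C".
#' @param subpops the three subpopulations (default WE, WA, SP).
#' @param minor optional precomputed [define_minor_allele()] vector.
#' @return object of class `sharing_partition`: `cells` (named 7-vector),
#'   `totals` (per-subpopulation presence counts), `n_snps` (SNPs in >= 1
#'   subpopulation), `subgenome`.
#' @export
venn_partition <- function(gm, subgenome, subpops = c("WE", "WA", "SP"),
                           minor = NULL) {
  stopifnot(length(subpops) == 3L)
  if (is.null(minor)) minor <- define_minor_allele(gm, subpops)
  on_sg <- gm$snps$subgenome == subgenome
  pres <- minor_presence(gm, subpops, minor)[on_sg, , drop = FALSE]
  a <- pres[, 1]; b <- pres[, 2]; c_ <- pres[, 3]
  cells <- c(sum(a & !b & !c_), sum(!a & b & !c_), sum(!a & !b & c_),
             sum(a & b & !c_), sum(a & !b & c_), sum(!a & b & c_),
             sum(a & b & c_))
  names(cells) <- sub("WE", subpops[1],
                      sub("WA", subpops[2], sub("SP", subpops[3],
                                                VENN_CELLS)))
  structure(list(cells = cells,
                 totals = stats::setNames(colSums(pres), subpops),
                 n_snps = sum(a | b | c_), subgenome = subgenome),
            class = "sharing_partition")
}

#' @export
print.sharing_partition <- function(x, ...) {
  cat(sprintf("sharing_partition (subgenome %s): %d SNPs in >= 1 subpopulation\n",
              x$subgenome, x$n_snps))
  print(x$cells)
  invisible(x)
}

#' Venn partition under subpopulation-size-matched downsampling
#'
#' Repeatedly downsamples every subpopulation larger than `target_n` to
#' `target_n` samples (without replacement), recomputes the partition, and
#' reports per-cell means and standard deviations. The minor-allele
#' definition is recomputed on each downsampled panel. Deterministic under
#' `seed`.
#'
#' @param gm a `geno_matrix`.
#' @param subgenome "A" or "C".
#' @param target_n target subpopulation size (e.g. the smallest
#'   subpopulation's size).
#' @param n_replicates number of downsamplings (default 100).
#' @param subpops the three subpopulations.
#' @param seed RNG seed.
#' @return object of class `sharing_downsampled`: `mean` and `sd` per cell,
#'   `totals_mean`, `replicates` (matrix of per-replicate cell counts),
#'   `target_n`.
#' @export
downsampled_partition <- function(gm, subgenome, target_n,
                                  n_replicates = 100,
                                  subpops = c("WE", "WA", "SP"), seed = 1) {
  sizes <- vapply(subpops, function(k) length(subpop_idx(gm, k)), 0L)
  if (any(sizes < target_n))
    stop("target_n exceeds the size of: ",
         paste(subpops[sizes < target_n], collapse = ", "))
  set.seed(seed)
  reps <- matrix(NA_real_, n_replicates, length(VENN_CELLS))
  totals <- matrix(NA_real_, n_replicates, 3L)
  for (r in seq_len(n_replicates)) {
    keep <- unlist(lapply(subpops, function(k) {
      rows <- subpop_idx(gm, k)
      if (length(rows) > target_n) sort(sample(rows, target_n)) else rows
    }))
    keep <- sort(unique(c(keep, setdiff(seq_len(n_samples(gm)),
                                        subpop_idx(gm, subpops)))))
    sub <- subset_samples(gm, keep)
    part <- venn_partition(sub, subgenome, subpops)
    reps[r, ] <- part$cells
    totals[r, ] <- part$totals
  }
  colnames(reps) <- VENN_CELLS
  structure(list(mean = colMeans(reps), sd = apply(reps, 2, stats::sd),
                 totals_mean = stats::setNames(colMeans(totals), subpops),
                 replicates = reps, target_n = target_n,
                 subgenome = subgenome),
            class = "sharing_downsampled")
}
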