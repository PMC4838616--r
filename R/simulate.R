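# Synthetic genotype panels with the statistical structure the analysis
# assumes: Balding-Nichols differentiation against a shared ancestral pool,
# selfing-level excess homozygosity, depth-coupled missingness of SBG-like
# severity, and segregating non-recombining (inversion) haplotype blocks.

# A01..A10 ~315 Mb total, C01..C09 ~527 Mb total, matching the reference
# assembly proportions (A subgenome ~37.5% of the genome).
default_chrom_lengths <- function() {
  c(stats::setNames(rep(31.5e6, 10), sprintf("A%02d", 1:10)),
    stats::setNames(rep(58.6e6, 9), sprintf("C%02d", 1:9)))
}

#' Specification of one segregating inversion region
#'
#' @param chrom chromosome name.
#' @param start,end interval in bp (1-based inclusive).
#' @param freq named numeric vector: frequency of the inverted haplotype in
#'   each subpopulation (values in `[0, 1]`).
#' @param divergence per-SNP probability that the two haplotypes carry
#'   different alleles (default 0.8: high enough for sharp PC1 banding).
#' @param noise per-allele-copy flip probability inside the region
#'   (default 0.01).
#' @return a list of class `inversion_spec`.
#' @export
inversion_spec <- function(chrom, start, end, freq,
                           divergence = 0.8, noise = 0.01) {
  stopifnot(start <= end, all(freq >= 0 & freq <= 1),
            divergence >= 0, divergence <= 1, noise >= 0, noise <= 1)
  structure(list(chrom = chrom, start = start, end = end, freq = freq,
                 divergence = divergence, noise = noise),
            class = "inversion_spec")
}

#' Simulation configuration
#'
#' Defaults emulate the diversity panel the package targets: 782 samples in
#' four subpopulations (WE 347, WA 212, SP 185, WAm 38), 30,881 SNPs split
#' 38.8%/61.2% between the A and C subgenomes (~1 SNP / 27.5 kb), pairwise
#' differentiation in the 0.18-0.28 range, strong selfing (F_is = 0.9), a
#' median SNP call rate near 25%, negative-binomial read depth (mean 8,
#' size 2; ~35% of genotypes under 4x), and one inversion on C02 segregating
#' at high frequency only in the spring subpopulation.
#'
#' @param n_samples named integer vector of subpopulation sizes.
#' @param n_snps named integer vector: SNP count per subgenome (`A`, `C`).
#' @param fst named numeric vector: per-subpopulation Balding-Nichols F
#'   against the shared ancestral pool. The realized pairwise Fst between two
#'   subpopulations is approximately the mean of their two F values.
#' @param f_is named numeric vector (or scalar) of within-subpopulation
#'   inbreeding coefficients.
#' @param call_rate_mean mean of the per-SNP call-rate distribution; 1
#'   disables missingness.
#' @param call_rate_disp Beta concentration of per-SNP call rates (smaller =
#'   more dispersed; the default right-skews the distribution so the median
#'   falls below the mean, as in real SBG data).
#' @param sample_rate_sd log-normal sd of the per-sample call-rate
#'   multiplier.
#' @param depth_mean,depth_size negative-binomial read-depth model.
#' @param maf_range range of the ancestral allele frequency (uniform draw).
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param inversions list of [inversion_spec()] objects.
#' @param seed RNG seed; the same seed gives byte-identical output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_samples = c(WE = 347, WA = 212, SP = 185, WAm = 38),
                       n_snps = c(A = 11982, C = 18899),
                       fst = c(WE = 0.18, WA = 0.18, SP = 0.28, WAm = 0.20),
                       f_is = 0.9,
                       call_rate_mean = 0.35,
                       call_rate_disp = 1.5,
                       sample_rate_sd = 0.2,
                       depth_mean = 8, depth_size = 2,
                       maf_range = c(0.05, 0.95),
                       chrom_lengths = default_chrom_lengths(),
                       inversions = list(
                         inversion_spec("C02", 23325687, 32393406,
                                        freq = c(WE = 0.02, WA = 0.02,
                                                 SP = 0.5, WAm = 0.2))),
                       seed = 1L) {
  pops <- names(n_samples)
  if (is.null(pops) || any(!nzchar(pops)))
    stop("n_samples must be a named vector of subpopulation sizes")
  if (length(f_is) == 1L) f_is <- stats::setNames(rep(f_is, length(pops)), pops)
  stopifnot(all(pops %in% names(fst)), all(pops %in% names(f_is)),
            all(fst >= 0 & fst <= 1), all(f_is >= 0 & f_is <= 1),
            all(n_snps >= 1), call_rate_mean > 0, call_rate_mean <= 1,
            depth_mean > 0, depth_size > 0)
  for (inv in inversions) {
    stopifnot(inherits(inv, "inversion_spec"))
    if (!inv$chrom %in% names(chrom_lengths) ||
        inv$end > chrom_lengths[[inv$chrom]])
      stop("inversion interval outside chromosome bounds: ", inv$chrom)
    if (!all(pops %in% names(inv$freq)))
      stop("inversion spec must give a frequency for every subpopulation")
  }
  structure(list(n_samples = n_samples, n_snps = n_snps, fst = fst[pops],
                 f_is = f_is[pops], call_rate_mean = call_rate_mean,
                 call_rate_disp = call_rate_disp,
                 sample_rate_sd = sample_rate_sd, depth_mean = depth_mean,
                 depth_size = depth_size, maf_range = maf_range,
                 chrom_lengths = chrom_lengths, inversions = inversions,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# place SNPs uniformly along chromosomes, count per subgenome fixed
place_snps <- function(config) {
  lens <- config$chrom_lengths
  sg <- subgenome_of(names(lens))
  out <- list()
  for (g in c("A", "C")) {
    chroms <- names(lens)[sg == g]
    if (!length(chroms) || is.na(config$n_snps[g]) || config$n_snps[g] < 1)
      next
    share <- lens[chroms] / sum(lens[chroms])
    cnt <- stats::setNames(floor(config$n_snps[[g]] * share), chroms)
    rem <- config$n_snps[[g]] - sum(cnt)
    if (rem > 0) {
      add <- chroms[order(share, decreasing = TRUE)][seq_len(rem)]
      cnt[add] <- cnt[add] + 1L
    }
    for (ch in chroms) {
      pos <- sort(sample.int(lens[[ch]], cnt[[ch]]))
      out[[ch]] <- data.frame(chrom = ch, pos = pos)
    }
  }
  snps <- do.call(rbind, out)
  snps <- snps[genome_order(snps), , drop = FALSE]
  snps$id <- paste0(snps$chrom, "_", snps$pos)
  rownames(snps) <- NULL
  snps[, c("id", "chrom", "pos")]
}

# Balding-Nichols subpopulation frequency given ancestral p and F
bn_freq <- function(p, f) {
  if (f < 1e-12) return(p)
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

# genotypes for one subpopulation: with prob f_is the two alleles are IBD
draw_genotypes <- function(n, p, f_is) {
  s <- length(p)
  g <- matrix(stats::rbinom(n * s, 2L, rep(p, each = n)), n, s)
  if (f_is > 0) {
    ibd <- matrix(stats::runif(n * s) < f_is, n, s)
    hom <- matrix(2L * stats::rbinom(n * s, 1L, rep(p, each = n)), n, s)
    g[ibd] <- hom[ibd]
  }
  g
}

# overwrite dosages inside an inversion region; uses the current RNG stream
apply_inversion <- function(dosage, snps, subpop, spec) {
  in_region <- snps$chrom == spec$chrom &
    snps$pos >= spec$start & snps$pos <= spec$end
  s <- sum(in_region)
  if (s < 20L)
    stop("inversion interval contains ", s,
         " SNPs (< 20): pattern undetectable, refusing")
  h1 <- stats::rbinom(s, 1L, 0.5)
  flip <- stats::rbinom(s, 1L, spec$divergence) == 1L
  h2 <- ifelse(flip, 1L - h1, h1)
  n <- length(subpop)
  q <- spec$freq[subpop]
  q[is.na(q)] <- mean(spec$freq)
  inv_g <- stats::rbinom(n, 2L, q)
  # allele carried by each of the two chromosome copies: a sample with g
  # copies of the inverted haplotype carries (2 - g) h1 copies and g h2
  copy1 <- matrix(rep(h1, each = n), n, s)
  copy2 <- copy1
  i2 <- which(inv_g == 2L)
  i1 <- which(inv_g == 1L)
  if (length(i2)) {
    copy1[i2, ] <- rep(h2, each = length(i2))
    copy2[i2, ] <- rep(h2, each = length(i2))
  }
  if (length(i1)) copy2[i1, ] <- rep(h2, each = length(i1))
  if (spec$noise > 0) {
    f1 <- matrix(stats::runif(n * s) < spec$noise, n, s)
    f2 <- matrix(stats::runif(n * s) < spec$noise, n, s)
    copy1[f1] <- 1L - copy1[f1]
    copy2[f2] <- 1L - copy2[f2]
  }
  dosage[, in_region] <- copy1 + copy2
  list(dosage = dosage,
       truth = list(spec = spec, snp_ids = snps$id[in_region],
                    h1 = h1, h2 = h2, inv_genotype = inv_g))
}

#' Simulate a genotype matrix
#'
#' Ancestral allele frequencies are uniform on `maf_range`; each
#' subpopulation's frequency is a Balding-Nichols draw with its configured F;
#' genotypes are drawn with inbreeding excess homozygosity
#' (`P(het) = 2p(1-p)(1-F_is)`); inversion regions override the site-wise
#' draw; missingness is applied last. Deterministic under a fixed seed.
#'
#' @param config a [sim_config()] object.
#' @return a `geno_matrix` with a `truth` attribute (ancestral and
#'   subpopulation frequencies, inversion haplotypes and genotypes).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  snps <- place_snps(config)
  s <- nrow(snps)
  pops <- names(config$n_samples)
  p_anc <- stats::runif(s, config$maf_range[1], config$maf_range[2])
  p_sub <- sapply(pops, function(k) bn_freq(p_anc, config$fst[[k]]))
  subpop <- rep(pops, config$n_samples)
  n <- length(subpop)
  dosage <- matrix(NA_integer_, n, s)
  for (k in pops) {
    rows <- which(subpop == k)
    dosage[rows, ] <- draw_genotypes(length(rows), p_sub[, k],
                                     config$f_is[[k]])
  }
  inv_truth <- list()
  for (inv in config$inversions) {
    res <- apply_inversion(dosage, snps, subpop, inv)
    dosage <- res$dosage
    inv_truth[[length(inv_truth) + 1L]] <- res$truth
  }
  if (config$call_rate_mean < 1) {
    mu <- config$call_rate_mean; t <- config$call_rate_disp
    r_snp <- stats::rbeta(s, mu * t, (1 - mu) * t)
    s_mult <- exp(stats::rnorm(n, 0, config$sample_rate_sd))
    pcall <- pmin(outer(s_mult, r_snp), 1)
    dosage[matrix(stats::runif(n * s), n, s) > pcall] <- NA_integer_
    empty <- which(colSums(!is.na(dosage)) == 0L)
    for (j in empty) {
      i <- sample.int(n, 1L)
      dosage[i, j] <- stats::rbinom(1L, 2L, p_sub[j, subpop[i]])
    }
  }
  geo <- c(WE = "Europe", WA = "Asia", WAm = "America")[subpop]
  sp_rows <- subpop == "SP"
  if (any(sp_rows))
    geo[sp_rows] <- sample(c("Europe", "Asia", "America"), sum(sp_rows),
                           replace = TRUE, prob = c(47, 26, 112))
  samples <- data.frame(
    id = sprintf("S%04d", seq_len(n)),
    growth_habit = ifelse(subpop == "SP", "spring", "winter"),
    geography = geo, subpop = subpop, stringsAsFactors = FALSE)
  gm <- genotype_matrix(dosage, snps, samples)
  attr(gm, "truth") <- list(p_anc = p_anc, p_sub = p_sub,
                            inversions = inv_truth)
  gm
}

#' Plant an inversion region into an existing genotype matrix
#'
#' Two fixed haplotype allele vectors (differing at each SNP with probability
#' `divergence`) define the region's alleles; each sample carries 0/1/2
#' copies of the inverted haplotype per its subpopulation's frequency;
#' heterozygous carriers are heterozygous at differing sites; a small
#' per-copy noise flips calls. The pre-existing missingness pattern is
#' preserved.
#'
#' @param gm a `geno_matrix` with subpopulation labels.
#' @param spec an [inversion_spec()].
#' @param seed optional RNG seed.
#' @return the modified `geno_matrix`; inversion truth is appended to the
#'   `truth` attribute.
#' @export
simulate_inversion <- function(gm, spec, seed = NULL) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(spec, "inversion_spec"))
  if (!is.null(seed)) set.seed(seed)
  was_na <- is.na(gm$dosage)
  res <- apply_inversion(gm$dosage, gm$snps, gm$samples$subpop, spec)
  dos <- res$dosage
  dos[was_na] <- NA_integer_
  truth <- attr(gm, "truth")
  gm$dosage <- dos
  truth$inversions <- c(truth$inversions, list(res$truth))
  attr(gm, "truth") <- truth
  gm
}
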