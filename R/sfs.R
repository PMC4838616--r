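# Folded site-frequency spectra by hypergeometric projection to a fixed
# chromosome count, and the diversity statistics computed from them
# (pi, per-SNP average pairwise mismatch, Tajima's D).

#' Hypergeometric projection of one SNP's allele count
#'
#' Probability mass of drawing k copies of an allele in `m` draws without
#' replacement from `m_obs` observed chromosomes carrying `j` copies,
#' folded so k and m-k share a class (the fold boundary k = m/2 is counted
#' once). Masses sum to 1.
#'
#' @param j allele copies among the observed chromosomes.
#' @param m_obs observed chromosome count (must be >= `m`).
#' @param m projection size in chromosomes (default 100).
#' @return numeric vector of length `m/2 + 1`, named "0".."m/2" (minor
#'   allele count classes).
#' @export
project_snp <- function(j, m_obs, m = 100) {
  if (m_obs < m)
    stop("cannot project ", m_obs, " observed chromosomes up to ", m)
  stopifnot(j >= 0, j <= m_obs)
  k <- 0:m
  mass <- stats::dhyper(k, j, m_obs - j, m)
  fold_mass(mass, m)
}

# fold an unfolded mass/count vector over k = 0..m onto k = 0..m/2
fold_mass <- function(mass, m) {
  half <- floor(m / 2)
  out <- numeric(half + 1)
  for (k in 0:half) {
    kk <- m - k
    out[k + 1] <- if (kk == k) mass[k + 1] else mass[k + 1] + mass[kk + 1]
  }
  names(out) <- 0:half
  out
}

#' Build the projected folded SFS of a subpopulation
#'
#' Each SNP's alternate-allele count (heterozygote = 1 copy of each allele;
#' missing genotypes excluded from the observed chromosome count) is
#' projected to `m` chromosomes and folded; per-SNP masses are summed.
#' SNPs with fewer than `m` called chromosomes cannot be downsampled and
#' are excluded (tallied). Mass at k = 0 (projected monomorphic) is kept
#' separate from the segregating mass.
#'
#' @param gm a `geno_matrix`.
#' @param subpop subpopulation label (must have >= m/2 samples).
#' @param subgenome "A", "C" or NULL for both.
#' @param m projection size in chromosomes (default 100 = 50 diploids).
#' @return object of class `folded_sfs`: `m`, `mass` (expected SNP count
#'   per minor-allele count class 0..m/2), `n_input_snps`, `n_excluded`,
#'   `n_projected`, `monomorphic_mass`.
#' @export
build_folded_sfs <- function(gm, subpop, subgenome = NULL, m = 100) {
  rows <- subpop_idx(gm, subpop)
  if (length(rows) < m / 2)
    stop("subpopulation ", subpop, " has ", length(rows),
         " samples; need at least m/2 = ", m / 2)
  idx <- seq_len(n_snps(gm))
  if (!is.null(subgenome)) idx <- idx[gm$snps$subgenome[idx] %in% subgenome]
  dos <- gm$dosage[rows, idx, drop = FALSE]
  called <- colSums(!is.na(dos))
  j <- colSums(dos, na.rm = TRUE)
  m_obs <- 2L * called
  ok <- m_obs >= m
  if (!any(ok))
    stop("all ", length(idx), " SNPs have fewer than ", m,
         " called chromosomes; nothing to project")
  half <- floor(m / 2)
  mass <- numeric(half + 1)
  key <- paste(j[ok], m_obs[ok])
  tab <- table(key)
  for (u in names(tab)) {
    jm <- as.integer(strsplit(u, " ", fixed = TRUE)[[1]])
    mass <- mass + tab[[u]] * project_snp(jm[1], jm[2], m)
  }
  names(mass) <- 0:half
  structure(list(m = m, mass = mass, n_input_snps = length(idx),
                 n_excluded = sum(!ok), n_projected = sum(ok),
                 monomorphic_mass = mass[[1]]),
            class = "folded_sfs")
}

#' @export
print.folded_sfs <- function(x, ...) {
  cat(sprintf(
    "folded_sfs: m = %d; %d SNPs projected (%d excluded), %.1f segregating mass\n",
    x$m, x$n_projected, x$n_excluded, sum(x$mass[-1])))
  invisible(x)
}

#' SNP density of a subgenome
#'
#' Number of SNPs divided by the base pairs they cover, computed on all
#' SNPs before any projection exclusion.
#'
#' @param gm a `geno_matrix`.
#' @param subgenome "A" or "C".
#' @param covered_bp base pairs of reference covered by the reads carrying
#'   these SNPs; defaults to the summed chromosome spans of the SNPs.
#' @return SNPs per bp.
#' @export
snp_density <- function(gm, subgenome, covered_bp = NULL) {
  idx <- gm$snps$subgenome == subgenome
  if (is.null(covered_bp)) {
    sp <- split(gm$snps$pos[idx], gm$snps$chrom[idx])
    covered_bp <- sum(vapply(sp, function(p) diff(range(p)) + 1, 0))
  }
  sum(idx) / covered_bp
}

#' Nucleotide diversity from a projected folded SFS
#'
#' Per-site diversity at minor-allele count k of m chromosomes is
#' 2k(m-k)/(m(m-1)); the SFS-weighted sum gives the total average pairwise
#' mismatch, and pi divides it by the effective sequence length
#' L = (projected SNP count) / (SNP density). For a single SNP (L = 1) pi
#' equals the per-SNP mismatch Pi. Doubling the density halves pi exactly.
#'
#' @param sfs a `folded_sfs`.
#' @param density SNPs per bp (see [snp_density()]).
#' @return list: `pi` (per bp), `L` (bp), `pi_total` (summed per-SNP
#'   diversity), `S` (segregating mass), `m`.
#' @export
pi_from_sfs <- function(sfs, density) {
  stopifnot(inherits(sfs, "folded_sfs"), density > 0)
  m <- sfs$m
  k <- as.integer(names(sfs$mass))
  persite <- 2 * k * (m - k) / (m * (m - 1))
  pi_total <- sum(sfs$mass * persite)
  L <- sfs$n_projected / density
  if (L <= 0) stop("zero effective sequence length")
  list(pi = pi_total / L, L = L, pi_total = pi_total,
       S = sum(sfs$mass[-1]), m = m)
}

#' Per-SNP average pairwise mismatch (Pi)
#'
#' With c0 reference and c1 alternate chromosomes among called genotypes at
#' a SNP, Pi = c0 * c1 / choose(c0 + c1, 2): the fraction of all chromosome
#' pairs that differ. SNPs with fewer than 2 called genotypes are NA.
#'
#' @param gm a `geno_matrix`.
#' @param subpop subpopulation label, or NULL for all samples.
#' @return numeric vector (one value per SNP, in the matrix's SNP order).
#' @export
big_pi_per_snp <- function(gm, subpop = NULL) {
  rows <- if (is.null(subpop)) seq_len(n_samples(gm)) else
    subpop_idx(gm, subpop)
  dos <- gm$dosage[rows, , drop = FALSE]
  called <- colSums(!is.na(dos))
  c1 <- colSums(dos, na.rm = TRUE)
  tot <- 2 * called
  c0 <- tot - c1
  out <- ifelse(called >= 2L, c0 * c1 / (tot * (tot - 1) / 2), NA_real_)
  stats::setNames(out, gm$snps$id)
}

# standard Tajima constants for sample size n chromosomes
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D from a projected folded SFS
#'
#' S is the segregating mass (k >= 1); the pairwise estimator is the
#' SFS-weighted sum of 2k(m-k)/(m(m-1)) (fold-invariant); D standardizes
#' their difference with the classical constants evaluated at n = m
#' chromosomes. Fractional (expected) masses are used directly. S = 0 gives
#' an NA result, reported as such.
#'
#' @param sfs a `folded_sfs`, or a numeric mass vector over minor-allele
#'   counts 0..m/2 together with `m`.
#' @param m projection size when `sfs` is a bare vector.
#' @return list: `D`, `S`, `pi_hat`, `theta_w`.
#' @export
tajimas_d <- function(sfs, m = NULL) {
  if (inherits(sfs, "folded_sfs")) {
    mass <- sfs$mass
    m <- sfs$m
  } else {
    mass <- sfs
    if (is.null(m)) stop("supply m when passing a bare mass vector")
    if (is.null(names(mass))) names(mass) <- seq_along(mass) - 1
  }
  k <- as.integer(names(mass))
  seg <- k >= 1L
  S <- sum(mass[seg])
  if (S <= 0) return(list(D = NA_real_, S = 0, pi_hat = 0, theta_w = 0))
  pi_hat <- sum(mass[seg] * 2 * k[seg] * (m - k[seg]) / (m * (m - 1)))
  cc <- tajima_constants(m)
  theta_w <- S / cc$a1
  denom <- sqrt(cc$e1 * S + cc$e2 * S * (S - 1))
  list(D = (pi_hat - theta_w) / denom, S = S, pi_hat = pi_hat,
       theta_w = theta_w)
}

#' Per-SNP heterozygosity and call-rate tracks
#'
#' For each SNP within a subpopulation: the proportion of heterozygous
#' genotypes among called samples, and the call rate (called / total
#' samples in the subpopulation). Genome order.
#'
#' @param gm a `geno_matrix`.
#' @param subpop subpopulation label, or NULL for all samples.
#' @return data.frame: id, chrom, pos, het_prop, call_rate.
#' @export
snp_tracks <- function(gm, subpop = NULL) {
  rows <- if (is.null(subpop)) seq_len(n_samples(gm)) else
    subpop_idx(gm, subpop)
  dos <- gm$dosage[rows, , drop = FALSE]
  called <- colSums(!is.na(dos))
  het <- colSums(dos == 1L, na.rm = TRUE)
  ord <- genome_order(gm$snps)
  data.frame(id = gm$snps$id, chrom = gm$snps$chrom, pos = gm$snps$pos,
             het_prop = ifelse(called > 0, het / called, NA_real_),
             call_rate = called / length(rows),
             stringsAsFactors = FALSE)[ord, , drop = FALSE]
}
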