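# Raw-VCF emission: dresses a simulated genotype matrix in read-level
# clothing (DP, AD, MM) and optionally plants records/genotypes that the
# filter cascade must remove, with exact truth bookkeeping for tests.

ACGT <- c("A", "C", "G", "T")

# negative-binomial draws conditioned on >= 4 (called genotypes)
rnb_ge4 <- function(n, mu, size) {
  x <- stats::rnbinom(n, size = size, mu = mu)
  while (any(low <- x < 4L))
    x[low] <- stats::rnbinom(sum(low), size = size, mu = mu)
  x
}

# draws conditioned on < 4 (genotypes that failed to be called)
rnb_lt4 <- function(n, mu, size) {
  p <- stats::dnbinom(0:3, size = size, mu = mu)
  sample(0:3, n, replace = TRUE, prob = p / sum(p))
}

# balanced het allele depths: minor-read fraction >= 0.25 where depth
# permits (DP >= 4); lower depths (injected low-depth cells that the mask
# stage removes anyway) take an unconstrained binomial split
r_het_ad <- function(dp) {
  alt <- ifelse(dp > 0, stats::rbinom(length(dp), pmax(dp, 0), 0.5), 0L)
  repeat {
    frac <- ifelse(dp > 0, pmin(alt, dp - alt) / dp, 1)
    bad <- dp >= 4 & frac < 0.25
    if (!any(bad)) break
    alt[bad] <- stats::rbinom(sum(bad), dp[bad], 0.5)
  }
  as.integer(alt)
}

#' Emit a raw VCF from a simulated genotype matrix
#'
#' Writes a VCF with per-genotype read depth (negative binomial, coupled to
#' the call/missing state: called genotypes have DP >= 4, missing ones
#' DP < 4), allele depths consistent with the genotype plus error reads, a
#' per-genotype MM mismatch count, and — at configurable exact counts —
#' planted violations for every stage of the filter cascade: indel records,
#' triallelic records, fixed-alternate records, low-depth called genotypes,
#' strongly imbalanced heterozygotes, and genotypes with > 3 sample-specific
#' mismatches.
#'
#' @param gm a `geno_matrix` (typically from [simulate_genotypes()]).
#' @param config the [sim_config()] providing the depth model.
#' @param path output VCF path.
#' @param inject named list of exact injection counts: `n_indel`,
#'   `n_triallelic`, `n_fixed_alt`, `n_low_depth`, `n_imbalanced_het`,
#'   `n_high_mismatch` (all default 0).
#' @param seed RNG seed (defaults to `config$seed + 1000`).
#' @return invisibly, the truth bookkeeping: data.frame `sites` (chrom, pos,
#'   class) for injected records and index matrices for injected genotypes.
#' @export
emit_raw_vcf <- function(gm, config, path, inject = list(),
                         seed = config$seed + 1000L) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(config, "sim_config"))
  inj <- utils::modifyList(
    list(n_indel = 0L, n_triallelic = 0L, n_fixed_alt = 0L,
         n_low_depth = 0L, n_imbalanced_het = 0L, n_high_mismatch = 0L),
    inject)
  set.seed(seed)
  n <- n_samples(gm); s <- n_snps(gm)
  dos <- gm$dosage
  called <- !is.na(dos)
  mu <- config$depth_mean; size <- config$depth_size

  dp <- matrix(NA_integer_, n, s)
  dp[called] <- rnb_ge4(sum(called), mu, size)
  dp[!called] <- rnb_lt4(sum(!called), mu, size)

  cells <- function(k, pool) {
    if (k == 0L) return(integer())
    if (length(pool) < k)
      stop("not enough genotypes available to inject ", k, " violations")
    sample(pool, k)
  }
  pool <- which(called)
  low_cells <- cells(inj$n_low_depth, pool)
  pool <- setdiff(pool, low_cells)
  imb_cells <- cells(inj$n_imbalanced_het, intersect(pool, which(dos == 1L)))
  pool <- setdiff(pool, imb_cells)
  mm_cells <- cells(inj$n_high_mismatch, pool)

  dp[low_cells] <- sample(0:3, length(low_cells), replace = TRUE,
                          prob = stats::dnbinom(0:3, size = size, mu = mu) + 1e-9)
  dp[imb_cells] <- pmax(dp[imb_cells], 10L)

  alt_reads <- matrix(0L, n, s)
  i_hom_ref <- which(called & dos == 0L)
  i_het <- which(called & dos == 1L)
  i_hom_alt <- which(called & dos == 2L)
  alt_reads[i_hom_ref] <- stats::rbinom(length(i_hom_ref), dp[i_hom_ref], 0.01)
  alt_reads[i_hom_alt] <- dp[i_hom_alt] -
    stats::rbinom(length(i_hom_alt), dp[i_hom_alt], 0.01)
  alt_reads[i_het] <- r_het_ad(dp[i_het])
  # imbalanced hets: minor allele gets a single read
  if (length(imb_cells)) {
    to_alt <- stats::runif(length(imb_cells)) < 0.5
    alt_reads[imb_cells[to_alt]] <- 1L
    alt_reads[imb_cells[!to_alt]] <- dp[imb_cells[!to_alt]] - 1L
  }
  mm <- matrix(stats::rbinom(n * s, 3L, 0.05), n, s)
  mm[mm_cells] <- sample(4:6, length(mm_cells), replace = TRUE)

  ref <- sample(ACGT, s, replace = TRUE)
  alt <- ACGT[(match(ref, ACGT) + sample(1:3, s, replace = TRUE) - 1L) %% 4L + 1L]

  base_rec <- lapply(seq_len(s), function(j) {
    g <- dos[, j]
    gt <- rbind(ifelse(is.na(g), NA_integer_, as.integer(g == 2L)),
                ifelse(is.na(g), NA_integer_, as.integer(g >= 1L)))
    ad <- lapply(seq_len(n), function(i) {
      if (is.na(g[i])) return(c(0L, 0L))
      c(dp[i, j] - alt_reads[i, j], alt_reads[i, j])
    })
    list(chrom = gm$snps$chrom[j], pos = gm$snps$pos[j], ref = ref[j],
         alts = alt[j], gt = gt, ad = ad, dp = dp[, j], mm = mm[, j])
  })

  # ---- injected whole records ------------------------------------------
  used <- paste(gm$snps$chrom, gm$snps$pos)
  rand_site <- function() {
    repeat {
      ch <- sample(names(config$chrom_lengths), 1L)
      p <- sample.int(config$chrom_lengths[[ch]], 1L)
      if (!paste(ch, p) %in% used) {
        used <<- c(used, paste(ch, p))
        return(list(chrom = ch, pos = p))
      }
    }
  }
  inj_genotype_fields <- function(g, n_alleles = 2L) {
    ok <- !is.na(g)
    dpv <- rep(NA_integer_, n)
    dpv[ok] <- rnb_ge4(sum(ok), mu, size)
    dpv[!ok] <- rnb_lt4(sum(!ok), mu, size)
    gt <- matrix(NA_integer_, 2L, n)
    gt[1, ok] <- as.integer(g[ok] == 2L)
    gt[2, ok] <- as.integer(g[ok] >= 1L)
    ad <- lapply(seq_len(n), function(i) {
      v <- integer(n_alleles)
      if (!ok[i]) return(v)
      a <- stats::rbinom(1L, dpv[i], 0.01)
      if (g[i] == 0L) { v[1] <- dpv[i] - a; v[2] <- a }
      else if (g[i] == 2L) { v[1] <- a; v[2] <- dpv[i] - a }
      else { v[2] <- r_het_ad(dpv[i]); v[1] <- dpv[i] - v[2] }
      v
    })
    list(gt = gt, ad = ad, dp = dpv,
         mm = stats::rbinom(n, 3L, 0.05))
  }
  inj_rec <- list(); inj_class <- character(); inj_chrom <- character()
  inj_pos <- integer()
  add_inj <- function(rec, cls) {
    inj_rec[[length(inj_rec) + 1L]] <<- rec
    inj_class[length(inj_class) + 1L] <<- cls
    inj_chrom[length(inj_chrom) + 1L] <<- rec$chrom
    inj_pos[length(inj_pos) + 1L] <<- rec$pos
  }
  for (i in seq_len(inj$n_indel)) {
    st <- rand_site()
    g <- stats::rbinom(n, 2L, 0.3)
    g[stats::runif(n) > 0.8] <- NA_integer_
    f <- inj_genotype_fields(g)
    add_inj(c(st, list(ref = "AT", alts = "A"), f), "indel")
  }
  for (i in seq_len(inj$n_triallelic)) {
    st <- rand_site()
    a1 <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    a2 <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    keep <- stats::runif(n) <= 0.8
    gt <- rbind(pmin(a1, a2), pmax(a1, a2))
    gt[, !keep] <- NA_integer_
    dpv <- rep(NA_integer_, n); dpv[keep] <- rnb_ge4(sum(keep), mu, size)
    dpv[!keep] <- rnb_lt4(sum(!keep), mu, size)
    ad <- lapply(seq_len(n), function(i) {
      v <- integer(3)
      if (!keep[i]) return(v)
      half <- dpv[i] %/% 2L
      v[gt[1, i] + 1L] <- v[gt[1, i] + 1L] + half
      v[gt[2, i] + 1L] <- v[gt[2, i] + 1L] + dpv[i] - half
      v
    })
    add_inj(c(st, list(ref = "A", alts = c("C", "G"), gt = gt, ad = ad,
                       dp = dpv, mm = stats::rbinom(n, 3L, 0.05))),
            "triallelic")
  }
  for (i in seq_len(inj$n_fixed_alt)) {
    st <- rand_site()
    g <- rep(2L, n)
    g[stats::runif(n) > 0.8] <- NA_integer_
    if (all(is.na(g))) g[1] <- 2L
    f <- inj_genotype_fields(g)
    add_inj(c(st, list(ref = "A", alts = "G"), f), "fixed_alt")
  }

  records <- c(base_rec, inj_rec)
  ord <- order(match(vapply(records, `[[`, "", "chrom"),
                     chrom_order(vapply(records, `[[`, "", "chrom"))),
               vapply(records, `[[`, 0L, "pos"))
  vr <- structure(list(samples = gm$samples$id, records = records[ord]),
                  class = "variant_records")
  write_vcf(vr, path)
  arr <- function(idx) if (!length(idx)) NULL else
    cbind(sample = row(dos)[idx], snp = col(dos)[idx])
  invisible(list(
    sites = data.frame(chrom = inj_chrom, pos = inj_pos, class = inj_class,
                       stringsAsFactors = FALSE),
    low_depth = arr(low_cells), imbalanced_het = arr(imb_cells),
    high_mismatch = arr(mm_cells)))
}
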