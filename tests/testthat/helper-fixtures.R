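# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; no binary fixtures.

# small simulation config with quiet defaults (no inversion, no missingness)
quick_cfg <- function(n_samples = c(WE = 40, WA = 40, SP = 40),
                      n_snps = c(A = 200, C = 300),
                      fst = c(WE = 0.2, WA = 0.2, SP = 0.2, WAm = 0.2),
                      f_is = 0, call_rate_mean = 1, inversions = list(),
                      seed = 1, ...) {
  sim_config(n_samples = n_samples, n_snps = n_snps, fst = fst,
             f_is = f_is, call_rate_mean = call_rate_mean,
             inversions = inversions, seed = seed, ...)
}

# hand-built geno_matrix from a dosage matrix (rows = samples)
toy_gm <- function(dosage, chrom = NULL, pos = NULL, subpop = NULL) {
  n <- nrow(dosage); s <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("A01", s)
  if (is.null(pos)) pos <- seq_len(s) * 1000L
  snps <- data.frame(id = paste0(chrom, "_", pos), chrom = chrom, pos = pos)
  samples <- data.frame(id = sprintf("s%02d", seq_len(n)),
                        subpop = if (is.null(subpop)) rep(NA_character_, n)
                        else subpop)
  genotype_matrix(dosage, snps, samples)
}

# literal VCF text fixture writer: body rows are lists with chrom, pos,
# ref, alt, and per-sample GT:AD:DP(:MM) strings
write_vcf_text <- function(rows, samples, path, fmt = "GT:AD:DP") {
  hdr <- c("##fileformat=VCFv4.2",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(rows, function(r)
    paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", ".",
            if (is.null(r$fmt)) fmt else r$fmt, r$cells), collapse = "\t"),
    "")
  writeLines(c(hdr, body), path)
  path
}

# GFF3 fixture writer from a gene data.frame (gene_id, chrom, start, end)
write_gff_text <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\ttest\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                     genes$chrom, genes$start, genes$end, genes$gene_id))
  writeLines(lines, path)
  path
}

# independent neutral-coalescent folded SFS simulator (Kingman tree with
# Poisson mutations; used only as an oracle for Tajima's D calibration)
coalescent_folded_sfs <- function(n, theta) {
  counts <- rep(1L, n)
  len <- numeric(n - 1)
  k <- n
  while (k > 1L) {
    t <- stats::rexp(1, k * (k - 1) / 2)
    len <- len + t * tabulate(counts, nbins = n - 1)
    pair <- sample.int(k, 2L)
    counts[pair[1]] <- counts[pair[1]] + counts[pair[2]]
    counts <- counts[-pair[2]]
    k <- k - 1L
  }
  xi <- stats::rpois(n - 1, theta / 2 * len)
  half <- floor(n / 2)
  eta <- numeric(half + 1)
  for (i in seq_len(n - 1)) {
    kk <- min(i, n - i)
    eta[kk + 1] <- eta[kk + 1] + xi[i]
  }
  names(eta) <- 0:half
  eta
}

# the exact neutral-expectation folded SFS shape at m chromosomes
neutral_folded_shape <- function(m, theta = 1) {
  half <- floor(m / 2)
  mass <- numeric(half + 1)
  for (k in seq_len(half))
    mass[k + 1] <- if (m - k == k) theta / k else theta / k + theta / (m - k)
  names(mass) <- 0:half
  mass
}

# brute-force O(n^2) all-pairs mismatch fraction at one SNP
brute_big_pi <- function(geno) {
  g <- geno[!is.na(geno)]
  if (length(g) < 2) return(NA_real_)
  chroms <- unlist(lapply(g, function(x) switch(x + 1L, c(0, 0), c(0, 1),
                                                c(1, 1))))
  pairs <- utils::combn(length(chroms), 2)
  mean(chroms[pairs[1, ]] != chroms[pairs[2, ]])
}

# brute-force weighted p-distance for two samples
brute_wpd <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (!sum(ok)) return(NA_real_)
  mean(abs(g1[ok] / 2 - g2[ok] / 2))
}

# brute-force gap merge of flagged positions on one ordering
brute_merge <- function(chrom, pos, flagged, max_gap, min_snps) {
  d <- data.frame(chrom = chrom[flagged], pos = pos[flagged])
  d <- d[order(match(d$chrom, chrom_order(d$chrom)), d$pos), ]
  out <- list()
  i <- 1
  while (i <= nrow(d)) {
    j <- i
    while (j < nrow(d) && d$chrom[j + 1] == d$chrom[j] &&
           d$pos[j + 1] - d$pos[j] <= max_gap) j <- j + 1
    if (j - i + 1 >= min_snps)
      out[[length(out) + 1]] <- data.frame(chrom = d$chrom[i],
                                           start = d$pos[i],
                                           end = d$pos[j],
                                           n_snps = j - i + 1)
    i <- j + 1
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}
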