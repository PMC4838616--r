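test_that("same seed gives identical output; different seed differs", {
  cfg <- quick_cfg(n_samples = c(WE = 10, SP = 10),
                   fst = c(WE = 0.1, SP = 0.1),
                   n_snps = c(A = 50, C = 80), f_is = 0.5,
                   call_rate_mean = 0.5, seed = 9)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  cfg2 <- quick_cfg(n_samples = c(WE = 10, SP = 10),
                    fst = c(WE = 0.1, SP = 0.1),
                    n_snps = c(A = 50, C = 80), f_is = 0.5,
                    call_rate_mean = 0.5, seed = 10)
  expect_false(identical(simulate_genotypes(cfg2)$dosage, g1$dosage))
})

test_that("panmixia: target Fst 0 gives realized Hudson Fst within 0.01", {
  cfg <- quick_cfg(n_samples = c(WE = 100, SP = 100),
                   fst = c(WE = 0, SP = 0),
                   n_snps = c(A = 8000, C = 12000), seed = 21)
  gm <- simulate_genotypes(cfg)
  f <- genomewide_fst(gm, c("WE", "SP"), inbreeding_adjust = FALSE)
  expect_lt(abs(f$fst), 0.01)
})

test_that("Balding-Nichols recovery at F = 0.2 agrees with a per-SNP oracle", {
  cfg <- quick_cfg(n_samples = c(WE = 200, SP = 200),
                   fst = c(WE = 0.2, SP = 0.2),
                   n_snps = c(A = 2000, C = 3000), seed = 31)
  gm <- simulate_genotypes(cfg)
  f <- genomewide_fst(gm, c("WE", "SP"), inbreeding_adjust = FALSE)
  expect_lt(abs(f$fst - 0.2), 0.02)
  # independent arithmetic oracle: per-SNP components from raw counts
  w <- gm$dosage[gm$samples$subpop == "WE", ]
  s <- gm$dosage[gm$samples$subpop == "SP", ]
  p1 <- colMeans(w) / 2; p2 <- colMeans(s) / 2
  n1 <- 2 * nrow(w); n2 <- 2 * nrow(s)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- p1 > 0 & p1 < 1   # ascertained in WE (default)
  expect_equal(f$fst, sum(num[keep]) / sum(den[keep]), tolerance = 1e-12)
})

test_that("F_is = 1 yields zero heterozygous calls; P(het) recovered at 10k SNPs", {
  cfg <- quick_cfg(n_samples = c(WE = 50), fst = c(WE = 0),
                   n_snps = c(A = 500, C = 500), f_is = 1, seed = 4)
  gm <- simulate_genotypes(cfg)
  expect_equal(sum(gm$dosage == 1L, na.rm = TRUE), 0L)
  cfg2 <- quick_cfg(n_samples = c(WE = 40), fst = c(WE = 0),
                    n_snps = c(A = 4000, C = 6000), f_is = 0.6, seed = 5)
  gm2 <- simulate_genotypes(cfg2)
  p <- attr(gm2, "truth")$p_anc
  expected_het <- mean(2 * p * (1 - p) * (1 - 0.6))
  expect_lt(abs(mean(gm2$dosage == 1L) - expected_het), 0.01)
})

test_that("realized per-sample missingness is within 3 binomial SD of target", {
  cfg <- quick_cfg(n_samples = c(WE = 30), fst = c(WE = 0),
                   n_snps = c(A = 2000, C = 3000),
                   call_rate_mean = 0.4, seed = 6)
  cfg$call_rate_disp <- 200   # near-constant per-SNP rate
  cfg$sample_rate_sd <- 0
  gm <- simulate_genotypes(cfg)
  cr <- rowMeans(!is.na(gm$dosage))
  sd3 <- 3 * sqrt(0.4 * 0.6 / n_snps(gm))
  expect_true(all(abs(cr - 0.4) <= sd3 + 0.01))
})

test_that("inversion at frequency 0 leaves the genome scan silent", {
  cfg <- quick_cfg(n_samples = c(WE = 50, SP = 50),
                   fst = c(WE = 0.05, SP = 0.05),
                   n_snps = c(A = 1000, C = 1500),
                   inversions = list(inversion_spec(
                     "C02", 1e6, 2e7, freq = c(WE = 0, WA = 0, SP = 0,
                                               WAm = 0))),
                   seed = 13)
  gm <- simulate_genotypes(cfg)
  track <- per_snp_fst_track(gm, c("WE", "SP"))
  sc <- roi_scan(gm, track)
  expect_equal(nrow(sc$regions), 0L)
})

test_that("inversion needs >= 20 SNPs in the interval", {
  cfg <- quick_cfg(n_samples = c(WE = 20), fst = c(WE = 0.1),
                   n_snps = c(A = 100, C = 100), seed = 2)
  gm <- simulate_genotypes(cfg)
  expect_error(
    simulate_inversion(gm, inversion_spec("C01", 1, 1000,
                                          freq = c(WE = 0.5)), seed = 1),
    "< 20")
})

test_that("spring-only inversion depletes the heterozygote band in winter groups", {
  cfg <- quick_cfg(
    n_samples = c(WE = 50, WA = 50, SP = 50),
    fst = c(WE = 0.15, WA = 0.15, SP = 0.15),
    n_snps = c(A = 500, C = 800),
    inversions = list(inversion_spec(
      "C02", 1e6, 2.8e7, freq = c(WE = 0.02, WA = 0.02, SP = 0.5,
                                  WAm = 0.2))),
    seed = 17)
  gm <- simulate_genotypes(cfg)
  bd <- region_pca_banding(gm, "C02", 1e6, 2.8e7)
  expect_equal(bd$diagnosis, "three-band")
  occ <- bd$occupancy
  # middle band (heterozygous carriers) dominated by SP, depleted in winter
  expect_gt(occ["SP", 2], occ["WE", 2] + occ["WA", 2])
  # the outer band holding the inverted homozygotes (the one with fewer
  # winter samples; PC1 orientation is arbitrary) is SP-dominated
  winter <- occ["WE", ] + occ["WA", ]
  b_inv <- if (winter[1] < winter[3]) 1 else 3
  expect_lt(winter[b_inv], occ["SP", b_inv])
})

test_that("emit_raw_vcf plants exact numbers of removable violations", {
  cfg <- quick_cfg(n_samples = c(WE = 25, SP = 25),
                   fst = c(WE = 0.1, SP = 0.1),
                   n_snps = c(A = 400, C = 600),
                   maf_range = c(0.3, 0.7), seed = 23)
  gm <- simulate_genotypes(cfg)
  p <- withr::local_tempfile(fileext = ".vcf")
  truth <- emit_raw_vcf(gm, cfg, p,
                        inject = list(n_indel = 37, n_triallelic = 12,
                                      n_fixed_alt = 50))
  vr <- read_vcf(p)
  expect_length(vr$records, 1099)
  s1 <- remove_nonbiallelic(vr)
  expect_equal(s1$report$removed, 99)
  expect_equal(length(s1$records$records), 1000)
  detail <- attr(s1$report, "detail")
  expect_equal(as.integer(detail[c("indel", "multiallelic", "fixed_alt")]),
               c(37L, 12L, 50L))
  expect_equal(nrow(truth$sites), 99L)
})

test_that("with no injections the cascade removes nothing but call-rate chance", {
  cfg <- quick_cfg(n_samples = c(WE = 25, SP = 25),
                   fst = c(WE = 0.1, SP = 0.1),
                   n_snps = c(A = 150, C = 250),
                   maf_range = c(0.3, 0.7), seed = 29)
  gm <- simulate_genotypes(cfg)
  p <- withr::local_tempfile(fileext = ".vcf")
  emit_raw_vcf(gm, cfg, p)
  fc <- filter_cascade(read_vcf(p), filter_config(min_samples_called = 1),
                       sample_meta = gm$samples)
  expect_equal(fc$report$removed, rep(0L, 6))
  expect_equal(unname(fc$matrix$dosage), unname(gm$dosage))
})
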