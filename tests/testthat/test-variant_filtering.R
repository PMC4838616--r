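# boundary-case records as literal VCF text: DP and AD chosen so each
# stage's strict/inclusive boundary is exercised exactly once
boundary_vcf <- function(path) {
  rows <- list(
    # DP = 4 kept, DP = 3 masked
    list(chrom = "A01", pos = 100, ref = "A", alt = "G", fmt = "GT:AD:DP:MM",
         cells = c("0/1:2,2:4:0", "0/1:2,1:3:0", "0/0:5,0:9:0")),
    # het AD 9,1 (0.1 < 0.2) recoded to hom-ref; AD 6,4 unchanged
    list(chrom = "A01", pos = 200, ref = "C", alt = "T", fmt = "GT:AD:DP:MM",
         cells = c("0/1:9,1:10:0", "0/1:6,4:10:0", "1/1:0,8:8:0")),
    # MM = 3 kept, MM = 4 masked
    list(chrom = "C01", pos = 300, ref = "G", alt = "A", fmt = "GT:AD:DP:MM",
         cells = c("0/1:3,3:6:3", "0/1:3,3:6:4", "0/0:6,0:6:0")))
  write_vcf_text(rows, c("s1", "s2", "s3"), path)
}

test_that("depth, imbalance and mismatch boundaries behave exactly", {
  p <- withr::local_tempfile(fileext = ".vcf")
  boundary_vcf(p)
  vr <- read_vcf(p)
  m <- mask_low_depth(vr)
  expect_false(is.na(m$records$records[[1]]$gt[1, 1]))  # DP 4 kept
  expect_true(is.na(m$records$records[[1]]$gt[1, 2]))   # DP 3 masked
  expect_equal(m$report$removed, 1L)
  r <- recode_imbalanced_hets(m$records)
  g2 <- r$records$records[[2]]$gt
  expect_equal(g2[, 1], c(0L, 0L))  # recoded to hom-ref
  expect_equal(g2[, 2], c(0L, 1L))  # balanced het untouched
  d <- drop_mismatch_loci(r$records)
  g3 <- d$records$records[[3]]$gt
  expect_equal(g3[, 1], c(0L, 1L))      # MM = 3 kept
  expect_true(all(is.na(g3[, 2])))      # MM = 4 masked
  expect_equal(d$report$removed, 1L)
})

test_that("site call-rate boundary: 30 calls kept, 29 dropped; 81% missing sample dropped", {
  set.seed(77)
  n <- 40
  make_row <- function(pos, n_called) {
    cells <- c(rep("0/1:3,3:6:0", n_called),
               rep("./.:0,0:0:0", n - n_called))
    list(chrom = "A01", pos = pos, ref = "A", alt = "G",
         fmt = "GT:AD:DP:MM", cells = cells)
  }
  rows <- c(list(make_row(100, 30), make_row(200, 29)),
            lapply(3:60, function(i) make_row(i * 100, n)))
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(rows, sprintf("s%02d", 1:n), p)
  vr <- read_vcf(p)
  res <- apply_site_and_sample_callrate(vr, filter_config())
  expect_equal(res$report$removed, c(1L, 0L))
  expect_true("A01_100" %in% res$matrix$snps$id)
  expect_false("A01_200" %in% res$matrix$snps$id)

  # sample with 81% missingness over 100 sites is removed; 80% is kept
  n2 <- 40
  rows2 <- lapply(1:100, function(i) {
    cells <- rep("0/0:6,0:6:0", n2)
    if (i <= 81) cells[1] <- "./.:0,0:0:0"   # sample 1: 81% missing
    if (i <= 80) cells[2] <- "./.:0,0:0:0"   # sample 2: exactly 80%
    list(chrom = "C02", pos = i * 10, ref = "A", alt = "G",
         fmt = "GT:AD:DP:MM", cells = cells)
  })
  write_vcf_text(rows2, sprintf("t%02d", 1:n2), p)
  res2 <- apply_site_and_sample_callrate(read_vcf(p), filter_config())
  expect_false("t01" %in% res2$matrix$samples$id)
  expect_true("t02" %in% res2$matrix$samples$id)
  expect_equal(res2$report$removed[2], 1L)
})

test_that("planted genotype-level violations are removed at exact counts", {
  cfg <- quick_cfg(n_samples = c(WE = 30, SP = 30),
                   fst = c(WE = 0.1, SP = 0.1),
                   n_snps = c(A = 300, C = 400),
                   maf_range = c(0.3, 0.7), seed = 41)
  gm <- simulate_genotypes(cfg)
  p <- withr::local_tempfile(fileext = ".vcf")
  truth <- emit_raw_vcf(gm, cfg, p,
                        inject = list(n_low_depth = 83,
                                      n_imbalanced_het = 21,
                                      n_high_mismatch = 34))
  vr <- read_vcf(p)
  s1 <- remove_nonbiallelic(vr)
  expect_equal(s1$report$removed, 0L)
  s2 <- mask_low_depth(s1$records)
  expect_equal(s2$report$removed, 83L)
  # masked exactly at the planted cells (brute-force DP scan agrees)
  dp_all <- do.call(cbind, lapply(vr$records, `[[`, "dp"))
  called <- do.call(cbind, lapply(vr$records, function(r) !is.na(r$gt[1, ])))
  expect_equal(sum(called & dp_all < 4), 83L)
  s3 <- recode_imbalanced_hets(s2$records)
  expect_equal(s3$report$removed, 21L)
  expect_equal(attr(s3$report, "detail")[["recoded"]], 21L)
  s4 <- drop_mismatch_loci(s3$records)
  expect_equal(s4$report$removed, 34L)
  expect_equal(nrow(truth$low_depth), 83L)
})

test_that("imbalanced-het recoding equals a brute-force fraction test", {
  set.seed(101)
  n <- 200
  ad <- cbind(rbinom(n, 12, 0.5), rbinom(n, 12, 0.5)) + 1L
  rows <- lapply(seq_len(n), function(i)
    list(chrom = "A01", pos = i * 10, ref = "A", alt = "G",
         cells = sprintf("0/1:%d,%d:%d", ad[i, 1], ad[i, 2], sum(ad[i, ]))))
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(rows, "s1", p)
  out <- recode_imbalanced_hets(read_vcf(p))
  recoded <- vapply(out$records$records, function(r)
    r$gt[1, 1] == r$gt[2, 1], TRUE)
  frac <- pmin(ad[, 1], ad[, 2]) / rowSums(ad)
  expect_equal(recoded, frac < 0.2)
  # recoded direction follows the majority-read allele
  hom <- which(recoded)
  maj <- vapply(out$records$records[hom], function(r) r$gt[1, 1], 0L)
  expect_equal(maj, as.integer(ad[hom, 2] > ad[hom, 1]))
  # het without AD cannot be assessed: set missing
  rows_na <- list(list(chrom = "A01", pos = 5, ref = "A", alt = "G",
                       fmt = "GT:DP", cells = "0/1:9"))
  write_vcf_text(rows_na, "s1", p)
  suppressWarnings(vr_na <- read_vcf(p))
  out_na <- recode_imbalanced_hets(vr_na)
  expect_true(all(is.na(out_na$records$records[[1]]$gt)))
})

test_that("cascade is idempotent and report conserves counts", {
  cfg <- quick_cfg(n_samples = c(WE = 25, SP = 25),
                   fst = c(WE = 0.1, SP = 0.1),
                   n_snps = c(A = 200, C = 300),
                   maf_range = c(0.2, 0.8), call_rate_mean = 0.85, seed = 55)
  gm <- simulate_genotypes(cfg)
  p <- withr::local_tempfile(fileext = ".vcf")
  emit_raw_vcf(gm, cfg, p, inject = list(n_indel = 5, n_low_depth = 40,
                                         n_imbalanced_het = 10,
                                         n_high_mismatch = 12))
  vr <- read_vcf(p)
  cfgf <- filter_config(min_samples_called = 10)
  fc1 <- filter_cascade(vr, cfgf)
  expect_equal(fc1$report$input - fc1$report$removed, fc1$report$output)
  # record-level stages are a fixed point on their own output
  s <- remove_nonbiallelic(vr)$records
  s <- mask_low_depth(s, cfgf)$records
  s <- recode_imbalanced_hets(s, cfgf)$records
  s <- drop_mismatch_loci(s, cfgf)$records
  expect_equal(remove_nonbiallelic(s)$report$removed, 0L)
  expect_equal(mask_low_depth(s, cfgf)$report$removed, 0L)
  expect_equal(recode_imbalanced_hets(s, cfgf)$report$removed, 0L)
  expect_equal(drop_mismatch_loci(s, cfgf)$report$removed, 0L)
  # matrix-level: re-applying call-rate thresholds changes nothing
  gm1 <- fc1$matrix
  called <- colSums(!is.na(gm1$dosage))
  expect_true(all(called >= 10))
  expect_true(all(rowMeans(is.na(gm1$dosage)) <= 0.80))
})

test_that("pinned stage order is enforced (fixed-alt removal precedes recoding)", {
  # this site is NOT fixed-alt at input (one imbalanced 0/1 remains), but
  # becomes all-alt after recoding; the pinned order keeps it
  rows <- list(list(chrom = "A01", pos = 10, ref = "A", alt = "G",
                    cells = c("1/1:0,9:9", "0/1:1,9:10", "1/1:0,7:7")))
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(rows, c("s1", "s2", "s3"), p)
  vr <- read_vcf(p)
  cfgf <- filter_config(min_samples_called = 1)
  fc <- suppressWarnings(filter_cascade(vr, cfgf))
  expect_equal(n_snps(fc$matrix), 1L)
  expect_equal(unname(fc$matrix$dosage[, 1]), c(2L, 2L, 2L))
  # swapped order (recode before the fixed-alt stage) removes the site:
  sw <- recode_imbalanced_hets(vr, cfgf)
  expect_equal(remove_nonbiallelic(sw$records)$report$removed, 1L)
  # and the report rows carry the pinned order
  expect_equal(fc$report$stage,
               c("nonbiallelic_fixed_alt", "depth_mask", "het_recode",
                 "mismatch_mask", "site_callrate", "sample_callrate"))
})

test_that("missing mismatch annotation skips the stage with a warning", {
  rows <- list(list(chrom = "A01", pos = 10, ref = "A", alt = "G",
                    cells = c("0/1:3,3:6", "0/0:5,0:5")))
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(rows, c("s1", "s2"), p)
  vr <- read_vcf(p)
  expect_warning(out <- drop_mismatch_loci(vr), "skipped")
  expect_equal(out$report$removed, 0L)
})

test_that("empty output is an explicit error", {
  rows <- list(list(chrom = "A01", pos = 10, ref = "A", alt = "G",
                    cells = c("0/1:3,3:6", "./.:0,0:0")))
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(rows, c("s1", "s2"), p)
  expect_error(apply_site_and_sample_callrate(read_vcf(p), filter_config()),
               "no SNPs left")
})
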