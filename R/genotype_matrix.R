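#' napusdiv: population genomics for sparse SBG genotype panels
#'
#' See the methods vignette (`vignette("napusdiv-methods")`) for the models
#' implemented and the README for a worked example.
#'
#' @keywords internal
"_PACKAGE"

SUBPOPS <- c("WE", "WA", "SP", "WAm")

#' Natural chromosome order (A01..A10 then C01..C09)
#'
#' @param chroms character vector of chromosome names.
#' @return the unique chromosome names sorted A-subgenome first, then by
#'   number; non A/C names sort last, alphabetically.
#' @export
chrom_order <- function(chroms) {
  u <- unique(as.character(chroms))
  letter <- substr(u, 1L, 1L)
  num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", u)))
  num[is.na(num)] <- .Machine$integer.max
  key <- ifelse(letter %in% c("A", "C"), letter, "Z")
  u[order(key, num, u)]
}

subgenome_of <- function(chrom) {
  ifelse(substr(chrom, 1L, 1L) == "A", "A", "C")
}

#' Construct a genotype matrix
#'
#' The central container of the package: a samples x SNPs matrix of
#' alternate-allele dosages in \{0, 1, 2, NA\}, with per-SNP metadata
#' (chromosome, position, subgenome, genic flag) and per-sample metadata
#' (growth habit, geography, subpopulation label).
#'
#' @param dosage integer matrix, samples in rows, SNPs in columns; values
#'   must be 0, 1, 2 or NA (missing).
#' @param snps data.frame with columns `id`, `chrom`, `pos` (1-based bp) and
#'   optionally `genic` (logical). The `subgenome` column is derived from the
#'   chromosome prefix ("A" iff the name starts with "A").
#' @param samples data.frame with column `id` and optionally `growth_habit`
#'   ("winter"/"spring"), `geography` ("Europe"/"Asia"/"America") and
#'   `subpop` ("WE","WA","WAm","SP" or NA for unassigned).
#' @return an object of class `geno_matrix`.
#' @export
genotype_matrix <- function(dosage, snps, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  stopifnot(is.data.frame(snps), is.data.frame(samples))
  if (nrow(samples) != nrow(dosage) || nrow(snps) != ncol(dosage))
    stop("dosage dimensions do not match metadata")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosage values must be in {0, 1, 2, NA}")
  if (ncol(dosage) > 0L && any(colSums(!is.na(dosage)) == 0L))
    stop("every SNP must have at least one non-missing call")
  snps$id <- as.character(snps$id)
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  snps$subgenome <- subgenome_of(snps$chrom)
  if (is.null(snps$genic)) snps$genic <- NA
  samples$id <- as.character(samples$id)
  for (col in c("growth_habit", "geography", "subpop"))
    if (is.null(samples[[col]])) samples[[col]] <- NA_character_
  rownames(dosage) <- samples$id
  colnames(dosage) <- snps$id
  rownames(snps) <- NULL
  rownames(samples) <- NULL
  structure(list(dosage = dosage, snps = snps, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d SNPs\n",
              nrow(x$dosage), ncol(x$dosage)))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missingness: %.1f%%; subgenome A: %d SNPs, C: %d SNPs\n",
              100 * miss, sum(x$snps$subgenome == "A"),
              sum(x$snps$subgenome == "C")))
  sp <- table(factor(x$samples$subpop, levels = SUBPOPS))
  cat("  subpopulations:", paste(names(sp), sp, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' @rdname genotype_matrix
#' @param gm a `geno_matrix`.
#' @export
n_samples <- function(gm) nrow(gm$dosage)

#' @rdname genotype_matrix
#' @export
n_snps <- function(gm) ncol(gm$dosage)

#' Subset a genotype matrix by SNPs or samples
#'
#' @param gm a `geno_matrix`.
#' @param idx logical, integer or character (id) index.
#' @return a new `geno_matrix`.
#' @export
subset_snps <- function(gm, idx) {
  if (is.character(idx)) idx <- match(idx, gm$snps$id)
  genotype_matrix(gm$dosage[, idx, drop = FALSE],
                  gm$snps[idx, , drop = FALSE], gm$samples)
}

#' @rdname subset_snps
#' @export
subset_samples <- function(gm, idx) {
  if (is.character(idx)) idx <- match(idx, gm$samples$id)
  dos <- gm$dosage[idx, , drop = FALSE]
  keep <- colSums(!is.na(dos)) > 0L
  genotype_matrix(dos[, keep, drop = FALSE],
                  gm$snps[keep, , drop = FALSE],
                  gm$samples[idx, , drop = FALSE])
}

# indices of the samples belonging to one subpopulation
subpop_idx <- function(gm, subpop) {
  which(!is.na(gm$samples$subpop) & gm$samples$subpop %in% subpop)
}

# per-SNP alternate / total chromosome counts within a sample subset
allele_counts <- function(gm, rows = seq_len(n_samples(gm))) {
  dos <- gm$dosage[rows, , drop = FALSE]
  called <- colSums(!is.na(dos))
  alt <- colSums(dos, na.rm = TRUE)
  list(alt = alt, chrom = 2L * called, called = called)
}

# order SNP indices along the genome (natural chromosome order, then pos)
genome_order <- function(snps) {
  ord <- chrom_order(snps$chrom)
  order(match(snps$chrom, ord), snps$pos)
}
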