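# VCF reading/writing for GT:AD:DP(:MM) call sets.
#
# The reader is deliberately dialect-tolerant: AD sums need not equal DP,
# unknown FORMAT keys are ignored, and multiallelic records are retained
# losslessly (they are rejected later by the filter cascade, not here).
# MM is a non-standard per-genotype integer carrying the number of
# sample-specific mismatches at the locus, used by `drop_mismatch_loci()`.

#' Read a VCF file into variant records
#'
#' Parses a VCF v4.x file with per-sample GT, AD and DP (and optionally MM)
#' FORMAT fields. One record per data line, in file order. `./.` (or `.`)
#' genotypes map to missing.
#'
#' @param path path to an uncompressed VCF file.
#' @return an object of class `variant_records`: a list with `samples`
#'   (character vector) and `records`, a list where each element has
#'   `chrom`, `pos`, `ref`, `alts`, `gt` (2 x n integer matrix of allele
#'   indices, NA = missing), `ad` (list of integer allele-depth vectors,
#'   possibly NULL), `dp` (integer vector) and `mm` (integer vector or NULL).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L)
    stop("malformed VCF header: no #CHROM line found in ", path)
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L || cols[9] != "FORMAT")
    stop("malformed VCF header: FORMAT/sample columns missing")
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  n <- length(samples)
  n_no_gt <- 0L; n_no_ad <- 0L; n_no_dp <- 0L
  records <- vector("list", length(body))
  for (r in seq_along(body)) {
    f <- strsplit(body[r], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L + n)
      stop("malformed VCF data line ", r, ": expected ", 9L + n,
           " columns, got ", length(f))
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    i_gt <- match("GT", fmt); i_ad <- match("AD", fmt)
    i_dp <- match("DP", fmt); i_mm <- match("MM", fmt)
    per <- strsplit(f[-(1:9)], ":", fixed = TRUE)
    gt <- matrix(NA_integer_, 2L, n)
    if (is.na(i_gt)) {
      n_no_gt <- n_no_gt + 1L
    } else {
      gts <- vapply(per, function(x) x[i_gt], "")
      ok <- !(gts %in% c(".", "./.", ".|.")) & !is.na(gts)
      if (any(ok)) {
        parts <- strsplit(gts[ok], "[/|]")
        gt[, ok] <- vapply(parts, function(p) {
          p <- suppressWarnings(as.integer(p))
          if (length(p) == 1L) p <- c(p, p)
          p[1:2]
        }, integer(2))
      }
    }
    ad <- NULL
    if (!is.na(i_ad)) {
      ad <- lapply(per, function(x) {
        v <- if (length(x) >= i_ad) x[i_ad] else "."
        if (is.na(v) || v == ".") return(NULL)
        suppressWarnings(as.integer(strsplit(v, ",", fixed = TRUE)[[1]]))
      })
    } else n_no_ad <- n_no_ad + 1L
    dp <- rep(NA_integer_, n)
    if (!is.na(i_dp)) {
      v <- vapply(per, function(x) if (length(x) >= i_dp) x[i_dp] else ".", "")
      dp <- suppressWarnings(as.integer(ifelse(v == ".", NA, v)))
    } else n_no_dp <- n_no_dp + 1L
    mm <- NULL
    if (!is.na(i_mm)) {
      v <- vapply(per, function(x) if (length(x) >= i_mm) x[i_mm] else ".", "")
      mm <- suppressWarnings(as.integer(ifelse(v == ".", NA, v)))
    }
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    pos <- as.integer(f[2])
    if (is.na(pos) || pos < 1L) stop("invalid POS at data line ", r)
    records[[r]] <- list(chrom = f[1], pos = pos, ref = f[4], alts = alts,
                         gt = gt, ad = ad, dp = dp, mm = mm)
  }
  if (n_no_gt + n_no_ad + n_no_dp > 0L)
    warning(sprintf(
      "records with missing FORMAT keys set to missing: GT in %d, AD in %d, DP in %d",
      n_no_gt, n_no_ad, n_no_dp))
  structure(list(samples = samples, records = records),
            class = "variant_records")
}

#' @export
print.variant_records <- function(x, ...) {
  cat(sprintf("variant_records: %d sites x %d samples\n",
              length(x$records), length(x$samples)))
  invisible(x)
}

fmt_gt <- function(a1, a2) {
  ifelse(is.na(a1) | is.na(a2), "./.", paste0(a1, "/", a2))
}

#' Write variant records to a VCF file
#'
#' Inverse of [read_vcf()]: emits a VCF v4.2 file with GT:AD:DP (and MM when
#' present) FORMAT fields. `write_vcf(read_vcf(p))` round-trips.
#'
#' @param vr a `variant_records` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vr, path) {
  stopifnot(inherits(vr, "variant_records"))
  has_mm <- any(vapply(vr$records, function(r) !is.null(r$mm), TRUE))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=napusdiv",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  if (has_mm)
    hdr <- c(hdr, paste0("##FORMAT=<ID=MM,Number=1,Type=Integer,",
                         "Description=\"Sample-specific mismatches at locus\">"))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", vr$samples),
                      collapse = "\t"))
  fmt <- if (has_mm) "GT:AD:DP:MM" else "GT:AD:DP"
  lines <- vapply(vr$records, function(r) {
    n <- length(vr$samples)
    gt <- fmt_gt(r$gt[1, ], r$gt[2, ])
    ad <- if (is.null(r$ad)) rep(".", n) else
      vapply(r$ad, function(a) if (is.null(a)) "." else
        paste(a, collapse = ","), "")
    dp <- ifelse(is.na(r$dp), ".", as.character(r$dp))
    cells <- paste(gt, ad, dp, sep = ":")
    if (has_mm) {
      mm <- if (is.null(r$mm)) rep(".", n) else
        ifelse(is.na(r$mm), ".", as.character(r$mm))
      cells <- paste(cells, mm, sep = ":")
    }
    paste(c(r$chrom, r$pos, ".", r$ref, paste(r$alts, collapse = ","),
            ".", "PASS", ".", fmt, cells), collapse = "\t")
  }, "")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' @param path TSV with header columns `sample_id`, `growth_habit`,
#'   `geography` and optionally `subpop`.
#' @return data.frame with columns `id`, `growth_habit`, `geography`,
#'   `subpop`.
#' @export
read_sample_metadata <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "growth_habit", "geography")
  if (!all(need %in% names(d)))
    stop("sample metadata must have columns: ", paste(need, collapse = ", "))
  data.frame(id = as.character(d$sample_id),
             growth_habit = d$growth_habit,
             geography = d$geography,
             subpop = if ("subpop" %in% names(d)) d$subpop else NA_character_,
             stringsAsFactors = FALSE)
}

#' Write a sample metadata table
#' @param samples data.frame as stored in a `geno_matrix` (`$samples`).
#' @param path output TSV path.
#' @export
write_sample_metadata <- function(samples, path) {
  out <- data.frame(sample_id = samples$id,
                    growth_habit = samples$growth_habit,
                    geography = samples$geography,
                    subpop = samples$subpop)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
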