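# Gene annotation: GFF3 input and genic/intergenic classification of SNPs.
# Coordinates are 1-based inclusive throughout (VCF and GFF3 convention);
# no half-open conversion is ever performed.

#' Read gene annotations from a GFF3 file
#'
#' Only rows of type "gene" are used. The gene id is taken from the `ID`
#' attribute (falling back to `Name`, then to a generated id).
#'
#' @param path GFF3 file path.
#' @param focal_ids optional character vector of gene ids forming the focal
#'   set (e.g. flowering-time and vernalization genes); marks `is_focal`.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive) and `is_focal`.
#' @export
read_gene_annotation <- function(path, focal_ids = character()) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  ids <- as.character(gr$ID)
  if (!is.null(gr$Name)) {
    nm <- as.character(gr$Name)
    ids[is.na(ids) | ids == ""] <- nm[is.na(ids) | ids == ""]
  }
  miss <- is.na(ids) | ids == ""
  ids[miss] <- paste0("gene", which(miss))
  out <- data.frame(gene_id = ids,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("gene with start > end in ", path)
  out$is_focal <- out$gene_id %in% focal_ids
  out
}

#' Annotate SNPs as genic or intergenic
#'
#' A SNP is genic iff its position lies within `[start, end]` of at least one
#' gene on the same chromosome (boundaries inclusive). SNPs on chromosomes
#' absent from the annotation are intergenic. The subgenome field is
#' (re)assigned from the chromosome prefix.
#'
#' @param gm a `geno_matrix`.
#' @param genes data.frame as returned by [read_gene_annotation()].
#' @return the `geno_matrix` with the per-SNP `genic` flag filled in.
#' @export
annotate_snps <- function(gm, genes) {
  stopifnot(inherits(gm, "geno_matrix"))
  snp_gr <- GenomicRanges::GRanges(
    gm$snps$chrom, IRanges::IRanges(gm$snps$pos, gm$snps$pos))
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::countOverlaps(snp_gr, gene_gr)
  gm$snps$genic <- hits > 0L
  gm$snps$subgenome <- subgenome_of(gm$snps$chrom)
  gm
}
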