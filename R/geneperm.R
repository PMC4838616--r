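# Matched-composition permutation test: is a focal gene set's mean Fst or
# mean per-SNP mismatch (Pi) extreme relative to random SNP sets with the
# same subgenome x genic/intergenic composition?

#' Representative SNPs for each gene
#'
#' Each gene is represented by exactly `r` SNPs: all SNPs inside the gene
#' (by position, up to `r`), then the nearest flanking SNPs on its
#' chromosome ordered by distance to the gene boundary, equidistant
#' left/right candidates breaking leftward. Genes whose chromosome runs out
#' of SNPs take all available and are flagged.
#'
#' @param gm a `geno_matrix` whose SNPs carry the genic flag (run
#'   [annotate_snps()] first).
#' @param genes data.frame of focal genes (gene_id, chrom, start, end).
#' @param r representative SNPs per gene (default 40).
#' @return object of class `gene_snp_set`: `sets` (named list of SNP id
#'   vectors), `tally` (data.frame subgenome x genic -> count over the
#'   concatenated representative lists, multiplicity retained), `flagged`
#'   (gene ids that could not reach `r`).
#' @export
representative_snps <- function(gm, genes, r = 40) {
  if (all(is.na(gm$snps$genic)))
    stop("SNPs lack the genic flag; run annotate_snps() first")
  sets <- vector("list", nrow(genes))
  names(sets) <- genes$gene_id
  flagged <- character(0)
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    on_chr <- which(gm$snps$chrom == g$chrom)
    pos <- gm$snps$pos[on_chr]
    inside <- on_chr[pos >= g$start & pos <= g$end]
    inside <- inside[order(gm$snps$pos[inside])]
    if (length(inside) >= r) {
      pick <- inside[seq_len(r)]
    } else {
      left <- on_chr[pos < g$start]
      right <- on_chr[pos > g$end]
      cand <- c(left, right)
      dist <- c(g$start - gm$snps$pos[left], gm$snps$pos[right] - g$end)
      side <- c(rep(0L, length(left)), rep(1L, length(right)))  # left first
      need <- r - length(inside)
      ord <- order(dist, side)
      flank <- cand[ord][seq_len(min(need, length(cand)))]
      pick <- c(inside, flank)
      if (length(pick) < r)
        flagged <- c(flagged, g$gene_id)
    }
    sets[[gi]] <- gm$snps$id[pick]
  }
  all_ids <- unlist(sets, use.names = FALSE)
  m <- match(all_ids, gm$snps$id)
  tally <- as.data.frame(table(
    subgenome = gm$snps$subgenome[m],
    genic = gm$snps$genic[m]), stringsAsFactors = FALSE)
  names(tally)[3] <- "count"
  tally$genic <- as.logical(tally$genic)
  structure(list(sets = sets, tally = tally, flagged = flagged, r = r),
            class = "gene_snp_set")
}

#' Draw a random SNP set matching a composition tally
#'
#' Samples SNP ids without replacement, stratified by subgenome x
#' genic/intergenic, with per-stratum counts equal to the tally. Errors
#' (naming the stratum) when a pool is too small.
#'
#' @param gm a `geno_matrix` with genic flags.
#' @param tally data.frame (subgenome, genic, count) as produced by
#'   [representative_snps()].
#' @param exclude SNP ids removed from the pools (e.g. NA-statistic SNPs).
#' @return character vector of SNP ids (no repeats within the draw).
#' @export
matched_null_draw <- function(gm, tally, exclude = character()) {
  keep <- !(gm$snps$id %in% exclude)
  out <- character(0)
  for (i in seq_len(nrow(tally))) {
    cnt <- tally$count[i]
    if (cnt == 0) next
    pool <- gm$snps$id[keep & gm$snps$subgenome == tally$subgenome[i] &
                         gm$snps$genic == tally$genic[i]]
    if (length(pool) < cnt)
      stop(sprintf("stratum %s/%s has %d SNPs; %d required",
                   tally$subgenome[i],
                   if (tally$genic[i]) "genic" else "intergenic",
                   length(pool), cnt))
    out <- c(out, sample(pool, cnt))
  }
  out
}

#' Matched-composition permutation test
#'
#' The observed statistic is the mean of a per-SNP statistic over the gene
#' set's representative SNPs (multiplicity retained); the null distribution
#' is the same mean over `iterations` matched random draws. The p-value is
#' the raw count of null values at least as extreme as the observed one
#' divided by `iterations` (no add-one correction); p = 0 outcomes carry a
#' `"< 1/iterations"` annotation.
#'
#' @param gm a `geno_matrix` with genic flags.
#' @param gene_set a `gene_snp_set` from [representative_snps()].
#' @param statistic either a named per-SNP numeric vector (names = SNP
#'   ids), or one of `"mean_fst"` / `"mean_big_pi"` computed internally.
#' @param pair subpopulation pair (for `"mean_fst"`).
#' @param subpop subpopulation (for `"mean_big_pi"`).
#' @param iterations number of null draws; required, no silent default
#'   (reported values in the source literature use both 1,000 and 10,000).
#' @param direction "greater" (observed expected high) or "less".
#' @param seed RNG seed.
#' @return object of class `permutation_result`: `observed`, `p`,
#'   `p_annotation`, `iterations`, `direction`, `null` (the null means),
#'   `n_snps_used`, `n_snps_dropped`.
#' @export
permutation_test <- function(gm, gene_set, statistic, pair = NULL,
                             subpop = NULL, iterations,
                             direction = c("greater", "less"), seed = 1) {
  direction <- match.arg(direction)
  stopifnot(inherits(gene_set, "gene_snp_set"))
  if (iterations < 100)
    warning("fewer than 100 iterations: p-value resolution is very limited")
  if (is.character(statistic) && length(statistic) == 1L) {
    statistic <- switch(
      statistic,
      mean_fst = {
        stopifnot(!is.null(pair))
        tr <- per_snp_fst_track(gm, pair)
        stats::setNames(tr$fst, tr$id)
      },
      mean_big_pi = big_pi_per_snp(gm, subpop),
      stop("unknown statistic: ", statistic))
  }
  stat <- statistic[gm$snps$id]
  names(stat) <- gm$snps$id
  dropped <- names(stat)[is.na(stat)]
  ids <- unlist(gene_set$sets, use.names = FALSE)
  ids_used <- ids[!ids %in% dropped]
  if (!length(ids_used)) stop("no representative SNP has a defined statistic")
  observed <- mean(stat[ids_used])
  # precomputed stratum pools; one sample() per stratum per iteration, in
  # tally row order — identical draws to matched_null_draw(gm, tally, ...)
  tally <- gene_set$tally
  keep <- !is.na(stat)
  pools <- lapply(seq_len(nrow(tally)), function(i)
    which(keep & gm$snps$subgenome == tally$subgenome[i] &
            gm$snps$genic == tally$genic[i]))
  for (i in seq_len(nrow(tally)))
    if (tally$count[i] > length(pools[[i]]))
      stop(sprintf("stratum %s/%s has %d SNPs; %d required",
                   tally$subgenome[i],
                   if (tally$genic[i]) "genic" else "intergenic",
                   length(pools[[i]]), tally$count[i]))
  set.seed(seed)
  null <- vapply(seq_len(iterations), function(i) {
    idx <- unlist(lapply(seq_len(nrow(tally)), function(j)
      if (tally$count[j] > 0) sample(pools[[j]], tally$count[j])
      else integer(0)))
    mean(stat[idx])
  }, 0)
  extreme <- if (direction == "greater") sum(null >= observed) else
    sum(null <= observed)
  p <- extreme / iterations
  structure(list(observed = observed, p = p,
                 p_annotation = if (extreme == 0)
                   sprintf("< %g", 1 / iterations) else NA_character_,
                 iterations = iterations, direction = direction,
                 null = null, n_snps_used = length(ids_used),
                 n_snps_dropped = length(ids) - length(ids_used)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_result: observed = %.5g, p = %g%s (%d iterations, %s)\n",
    x$observed, x$p,
    if (!is.na(x$p_annotation)) paste0(" [", x$p_annotation, "]") else "",
    x$iterations, x$direction))
  invisible(x)
}
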