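# Probabilistic PCA on incomplete dosage matrices, fitted by the
# imputation-EM algorithm: missing entries are replaced by their current
# model reconstruction each cycle, followed by a complete-data EM update of
# the loading matrix and noise variance. On complete data this is exact EM
# for the isotropic latent-variable model and converges to classical PCA.

#' Fit probabilistic PCA to a genotype matrix with missing entries
#'
#' Dosages are column-centered on observed means and left unscaled. Missing
#' entries are treated as latent and imputed from the current model at each
#' EM cycle. Convergence is declared when the relative change in the
#' observed-data reconstruction error falls below `tol`. After convergence
#' the completed matrix is decomposed by SVD so components are orthogonal,
#' variance-ordered, and comparable to classical PCA; each loading vector is
#' flipped so its largest-magnitude entry is positive.
#'
#' @param x a `geno_matrix` or a numeric matrix (samples x variables,
#'   NA = missing).
#' @param q number of components (default 10).
#' @param tol relative-change convergence tolerance (default 1e-6).
#' @param max_iter EM iteration cap; non-convergence is reported via the
#'   `converged` flag, not an error.
#' @param seed seed for the random loading initialization (fixed default so
#'   results are deterministic).
#' @return an object of class `ppca_result`: `scores` (n x q), `loadings`
#'   (p x q, unit-norm columns), `evf` (explained-variance fractions),
#'   `converged`, `iterations`, `final_delta`, `objective` (per-iteration
#'   observed-data reconstruction error), `center`, and `snps` metadata when
#'   `x` is a `geno_matrix`.
#' @export
ppca_fit <- function(x, q = 10, tol = 1e-6, max_iter = 1000, seed = 1) {
  snps <- NULL
  if (inherits(x, "geno_matrix")) {
    snps <- x$snps
    x <- x$dosage
  }
  x <- as.matrix(x) * 1.0
  n <- nrow(x); p <- ncol(x)
  if (q >= min(n, p)) stop("q must be smaller than both matrix dimensions")
  if (any(rowSums(!is.na(x)) == 0L) || any(colSums(!is.na(x)) == 0L))
    stop("every sample and every SNP must have at least one observed value")
  obs <- !is.na(x)
  ctr <- colMeans(x, na.rm = TRUE)
  xc <- sweep(x, 2L, ctr)
  xc[!obs] <- 0
  set.seed(seed)
  w <- matrix(stats::rnorm(p * q), p, q)
  ss <- 1
  objective <- numeric(0)
  prev <- Inf; delta <- Inf; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    m <- crossprod(w) + diag(ss, q)
    minv <- solve(m)
    ez <- xc %*% w %*% minv                       # n x q
    recon <- ez %*% t(w)
    rss <- sum((xc[obs] - recon[obs])^2)
    objective[it] <- rss
    xc[!obs] <- recon[!obs]
    szz <- n * ss * minv + crossprod(ez)
    w <- crossprod(xc, ez) %*% solve(szz)
    ss <- max((sum(xc^2) - 2 * sum(ez * (xc %*% w)) +
                 sum(szz * crossprod(w))) / (n * p), 1e-12)
    delta <- abs(prev - rss) / max(rss, 1e-12)
    prev <- rss
    if (delta < tol) break
  }
  sv <- svd(xc)
  k <- seq_len(q)
  scores <- sv$u[, k, drop = FALSE] %*% diag(sv$d[k], q)
  loadings <- sv$v[, k, drop = FALSE]
  for (j in k) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  tot <- sum(sv$d^2)
  evf <- if (tot > 0) sv$d[k]^2 / tot else rep(0, q)
  rownames(scores) <- rownames(x)
  rownames(loadings) <- colnames(x)
  colnames(scores) <- colnames(loadings) <- paste0("PC", k)
  structure(list(scores = scores, loadings = loadings, evf = evf,
                 converged = delta < tol, iterations = it,
                 final_delta = delta, objective = objective, center = ctr,
                 snps = snps),
            class = "ppca_result")
}

#' @export
print.ppca_result <- function(x, ...) {
  cat(sprintf("ppca_result: %d samples, %d components (%s, %d iterations)\n",
              nrow(x$scores), ncol(x$scores),
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$evf), collapse = " "), "\n")
  invisible(x)
}

#' Top-loading SNPs of a component, with genomic block detection
#'
#' Ranks SNPs by absolute loading on one component and merges the selected
#' SNPs into contiguous genomic blocks (selected SNPs closer than
#' `merge_gap_bp` are joined), flagging regions that drive the component.
#'
#' @param fit a `ppca_result` fitted from a `geno_matrix` (so SNP metadata
#'   is available), or supply `snps` explicitly.
#' @param component component index (default 1).
#' @param k how many SNPs to report (default 300); truncated with a warning
#'   when larger than the SNP count.
#' @param merge_gap_bp gap threshold for block merging (default 1 Mb).
#' @param min_block_snps minimum SNPs for a reported block (default 5).
#' @param snps optional SNP metadata data.frame (id, chrom, pos).
#' @return list with `snps` (ranked data.frame: id, chrom, pos, loading) and
#'   `blocks` (data.frame: chrom, start, end, n_snps).
#' @export
top_loading_snps <- function(fit, component = 1, k = 300,
                             merge_gap_bp = 1e6, min_block_snps = 5,
                             snps = NULL) {
  stopifnot(inherits(fit, "ppca_result"), component <= ncol(fit$loadings))
  if (is.null(snps)) snps <- fit$snps
  if (is.null(snps)) stop("SNP metadata required (fit on a geno_matrix)")
  lo <- fit$loadings[, component]
  if (k > length(lo)) {
    warning("k exceeds SNP count; truncating to ", length(lo))
    k <- length(lo)
  }
  ord <- genome_order(snps)
  rank_in_genome <- match(seq_along(lo), ord)
  sel <- order(-abs(lo), rank_in_genome)[seq_len(k)]
  ranked <- data.frame(id = snps$id[sel], chrom = snps$chrom[sel],
                       pos = snps$pos[sel], loading = lo[sel],
                       stringsAsFactors = FALSE)
  flags <- logical(length(lo))
  flags[sel] <- TRUE
  blocks <- merge_regions(snps$chrom, snps$pos, flags,
                          max_gap_bp = merge_gap_bp,
                          min_snps = min_block_snps)
  list(snps = ranked, blocks = blocks)
}

#' Nearest-centroid cluster support and discordance flags
#'
#' Computes the centroid of each labeled group in PC1-PC2 space, assigns
#' every sample to its nearest centroid, and flags samples whose assignment
#' disagrees with their label. Groups with fewer than 3 samples get their
#' centroid flagged low-confidence.
#'
#' @param fit a `ppca_result`.
#' @param labels character vector of group labels per sample (NA =
#'   unlabeled; unlabeled samples are assigned but never flagged).
#' @return data.frame: sample, label, assigned, discordant, plus a
#'   `centroids` attribute (group, PC1, PC2, n, low_confidence).
#' @export
cluster_support <- function(fit, labels) {
  stopifnot(inherits(fit, "ppca_result"))
  pc <- fit$scores[, 1:2, drop = FALSE]
  labels <- as.character(labels)
  groups <- sort(unique(labels[!is.na(labels)]))
  if (length(groups) < 2L) stop("need at least 2 labeled groups")
  cent <- t(vapply(groups, function(g)
    colMeans(pc[which(labels == g), , drop = FALSE]), numeric(2)))
  nsz <- vapply(groups, function(g) sum(labels == g, na.rm = TRUE), 0L)
  d2 <- outer(rowSums(pc^2), rep(1, length(groups))) -
    2 * pc %*% t(cent) + outer(rep(1, nrow(pc)), rowSums(cent^2))
  assigned <- groups[max.col(-d2, ties.method = "first")]
  out <- data.frame(sample = rownames(pc), label = labels,
                    assigned = assigned,
                    discordant = !is.na(labels) & assigned != labels,
                    stringsAsFactors = FALSE)
  attr(out, "centroids") <- data.frame(
    group = groups, PC1 = cent[, 1], PC2 = cent[, 2], n = nsz,
    low_confidence = nsz < 3L, stringsAsFactors = FALSE)
  out
}
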