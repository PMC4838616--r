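# Weighted-genotype distances, neighbor joining, midpoint rooting and
# bootstrap bipartition supports. Trees live in ape "phylo" objects; the
# algorithms themselves are implemented here (pinned tie-breaks, negative
# branch handling, pairwise-deletion distances).

# core of the weighted p-distance: dosage -> list(d, shared)
wpd_core <- function(dosage) {
  a0 <- (dosage == 0L); a0[is.na(a0)] <- FALSE; storage.mode(a0) <- "double"
  ah <- (dosage == 1L); ah[is.na(ah)] <- FALSE; storage.mode(ah) <- "double"
  a1 <- (dosage == 2L); a1[is.na(a1)] <- FALSE; storage.mode(a1) <- "double"
  cc <- !is.na(dosage); storage.mode(cc) <- "double"
  shared <- tcrossprod(cc)
  mismatch <- 0.5 * (tcrossprod(a0, ah) + tcrossprod(ah, a0) +
                       tcrossprod(a1, ah) + tcrossprod(ah, a1)) +
    tcrossprod(a0, a1) + tcrossprod(a1, a0)
  d <- ifelse(shared > 0, mismatch / shared, NA_real_)
  diag(d) <- 0
  list(d = d, shared = shared)
}

#' Weighted p-distance matrix with pairwise deletion
#'
#' Genotypes are weighted 0 / 0.5 / 1 (alternate dosage over 2); the
#' distance between two samples is the mean absolute weight difference over
#' loci called in both. Pairs sharing fewer than `min_shared` loci are
#' undefined (NA) — the pairwise-deletion distance is unstable for sparse
#' pairs.
#'
#' @param gm a `geno_matrix`.
#' @param min_shared minimum shared called loci per pair (default 50).
#' @return object of class `weighted_dist`: `d` (symmetric matrix, zero
#'   diagonal), `shared` (per-pair shared-locus counts), `ids`.
#' @export
weighted_p_distance <- function(gm, min_shared = 50) {
  if (n_samples(gm) < 2L) stop("need at least 2 samples")
  res <- wpd_core(gm$dosage)
  d <- res$d
  off <- row(d) != col(d)
  d[off & res$shared < min_shared] <- NA_real_
  rownames(d) <- colnames(d) <- gm$samples$id
  structure(list(d = d, shared = res$shared, ids = gm$samples$id),
            class = "weighted_dist")
}

fmt_len <- function(x) sprintf("%.12g", x)

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration minimizing
#' Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k), with branch lengths
#' from the standard split formula. Ties break on the smallest (i, j) index
#' pair in the current matrix order; a negative branch length is clamped to
#' zero with the deficit moved to its sibling branch (total preserved).
#'
#' @param dist a `weighted_dist`, `dist`, or symmetric numeric matrix with
#'   dimnames. Any NA off-diagonal entry is an error (remove the offending
#'   samples first).
#' @return an unrooted `phylo` tree (trifurcating root node).
#' @export
neighbor_joining <- function(dist) {
  d <- if (inherits(dist, "weighted_dist")) dist$d else as.matrix(dist)
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (any(is.na(d[row(d) != col(d)])))
    stop("distance matrix has undefined pairs; remove sparse samples ",
         "before tree building")
  if (n < 2L) stop("need at least 2 samples for a tree")
  if (n == 2L)
    return(ape::read.tree(text = sprintf(
      "(%s:%s,%s:%s);", labels[1], fmt_len(d[1, 2] / 2),
      labels[2], fmt_len(d[1, 2] / 2))))
  frag <- labels
  while (n > 3L) {
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    hit <- which(q == min(q), arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- li + lj; li <- 0 }
    if (lj < 0) { li <- max(li + lj, 0); lj <- 0 }
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    merged <- sprintf("(%s:%s,%s:%s)", frag[i], fmt_len(li),
                      frag[j], fmt_len(lj))
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    d <- d2
    frag <- c(frag[keep], merged)
    n <- n - 1L
  }
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt_len(max(l1, 0)), frag[2], fmt_len(max(l2, 0)),
                 frag[3], fmt_len(max(l3, 0)))
  ape::read.tree(text = txt)
}

# adjacency list (neighbor id, edge length) keyed by node id
tree_adjacency <- function(phy, extra_node = NULL) {
  nn <- max(phy$edge)
  adj <- vector("list", nn + ifelse(is.null(extra_node), 0L, 1L))
  add <- function(u, v, l) {
    adj[[u]][[length(adj[[u]]) + 1L]] <<- c(v, l)
    adj[[v]][[length(adj[[v]]) + 1L]] <<- c(u, l)
  }
  for (e in seq_len(nrow(phy$edge)))
    add(phy$edge[e, 1], phy$edge[e, 2], phy$edge.length[e])
  list(adj = adj, add = add)
}

# build a rooted phylo from an undirected adjacency, rooted at `root`
root_adjacency <- function(adj, root, n_tips, tip_labels) {
  parent <- integer(0); child <- integer(0); len <- numeric(0)
  visited <- rep(FALSE, length(adj))
  queue <- root; visited[root] <- TRUE
  order_internal <- integer(0)
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    if (u > n_tips) order_internal <- c(order_internal, u)
    for (nb in adj[[u]]) {
      v <- nb[1]
      if (visited[v]) next
      visited[v] <- TRUE
      parent <- c(parent, u); child <- c(child, v); len <- c(len, nb[2])
      queue <- c(queue, v)
    }
  }
  new_id <- integer(length(adj))
  new_id[seq_len(n_tips)] <- seq_len(n_tips)
  new_id[order_internal] <- n_tips + seq_along(order_internal)
  tree <- list(edge = cbind(new_id[parent], new_id[child]),
               edge.length = len, tip.label = tip_labels,
               Nnode = length(order_internal))
  class(tree) <- "phylo"
  attr(tree, "order") <- NULL
  ape::reorder.phylo(tree, "cladewise")
}

#' Midpoint-root a tree
#'
#' Places the root halfway along the longest leaf-to-leaf path. If the
#' midpoint falls exactly on an internal node, the tree is rooted at that
#' node (documented tie rule); otherwise the containing edge is split by a
#' new root node. The root is equidistant from the two farthest leaves.
#'
#' @param phy an (unrooted) `phylo` tree with branch lengths.
#' @return a rooted `phylo` tree.
#' @export
midpoint_root <- function(phy) {
  n <- length(phy$tip.label)
  dd <- ape::dist.nodes(phy)
  td <- dd[seq_len(n), seq_len(n), drop = FALSE]
  if (max(td) <= 0) stop("all branch lengths are zero; midpoint undefined")
  hit <- which(td == max(td), arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  i <- hit[1, 1]; j <- hit[1, 2]
  path <- ape::nodepath(phy, i, j)
  seg <- dd[cbind(path[-length(path)], path[-1])]
  cum <- c(0, cumsum(seg))
  half <- td[i, j] / 2
  eps <- 1e-12 * max(1, half)
  t_at <- which(abs(cum - half) <= eps)
  ta <- tree_adjacency(phy)
  adj <- ta$adj
  n_nodes <- max(phy$edge)
  if (length(t_at)) {
    root <- path[t_at[1]]
    if (root <= n) {
      # midpoint on a leaf can only happen with zero-length path segments;
      # root at its neighbor instead
      root <- path[if (t_at[1] == 1L) 2L else t_at[1] - 1L]
    }
    return(root_adjacency(adj, root, n, phy$tip.label))
  }
  t0 <- max(which(cum < half))
  u <- path[t0]; v <- path[t0 + 1]
  a <- half - cum[t0]
  new_node <- n_nodes + 1L
  adj[[new_node]] <- list()
  # drop the u-v edge, insert u - new - v
  adj[[u]] <- Filter(function(nb) nb[1] != v, adj[[u]])
  adj[[v]] <- Filter(function(nb) nb[1] != u, adj[[v]])
  adj[[u]][[length(adj[[u]]) + 1L]] <- c(new_node, a)
  adj[[new_node]][[1L]] <- c(u, a)
  adj[[v]][[length(adj[[v]]) + 1L]] <- c(new_node, seg[t0] - a)
  adj[[new_node]][[2L]] <- c(v, seg[t0] - a)
  root_adjacency(adj, new_node, n, phy$tip.label)
}

# tip-label sets below each internal edge, normalized so the side not
# containing the lexicographically smallest label is kept (stable across
# trees over the same label set); trivial splits excluded
tree_bipartitions_keys <- function(phy) {
  n <- length(phy$tip.label)
  ref <- min(phy$tip.label)
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  keys <- character(0)
  for (set in pp) {
    tips <- labs[set]
    if (ref %in% tips) tips <- setdiff(labs, tips)
    if (length(tips) < 2L || length(tips) > n - 2L) next
    keys <- c(keys, paste(sort(tips), collapse = "|"))
  }
  unique(keys)
}

#' Non-trivial bipartitions of a tree
#'
#' @param phy a `phylo` tree.
#' @return character vector of normalized bipartition keys (sorted tip
#'   labels of the side not containing the lexicographically smallest tip,
#'   "|"-separated).
#' @export
tree_bipartitions <- function(phy) tree_bipartitions_keys(phy)

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the NJ tree from the full weighted p-distance matrix, midpoint
#' roots it, then resamples loci with replacement `n_replicates` times,
#' recomputing distance and NJ each time. The support of each internal node
#' is the percentage of replicates whose tree contains the node's
#' bipartition (Felsenstein-style, attached to the original topology).
#' Replicates producing an undefined pair are redrawn (counted, capped at
#' `10 * n_replicates` total draws).
#'
#' @param gm a `geno_matrix`.
#' @param n_replicates bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param min_shared per-pair shared-locus floor (see
#'   [weighted_p_distance()]).
#' @return a rooted `phylo` with integer percentage `node.label`s (empty
#'   for the root and trivial nodes) and attributes `support_table`
#'   (data.frame key/support) and `n_redrawn`.
#' @export
bootstrap_support <- function(gm, n_replicates = 1000, seed = 1,
                              min_shared = 50) {
  wd <- weighted_p_distance(gm, min_shared)
  base <- neighbor_joining(wd)
  rooted <- midpoint_root(base)
  keys <- tree_bipartitions_keys(base)
  counts <- stats::setNames(numeric(length(keys)), keys)
  set.seed(seed)
  L <- n_snps(gm)
  n_done <- 0L; n_redrawn <- 0L
  while (n_done < n_replicates) {
    idx <- sample.int(L, L, replace = TRUE)
    res <- wpd_core(gm$dosage[, idx, drop = FALSE])
    d <- res$d
    off <- row(d) != col(d)
    if (any(res$shared[off] < min_shared) || any(is.na(d[off]))) {
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 10L * n_replicates)
        stop("too many bootstrap replicates with undefined pairs")
      next
    }
    rownames(d) <- colnames(d) <- gm$samples$id
    rep_keys <- tree_bipartitions_keys(neighbor_joining(d))
    hitk <- keys[keys %in% rep_keys]
    counts[hitk] <- counts[hitk] + 1
    n_done <- n_done + 1L
  }
  support <- 100 * counts / n_replicates
  # map supports onto the rooted tree's internal nodes
  n <- length(rooted$tip.label)
  ref <- min(rooted$tip.label)
  labels_all <- rooted$tip.label
  node_lab <- character(rooted$Nnode)
  clades <- clade_tip_sets(rooted)
  for (k in seq_len(rooted$Nnode)) {
    node <- n + k
    tips <- clades[[node]]
    if (ref %in% tips) tips <- setdiff(labels_all, tips)
    if (length(tips) < 2L || length(tips) > n - 2L) {
      node_lab[k] <- ""
      next
    }
    key <- paste(sort(tips), collapse = "|")
    node_lab[k] <- if (key %in% names(support))
      as.character(round(support[[key]])) else ""
  }
  rooted$node.label <- node_lab
  attr(rooted, "support_table") <- data.frame(
    key = names(support), support = as.numeric(support),
    stringsAsFactors = FALSE)
  attr(rooted, "n_redrawn") <- n_redrawn
  rooted
}

# tip labels below every node (indexed by node id)
clade_tip_sets <- function(phy) {
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(n)) sets[[i]] <- phy$tip.label[i]
  ord <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}
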