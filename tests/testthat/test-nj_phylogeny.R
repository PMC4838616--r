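coph <- function(phy) {
  d <- ape::cophenetic.phylo(phy)
  d[order(rownames(d)), order(colnames(d))]
}

test_that("weighted p-distance equals the brute-force double loop", {
  set.seed(401)
  dos <- matrix(sample(c(0L, 1L, 2L, NA), 20 * 300, replace = TRUE,
                       prob = c(0.35, 0.2, 0.35, 0.1)), 20, 300)
  dos <- dos[, colSums(!is.na(dos)) > 0]
  gm <- toy_gm(dos)
  wd <- weighted_p_distance(gm, min_shared = 10)
  for (i in 1:19) for (j in (i + 1):20)
    expect_equal(wd$d[i, j], brute_wpd(dos[i, ], dos[j, ]),
                 tolerance = 1e-12)
  expect_true(isSymmetric(wd$d))
  expect_equal(unname(diag(wd$d)), rep(0, 20))
  # worked example: hom-ref vs het at 1 of 10 shared loci -> 0.05
  g1 <- rep(0L, 10); g2 <- c(1L, rep(0L, 9))
  gm2 <- toy_gm(rbind(g1, g2))
  expect_equal(weighted_p_distance(gm2, min_shared = 5)$d[1, 2], 0.05)
  # identical samples -> 0
  gm3 <- toy_gm(rbind(g1, g1))
  expect_equal(weighted_p_distance(gm3, min_shared = 5)$d[1, 2], 0)
  # sparse pairs are undefined
  g4 <- c(0L, rep(NA_integer_, 9))
  gm4 <- toy_gm(rbind(g1, g4))
  expect_true(is.na(weighted_p_distance(gm4, min_shared = 5)$d[1, 2]))
})

test_that("NJ exactly recovers additive trees on 4-8 taxa", {
  set.seed(402)
  for (n_taxa in 4:8) {
    for (rep in 1:5) {
      true <- ape::rtree(n_taxa, br = function(k) runif(k, 0.05, 1))
      true$tip.label <- paste0("t", seq_len(n_taxa))
      d <- ape::cophenetic.phylo(true)
      d <- d[sample(n_taxa), , drop = FALSE][, rownames(d), drop = FALSE]
      d <- d[, rownames(d)]
      est <- neighbor_joining(d)
      expect_equal(ape::dist.topo(ape::unroot(true), est), 0,
                   ignore_attr = TRUE)
      expect_equal(coph(est), coph(true), tolerance = 1e-9)
    }
  }
})

test_that("NJ agrees with an independent implementation on random matrices", {
  set.seed(403)
  for (rep in 1:5) {
    n <- 10
    x <- matrix(runif(n * 25), n)
    d <- as.matrix(dist(x))
    rownames(d) <- colnames(d) <- paste0("s", 1:n)
    mine <- neighbor_joining(d)
    ref <- ape::nj(as.dist(d))
    expect_equal(ape::dist.topo(mine, ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("input order does not change the topology", {
  set.seed(404)
  n <- 12
  x <- matrix(runif(n * 30), n)
  d <- as.matrix(dist(x))
  rownames(d) <- colnames(d) <- paste0("s", 1:n)
  t1 <- neighbor_joining(d)
  perm <- sample(n)
  t2 <- neighbor_joining(d[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
})

test_that("undefined pairs block tree building with advice", {
  d <- matrix(c(0, 1, NA, 1, 0, 1, NA, 1, 0), 3)
  rownames(d) <- colnames(d) <- c("a", "b", "c")
  expect_error(neighbor_joining(d), "remove sparse samples")
})

test_that("midpoint rooting is equidistant from the two farthest leaves", {
  set.seed(405)
  for (rep in 1:10) {
    phy <- ape::unroot(ape::rtree(sample(4:15, 1),
                                  br = function(k) runif(k, 0.01, 2)))
    rooted <- midpoint_root(phy)
    n <- length(rooted$tip.label)
    dd <- ape::dist.nodes(rooted)
    td <- dd[1:n, 1:n]
    far <- which(td == max(td), arr.ind = TRUE)[1, ]
    root <- n + 1L
    expect_equal(dd[root, far[1]], dd[root, far[2]], tolerance = 1e-9)
    # tips and branch lengths preserved
    expect_equal(sum(rooted$edge.length), sum(phy$edge.length),
                 tolerance = 1e-9)
    expect_setequal(rooted$tip.label, phy$tip.label)
  }
  # caterpillar with one long terminal branch: root bisects that branch
  cat_tree <- ape::read.tree(text = "(((a:0.1,b:0.1):0.1,c:0.1):0.1,d:10);")
  rooted <- midpoint_root(ape::unroot(cat_tree))
  n <- length(rooted$tip.label)
  dd <- ape::dist.nodes(rooted)
  expect_equal(dd[n + 1L, which(rooted$tip.label == "d")],
               max(dd[1:n, 1:n]) / 2, tolerance = 1e-9)
  # symmetric quartet: root on the central edge
  q <- ape::read.tree(text = "((a:1,b:1):0.5,(c:1,d:1):0.5);")
  rooted_q <- midpoint_root(ape::unroot(q))
  dd_q <- ape::dist.nodes(rooted_q)
  expect_equal(unname(dd_q[5, 1:4]), rep(1.5, 4), tolerance = 1e-9)
  expect_error(midpoint_root(ape::read.tree(text = "((a:0,b:0):0,c:0);")),
               "zero")
})

# normalized split key, matching the package convention (the side not
# containing the lexicographically smallest tip label)
split_key <- function(tree, tips, all_ids) {
  if (min(all_ids) %in% tips) tips <- setdiff(all_ids, tips)
  paste(sort(tips), collapse = "|")
}

test_that("bootstrap: diverged groups get high support, star-like data low", {
  cfg <- quick_cfg(n_samples = c(WE = 12, WA = 12, SP = 12),
                   fst = c(WE = 0.4, WA = 0.4, SP = 0.4),
                   n_snps = c(A = 400, C = 600), seed = 406)
  gm <- simulate_genotypes(cfg)
  tree <- bootstrap_support(gm, n_replicates = 100, seed = 407,
                            min_shared = 50)
  st <- attr(tree, "support_table")
  ids <- gm$samples$id
  for (pop in c("WE", "WA", "SP")) {
    key <- split_key(tree, ids[gm$samples$subpop == pop], ids)
    expect_true(key %in% st$key)
    expect_gte(st$support[st$key == key], 95)
  }
  # groups are monophyletic in the base tree
  expect_true(ape::is.monophyletic(tree, ids[gm$samples$subpop == "SP"]))
  # unstructured panel: supports are low on average
  cfg0 <- quick_cfg(n_samples = c(WE = 24), fst = c(WE = 0),
                    n_snps = c(A = 150, C = 250), seed = 408)
  gm0 <- simulate_genotypes(cfg0)
  tree0 <- bootstrap_support(gm0, n_replicates = 100, seed = 409)
  st0 <- attr(tree0, "support_table")
  expect_lt(mean(st0$support), 60)
})

test_that("bootstrap supports are seed-stable within Monte-Carlo tolerance", {
  cfg <- quick_cfg(n_samples = c(WE = 10, WA = 10, SP = 10),
                   fst = c(WE = 0.35, WA = 0.35, SP = 0.35),
                   n_snps = c(A = 250, C = 350), seed = 410)
  gm <- simulate_genotypes(cfg)
  t1 <- bootstrap_support(gm, n_replicates = 200, seed = 1)
  t2 <- bootstrap_support(gm, n_replicates = 200, seed = 2)
  s1 <- attr(t1, "support_table")
  s2 <- attr(t2, "support_table")
  m <- merge(s1, s2, by = "key")
  # strongly supported splits are stable; middling splits carry binomial
  # noise of a few points at 200 replicates
  strong <- m$support.x >= 90
  expect_true(any(strong))
  expect_lt(max(abs(m$support.x - m$support.y)[strong]), 10)
  expect_lt(mean(abs(m$support.x - m$support.y)), 6)
  # same seed reproduces exactly
  t1b <- bootstrap_support(gm, n_replicates = 200, seed = 1)
  expect_identical(attr(t1, "support_table"), attr(t1b, "support_table"))
})
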