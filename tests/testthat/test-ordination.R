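test_that("unweighted UniFrac matches hand-enumerated branch fractions", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(unweightedUnifrac(c("A", "B"), c("A", "B"), tr), 0)
  expect_equal(unweightedUnifrac(c("A", "B"), "C", tr), 1)
  expect_equal(unweightedUnifrac(c("A", "B"), c("A", "C"), tr), 0.6)
  expect_equal(unweightedUnifrac(c("A", "C"), c("A", "B"), tr), 0.6)

  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  expect_equal(unweightedUnifrac(c("a", "b"), c("c", "d"), star), 1)
  expect_error(unweightedUnifrac("a", "zz", star), "zz")
})

test_that("weighted UniFrac moves mass along branches", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  a <- c(a = 1); b <- c(b = 1)
  expect_equal(weightedUnifrac(a, b, star, normalized = TRUE), 1)
  expect_equal(weightedUnifrac(a, b, star, normalized = FALSE), 2)
  expect_equal(weightedUnifrac(b, a, star), weightedUnifrac(a, b, star))
  p <- c(a = 0.5, b = 0.5)
  expect_equal(weightedUnifrac(p, p, star), 0)
  expect_error(weightedUnifrac(c(a = 0.5), b, star), "sum to 1")
})

test_that("the UniFrac matrix agrees with the pairwise operations and phyloseq", {
  ds <- generateDataset(syntheticSpec(groups = c(A = 4L, B = 4L), n_taxa = 12,
                                      base_log_mean = rep(0, 12), seed = 31))
  tab <- totalSumScale(ds$table)
  tr <- ds$tree
  Du <- unifracMatrix(tab, tr, "unweighted")
  Dw <- unifracMatrix(tab, tr, "weighted", normalized = TRUE)
  v <- abundances(tab)
  i <- "A_01"; j <- "B_02"
  expect_equal(Du[i, j],
               unweightedUnifrac(colnames(v)[v[i, ] > 0],
                                 colnames(v)[v[j, ] > 0], tr))
  expect_equal(Dw[i, j], weightedUnifrac(v[i, ], v[j, ], tr))
  expect_true(all(Du >= 0 & Du <= 1) && all(Dw >= 0 & Dw <= 1 + 1e-12))
  expect_equal(max(abs(Du - t(Du))), 0)

  # independent implementation cross-check
  suppressMessages({
    ps <- phyloseq::phyloseq(
      phyloseq::otu_table(t(v), taxa_are_rows = TRUE),
      phyloseq::phy_tree(tr))
    ps_u <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))
    ps_w <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                        normalized = TRUE))
  })
  expect_equal(Du, ps_u[rownames(Du), colnames(Du)], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(Dw, ps_w[rownames(Dw), colnames(Dw)], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("PCoA reconstructs Euclidean configurations exactly", {
  set.seed(9)
  X <- matrix(rnorm(20), 10, 2,
              dimnames = list(paste0("s", 1:10), NULL))
  D <- euclideanD(X)
  ord <- pcoa(D)
  Drec <- as.matrix(dist(ord$points))
  expect_lt(max(abs(Drec - D)), 1e-8)
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))
  expect_lt(min(ord$eigenvalues), 1e-8 * max(ord$eigenvalues))  # no big negatives

  # against the classical scaling reference
  cm <- stats::cmdscale(D, k = 2, eig = TRUE)
  expect_equal(abs(ord$points[, 1:2]), abs(cm$points), tolerance = 1e-8,
               ignore_attr = TRUE)

  # three equidistant samples: two equal positive axes, third ~ 0
  D3 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(D3) <- 0
  e3 <- pcoa(D3)$eigenvalues
  expect_equal(e3[1], e3[2], tolerance = 1e-10)
  expect_lt(abs(e3[3]), 1e-10)

  # a duplicated sample lands on the same coordinates
  Xd <- rbind(X, dup = X[1, ])
  od <- pcoa(euclideanD(Xd))
  expect_lt(max(abs(od$points["s1", ] - od$points["dup", ])), 1e-8)

  expect_error(pcoa(matrix(0, 2, 2, dimnames = list(1:2, 1:2))), "3")
})

test_that("PERMANOVA separates planted clusters and matches vegan's F", {
  # exhaustive oracle on n=6: the observed bipartition uniquely maximizes F
  pts <- matrix(c(0, 0.1, 0.2, 10, 10.1, 10.2), ncol = 1,
                dimnames = list(paste0("s", 1:6), NULL))
  D <- euclideanD(pts)
  labs <- rep(c("a", "b"), each = 3)
  res <- permanova(D, labs, n_permutations = 999, seed = 1)
  combos <- utils::combn(6, 3)
  fs <- apply(combos, 2, function(idx) {
    l <- rep("b", 6); l[idx] <- "a"
    MicrobeClubs:::permanovaF(D^2, l)
  })
  expect_equal(max(fs), res$pseudo_F, tolerance = 1e-12)
  expect_equal(sum(fs >= res$pseudo_F - 1e-9), 2)  # the split and its mirror
  expect_lt(res$p_value, 0.15)  # only relabelings recreating the split tie

  # with clusters big enough that a permutation almost never recreates the
  # split, p hits its floor 1/(n_permutations + 1)
  set.seed(2)
  X <- rbind(matrix(rnorm(20, 0, 0.05), 10),
             matrix(rnorm(20, 5, 0.05), 10))
  rownames(X) <- paste0("s", 1:20)
  big <- permanova(euclideanD(X), rep(c("a", "b"), each = 10),
                   n_permutations = 999, seed = 3)
  expect_equal(big$p_value, 1 / 1000)

  expect_identical(permanova(D, labs, seed = 7)$p_value,
                   permanova(D, labs, seed = 7)$p_value)
  expect_error(permanova(D, c("a", rep("b", 5))), "singleton")

  set.seed(4)
  Y <- matrix(rnorm(36), 12, 3, dimnames = list(paste0("s", 1:12), NULL))
  gl <- rep(c("x", "y", "z"), each = 4)
  ref <- vegan::adonis2(stats::dist(Y) ~ g,
                        data = data.frame(g = gl), permutations = 99)
  expect_equal(permanova(euclideanD(Y), gl, 99, seed = 5)$pseudo_F,
               ref$F[1], tolerance = 1e-10)
})

test_that("PERMANOVA p-values are uniform under the null", {
  set.seed(31)
  ps <- replicate(300, {
    X <- matrix(rnorm(24), 12, 2, dimnames = list(paste0("s", 1:12), NULL))
    permanova(euclideanD(X), rep(c("a", "b"), each = 6), 99,
              seed = sample.int(1e6, 1))$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("dispersion measures distance-to-center with the expected geometry", {
  # identical samples disperse to zero
  X0 <- matrix(1, 4, 2, dimnames = list(paste0("s", 1:4), NULL))
  d0 <- dispersion(euclideanD(X0), rep(c("a", "b"), 2))
  expect_lt(max(d0$group_means), 1e-8)

  # inflating a cluster x3 scales its dispersion x3
  set.seed(12)
  base <- matrix(rnorm(24), 12, 2)
  X <- rbind(base, base * 3)
  rownames(X) <- paste0("s", 1:24)
  labs <- rep(c("a", "b"), each = 12)
  d <- dispersion(euclideanD(X), labs)
  expect_equal(d$group_means[["b"]] / d$group_means[["a"]], 3,
               tolerance = 1e-6)

  # centroid and spatial median coincide for a symmetric point set
  sq <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE,
               dimnames = list(paste0("s", 1:4), NULL))
  sym <- rbind(sq, sq + 10)
  rownames(sym) <- paste0("s", 1:8)
  l2 <- rep(c("a", "b"), each = 4)
  dm <- dispersion(euclideanD(sym), l2, center = "median")
  dc <- dispersion(euclideanD(sym), l2, center = "centroid")
  expect_equal(dm$group_means, dc$group_means, tolerance = 1e-6)

  # against the reference implementation (spatial medians, Euclidean input)
  set.seed(13)
  Z <- matrix(rnorm(60), 20, 3, dimnames = list(paste0("s", 1:20), NULL))
  lz <- rep(c("a", "b"), each = 10)
  ours <- dispersion(euclideanD(Z), lz, center = "median")
  ref <- vegan::betadisper(stats::dist(Z), lz, type = "median")
  expect_equal(ours$group_means,
               tapply(ref$distances, lz, mean), tolerance = 1e-4,
               ignore_attr = TRUE)

  expect_error(dispersion(euclideanD(sym), c("a", rep("b", 7))), "singleton")
})
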