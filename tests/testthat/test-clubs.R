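mkEstimate <- function(rho, pvals) {
  new("CorrelationEstimate", rho = rho, pvals = pvals,
      n_inner = 1L, n_boot = 100L, seed = 1L)
}

test_that("network construction applies the p and |rho| filters", {
  taxa <- paste0("t", 1:4)
  rho <- diag(4); dimnames(rho) <- list(taxa, taxa)
  p <- matrix(1, 4, 4, dimnames = list(taxa, taxa))
  rel <- totalSumScale(otuTable(matrix(1:16, 4, 4,
    dimnames = list(paste0("s", 1:4), taxa))))

  net0 <- buildNetwork(mkEstimate(rho, p), rel)
  expect_equal(nrow(networkEdges(net0)), 0)
  expect_equal(nrow(networkNodes(net0)), 4)

  rho[1, 2] <- rho[2, 1] <- 0.9
  p[1, 2] <- p[2, 1] <- 0.01
  net1 <- buildNetwork(mkEstimate(rho, p), rel)
  expect_equal(nrow(networkEdges(net1)), 1)
  expect_equal(networkEdges(net1)$correlation, 0.9)

  rho[3, 4] <- rho[4, 3] <- 0.3
  p[3, 4] <- p[4, 3] <- 0.001
  net2 <- buildNetwork(mkEstimate(rho, p), rel, min_abs_r = 0.5)
  expect_equal(nrow(networkEdges(net2)), 1)  # significant 0.3 edge dropped

  expect_equal(networkNodes(net1)$abundance,
               unname(colMeans(abundances(rel))))
  bad <- rel[, 1:3]
  expect_error(buildNetwork(mkEstimate(rho, p), bad), "mismatch")
  no_p <- new("CorrelationEstimate", rho = rho,
              pvals = matrix(numeric(0), 0, 0),
              n_inner = 1L, n_boot = 0L, seed = 1L)
  expect_error(buildNetwork(no_p, rel), "no p-values")
})

test_that("MCL keeps disjoint components apart and merges complete graphs", {
  tri2 <- rbind(cliqueEdges(c("a", "b", "c"), 0.8),
                cliqueEdges(c("d", "e", "f"), 0.8))
  cl <- mclCluster(mkNetwork(tri2, letters[1:6]))
  m <- membership(cl)
  expect_equal(length(unique(m)), 2)
  expect_length(unique(m[c("a", "b", "c")]), 1)
  expect_length(unique(m[c("d", "e", "f")]), 1)
  expect_true(cl@converged)

  k5 <- mclCluster(mkNetwork(cliqueEdges(paste0("n", 1:5), 0.6),
                             paste0("n", 1:5)))
  expect_equal(length(unique(membership(k5))), 1)

  # isolated node becomes its own singleton cluster
  iso <- mclCluster(mkNetwork(cliqueEdges(c("a", "b", "c"), 0.8),
                              c("a", "b", "c", "lone")))
  expect_equal(sum(membership(iso) == membership(iso)["lone"]), 1)
})

test_that("MCL recovers the modularity-optimal split of a two-block graph", {
  blockA <- paste0("a", 1:6); blockB <- paste0("b", 1:6)
  edges <- rbind(cliqueEdges(blockA, 0.8), cliqueEdges(blockB, 0.8),
                 data.frame(from = "a1", to = "b1", correlation = 0.1))
  nodes <- c(blockA, blockB)
  cl <- mclCluster(mkNetwork(edges, nodes))
  m <- membership(cl)
  expect_equal(length(unique(m)), 2)

  A <- matrix(0, 12, 12, dimnames = list(nodes, nodes))
  A[cbind(edges$from, edges$to)] <- edges$correlation
  A <- A + t(A)
  oracle <- bestBipartition(A)$side
  expect_equal(length(unique(m[oracle == 0])), 1)
  expect_equal(length(unique(m[oracle == 1])), 1)
  expect_false(m[which(oracle == 0)[1]] == m[which(oracle == 1)[1]])
})

test_that("MCL is deterministic and invariant to node relabeling", {
  set.seed(77)
  nodes <- paste0("n", 1:15)
  prs <- t(utils::combn(nodes, 2))
  keep <- runif(nrow(prs)) < 0.25
  edges <- data.frame(from = prs[keep, 1], to = prs[keep, 2],
                      correlation = runif(sum(keep), 0.2, 0.9))
  net <- mkNetwork(edges, nodes)
  m1 <- membership(mclCluster(net))
  m2 <- membership(mclCluster(net))
  expect_identical(m1, m2)

  perm <- sample(nodes)
  net_p <- mkNetwork(edges, perm)  # same edges, different node order
  m3 <- membership(mclCluster(net_p))
  # same partition: co-membership must agree for every pair
  co <- function(m, a, b) unname(m[a] == m[b])
  for (k in 1:40) {
    ab <- sample(nodes, 2)
    expect_equal(co(m1, ab[1], ab[2]), co(m3, ab[1], ab[2]))
  }

  # clusters never span disconnected components of the positive subgraph
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                     vertices = nodes)
  comp <- igraph::components(g)$membership
  for (cl_id in unique(m1)) {
    members <- names(m1)[m1 == cl_id]
    expect_length(unique(comp[members]), 1)
  }
})

test_that("club statistics report size and tightness over network edges", {
  cl4 <- cliqueEdges(paste0("k", 1:4), 0.8)
  net <- mkNetwork(cl4, paste0("k", 1:4))
  clustering <- mclCluster(net)
  soc <- clubStatistics(net, clustering)
  expect_equal(nrow(soc), 1)
  expect_equal(soc$size, 4)
  expect_equal(soc$tightness_mean, 0.8)
  expect_equal(soc$tightness_sd, 0)
  expect_equal(soc$n_edges, 6)

  # singleton clusters yield no social clubs
  lonely <- mkNetwork(NULL, c("x", "y", "z"))
  soc0 <- clubStatistics(lonely, mclCluster(lonely))
  expect_equal(nrow(soc0), 0)

  # all-pairs tightness via the correlation matrix
  taxa <- paste0("k", 1:4)
  rho <- matrix(0.5, 4, 4, dimnames = list(taxa, taxa)); diag(rho) <- 1
  soc_all <- clubStatistics(net, clustering, rho = rho)
  expect_equal(soc_all$tightness_mean, 0.5)
})

test_that("rival clubs require enough strongly negative cross edges", {
  a <- paste0("a", 1:3); b <- paste0("b", 1:3)
  grid <- expand.grid(from = a, to = b, stringsAsFactors = FALSE)
  edges <- rbind(cliqueEdges(a, 0.7), cliqueEdges(b, 0.7),
                 cbind(grid, correlation = -0.8))
  net <- mkNetwork(edges, c(a, b))
  clustering <- mclCluster(net)
  riv <- rivalClubs(net, clustering)
  expect_equal(nrow(riv), 1)
  expect_equal(riv$mean_correlation, -0.8)
  expect_equal(riv$n_edges, 9)

  # positive bridges are not rivalry
  edges2 <- rbind(cliqueEdges(a, 0.7), cliqueEdges(b, 0.7),
                  cbind(grid[1:4, ], correlation = 0.5))
  net2 <- mkNetwork(edges2, c(a, b))
  expect_equal(nrow(rivalClubs(net2, mclCluster(net2))), 0)

  # too few negative edges
  edges3 <- rbind(cliqueEdges(a, 0.7), cliqueEdges(b, 0.7),
                  cbind(grid[1:2, ], correlation = -0.9))
  net3 <- mkNetwork(edges3, c(a, b))
  expect_equal(nrow(rivalClubs(net3, mclCluster(net3))), 0)

  # a weak negative mean does not qualify
  edges4 <- rbind(cliqueEdges(a, 0.7), cliqueEdges(b, 0.7),
                  cbind(grid, correlation = -0.2))
  net4 <- mkNetwork(edges4, c(a, b))
  expect_equal(nrow(rivalClubs(net4, mclCluster(net4))), 0)
})

test_that("heatmap ordering restores block structure", {
  # identity clustering: stable order by taxon id
  taxa <- c("delta", "alpha", "charlie", "bravo")
  rho <- diag(4); dimnames(rho) <- list(taxa, taxa)
  singletons <- new("ClubClustering",
                    membership = stats::setNames(0:3, taxa),
                    converged = TRUE, n_iter = 1L)
  est <- mkEstimate(rho, matrix(1, 4, 4, dimnames = list(taxa, taxa)))
  expect_identical(heatmapOrder(est, singletons), sort(taxa))

  # larger cluster comes first
  taxa8 <- paste0("t", 1:8)
  rho8 <- diag(8); dimnames(rho8) <- list(taxa8, taxa8)
  memb <- stats::setNames(c(rep(0L, 3), rep(1L, 5)), taxa8)
  cl8 <- new("ClubClustering", membership = memb, converged = TRUE,
             n_iter = 1L)
  ord <- heatmapOrder(mkEstimate(rho8, matrix(1, 8, 8,
    dimnames = list(taxa8, taxa8))), cl8)
  expect_setequal(ord[1:5], taxa8[4:8])

  # a shuffled block-diagonal matrix is restored to leading bright blocks
  set.seed(5)
  n <- 12; taxa12 <- paste0("x", sprintf("%02d", 1:n))
  R <- diag(n)
  R[1:5, 1:5] <- 0.8; R[6:9, 6:9] <- 0.6; diag(R) <- 1
  shuf <- sample(n)
  Rs <- R[shuf, shuf]
  dimnames(Rs) <- list(taxa12, taxa12)
  memb12 <- integer(n)
  memb12[order(shuf)[1:5]] <- 1L   # members of the 0.8 block after shuffle
  memb12[order(shuf)[6:9]] <- 2L
  memb12[memb12 == 0] <- c(0L, 3L, 4L)[seq_len(sum(memb12 == 0))]
  # relabel dense from 0 by decreasing size
  memb12 <- stats::setNames(as.integer(factor(memb12,
    levels = names(sort(table(memb12), decreasing = TRUE)))) - 1L, taxa12)
  cl12 <- new("ClubClustering", membership = memb12, converged = TRUE,
              n_iter = 1L)
  ord12 <- heatmapOrder(mkEstimate(Rs, matrix(1, n, n,
    dimnames = list(taxa12, taxa12))), cl12)
  Ro <- Rs[ord12, ord12]
  lead <- mean(Ro[1:5, 1:5][upper.tri(diag(5))])
  off <- mean(Ro[1:5, 6:n])
  expect_gt(lead, off + 0.5)
})
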