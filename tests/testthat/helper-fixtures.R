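# Shared fixtures, built in code at test time.

# small counts table with two groups
tinyCounts <- function() {
  m <- matrix(c(2, 3, 5, 0,
                1, 0, 9, 4,
                4, 4, 0, 2,
                0, 5, 5, 5),
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("t", 1:4)))
  otuTable(m, kind = "counts",
           groups = c(s1 = "g1", s2 = "g1", s3 = "g2", s4 = "g2"))
}

# build a CoNetwork directly from an edge table
mkNetwork <- function(edges, nodes, abundance = 0.01) {
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        correlation = numeric(), p_value = numeric(),
                        stringsAsFactors = FALSE)
  } else if (!"p_value" %in% names(edges)) edges$p_value <- 0.01
  new("CoNetwork",
      nodes = data.frame(taxon = nodes, abundance = abundance,
                         stringsAsFactors = FALSE),
      edges = edges)
}

cliqueEdges <- function(nodes, w) {
  prs <- t(utils::combn(nodes, 2))
  data.frame(from = prs[, 1], to = prs[, 2], correlation = w,
             stringsAsFactors = FALSE)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# exhaustive best weighted-modularity bipartition of a symmetric adjacency
bestBipartition <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  m2 <- sum(A)
  bestQ <- -Inf
  best <- NULL
  for (code in 0:(2^(n - 1) - 1)) {
    side <- c(0L, as.integer(intToBits(code))[seq_len(n - 1)])
    S <- outer(side, side, "==")
    Q <- sum((A - outer(deg, deg) / m2) * S) / m2
    if (Q > bestQ) { bestQ <- Q; best <- side }
  }
  list(Q = bestQ, side = best)
}

# distance matrix of Euclidean points (rows)
euclideanD <- function(X) {
  D <- as.matrix(stats::dist(X))
  dimnames(D) <- list(rownames(X), rownames(X))
  if (is.null(rownames(X)))
    dimnames(D) <- list(paste0("s", seq_len(nrow(X))),
                        paste0("s", seq_len(nrow(X))))
  D
}

# a spec for a single-group panel with one planted club, used in recovery
# checks: D taxa, one block at correlation r, flat base composition
oneClubSpec <- function(n, D, block_size, r, depth, seed) {
  syntheticSpec(groups = c(G = as.integer(n)), n_taxa = D,
                blocks = list(list(taxa = seq_len(block_size), cor = r)),
                base_log_mean = rep(0, D), base_log_sd = rep(1, D),
                depth_range = c(depth, depth), seed = seed)
}

nullSpec <- function(n, D, depth, seed) {
  syntheticSpec(groups = c(G = as.integer(n)), n_taxa = D,
                base_log_mean = rep(0, D), base_log_sd = rep(1, D),
                depth_range = c(depth, depth), seed = seed)
}
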