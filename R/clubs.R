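# Co-occurrence network construction, from-scratch Markov clustering (MCL)
# of the positive-association subgraph, and the social-club / rival-club
# statistics. "Social clubs" are Markov clusters of taxa joined by
# significant positive correlations; "rival clubs" are club pairs connected
# predominantly by significant negative correlations.

#' Build a co-occurrence network from a correlation estimate
#'
#' An edge (i, j) is included iff `p_ij < alpha` and `|rho_ij| >=`
#' `min_abs_r`. Nodes carry their mean relative abundance across samples
#' (the conventional node-size attribute).
#'
#' @param est [CorrelationEstimate-class] with p-values.
#' @param rel_abund relative-kind [OtuTable-class] over the same taxa.
#' @param alpha edge significance level (default 0.05).
#' @param min_abs_r minimum |correlation| for an edge (default 0).
#' @return a [CoNetwork-class].
#' @export
buildNetwork <- function(est, rel_abund, alpha = 0.05, min_abs_r = 0) {
  stopifnot(is(est, "CorrelationEstimate"), is(rel_abund, "OtuTable"))
  p <- pValues(est)
  if (is.null(p)) stop("correlation estimate carries no p-values")
  taxa <- taxonNames(est)
  if (!setequal(taxa, taxonNames(rel_abund)))
    stop("taxa mismatch between correlation estimate and abundance table")
  rho <- correlations(est)
  ab <- colMeans(abundances(rel_abund)[, taxa, drop = FALSE])
  sel <- which(upper.tri(p) & p < alpha & abs(rho) >= min_abs_r, arr.ind = TRUE)
  edges <- data.frame(
    from = taxa[sel[, 1]], to = taxa[sel[, 2]],
    correlation = rho[sel], p_value = p[sel], stringsAsFactors = FALSE)
  nodes <- data.frame(taxon = taxa, abundance = unname(ab),
                      stringsAsFactors = FALSE)
  new("CoNetwork", nodes = nodes, edges = edges[order(edges$from, edges$to), ,
                                                drop = FALSE])
}

#' Markov clustering of the positive-association subgraph
#'
#' Runs MCL on the subgraph of positive edges (negative edges encode
#' avoidance, not flow, and are reserved for rivalry detection): unit
#' self-loops are added, columns are normalized to a stochastic matrix, and
#' the expansion (matrix power), inflation (entry-wise power) and prune steps
#' are iterated until the matrix change falls below `tol` or `max_iter` is
#' reached. Clusters are read off the attractor rows of the limit matrix;
#' attractor systems sharing nodes are merged; a node attracted by several
#' clusters joins the one receiving its largest matrix mass (remaining ties:
#' smallest cluster id). Isolated nodes become singleton clusters. The whole
#' operator is deterministic and invariant to node relabeling.
#'
#' @param network a [CoNetwork-class] (non-empty node set).
#' @param inflation entry-wise power (default 2).
#' @param expansion matrix power (default 2).
#' @param prune entries below this are zeroed each iteration (default 1e-5).
#' @param tol convergence tolerance on the max entry change (default 1e-8).
#' @param max_iter iteration cap; non-convergence yields a warning flag in
#'   the result, not an error.
#' @return a [ClubClustering-class] with dense cluster ids from 0 (ordered by
#'   decreasing size, ties by smallest member name).
#' @export
mclCluster <- function(network, inflation = 2, expansion = 2, prune = 1e-5,
                       tol = 1e-8, max_iter = 100L) {
  stopifnot(is(network, "CoNetwork"))
  nodes <- networkNodes(network)$taxon
  if (!length(nodes)) stop("network has no nodes")
  edges <- networkEdges(network)
  edges <- edges[edges$correlation > 0, , drop = FALSE]
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    A[cbind(edges$from, edges$to)] <- edges$correlation
    A[cbind(edges$to, edges$from)] <- edges$correlation
  }
  diag(A) <- 1  # unit self-loops
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    M_new <- M
    for (k in seq_len(expansion - 1L)) M_new <- M_new %*% M
    M_new <- M_new^inflation
    M_new[M_new < prune] <- 0
    cs <- colSums(M_new)
    cs[cs == 0] <- 1
    M_new <- sweep(M_new, 2, cs, "/")
    delta <- max(abs(M_new - M))
    M <- M_new
    if (delta < tol) { converged <- TRUE; break }
  }
  # attractors: nodes retaining mass on their own diagonal
  attractors <- which(diag(M) > 0)
  if (!length(attractors)) attractors <- seq_len(n)  # degenerate; keep all
  # merge attractor rows whose supports overlap (one attractor system each)
  support <- lapply(attractors, function(a) which(M[a, ] > 0 | seq_len(n) == a))
  comp <- seq_along(attractors)
  repeat {
    changed <- FALSE
    for (i in seq_along(attractors)) for (j in seq_along(attractors)) {
      if (comp[i] != comp[j] &&
          length(intersect(support[[i]], support[[j]]))) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  systems <- split(seq_along(attractors), comp)
  mass <- matrix(0, length(systems), n)  # cluster x node attraction mass
  for (s in seq_along(systems))
    mass[s, ] <- colSums(M[attractors[systems[[s]]], , drop = FALSE])
  assign <- integer(n)
  for (v in seq_len(n)) {
    mv <- mass[, v]
    if (max(mv) <= 0) assign[v] <- NA_integer_  # unattracted: singleton
    else assign[v] <- which(mv == max(mv))[1L]  # ties: smallest cluster id
  }
  singles <- which(is.na(assign))
  if (length(singles))
    assign[singles] <- length(systems) + seq_along(singles)
  # dense ids ordered by decreasing size, ties by smallest member name
  sizes <- table(assign)
  first_member <- vapply(names(sizes), function(cl)
    min(nodes[assign == as.integer(cl)]), "")
  ord <- order(-as.integer(sizes), first_member)
  relabel <- stats::setNames(seq_along(ord) - 1L, names(sizes)[ord])
  mem <- as.integer(relabel[as.character(assign)])
  names(mem) <- nodes
  new("ClubClustering", membership = mem,
      converged = converged, n_iter = it)
}

socialClubIds <- function(clustering, min_club_size) {
  sz <- table(membership(clustering))
  as.integer(names(sz)[sz >= min_club_size])
}

#' Social-club membership and tightness statistics
#'
#' Social clubs are clusters with at least `min_club_size` members.
#' Tightness is the mean and standard deviation of the correlations on
#' intra-club edges present in the network (i.e. pairs that passed the
#' significance filter); with `rho` supplied, tightness is instead computed
#' over all intra-club pairs of the correlation matrix.
#'
#' @param network a [CoNetwork-class].
#' @param clustering a [ClubClustering-class] covering the network nodes.
#' @param min_club_size minimum cluster size to count as a club (default 3).
#' @param rho optional full correlation matrix for all-pairs tightness.
#' @return data.frame with one row per social club: `club`, `size`,
#'   `members` (comma-joined), `tightness_mean`, `tightness_sd`, `n_edges`.
#' @export
clubStatistics <- function(network, clustering, min_club_size = 3,
                           rho = NULL) {
  stopifnot(is(network, "CoNetwork"), is(clustering, "ClubClustering"))
  mem <- membership(clustering)
  nodes <- networkNodes(network)$taxon
  if (!all(nodes %in% names(mem)))
    stop("clustering does not cover every network node")
  edges <- networkEdges(network)
  clubs <- socialClubIds(clustering, min_club_size)
  rows <- lapply(clubs, function(cl) {
    members <- sort(names(mem)[mem == cl])
    if (is.null(rho)) {
      intra <- edges$correlation[mem[edges$from] == cl & mem[edges$to] == cl]
    } else {
      prs <- utils::combn(members, 2L)
      intra <- rho[cbind(prs[1L, ], prs[2L, ])]
    }
    data.frame(club = cl, size = length(members),
               members = paste(members, collapse = ","),
               tightness_mean = if (length(intra)) mean(intra) else NA_real_,
               tightness_sd = if (length(intra) > 1) stats::sd(intra) else 0,
               n_edges = length(intra), stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(club = integer(), size = integer(),
                      members = character(), tightness_mean = numeric(),
                      tightness_sd = numeric(), n_edges = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Rival club pairs
#'
#' For each unordered pair of social clubs, collects the (significant)
#' negative edges running between them; the pair is rival iff there are at
#' least `min_rival_edges` such edges and their mean correlation is at most
#' `rival_threshold`.
#'
#' @param network a [CoNetwork-class].
#' @param clustering a [ClubClustering-class] covering the network nodes.
#' @param rival_threshold mean-correlation ceiling (default -0.4).
#' @param min_rival_edges minimum number of negative cross edges (default 3).
#' @param min_club_size passed through to the social-club definition.
#' @return data.frame with one row per rival pair: `club_a`, `club_b`,
#'   `mean_correlation`, `n_edges`.
#' @export
rivalClubs <- function(network, clustering, rival_threshold = -0.4,
                       min_rival_edges = 3, min_club_size = 3) {
  stopifnot(is(network, "CoNetwork"), is(clustering, "ClubClustering"))
  mem <- membership(clustering)
  edges <- networkEdges(network)
  clubs <- socialClubIds(clustering, min_club_size)
  out <- list()
  if (length(clubs) >= 2) {
    prs <- utils::combn(clubs, 2L)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1L, k]; b <- prs[2L, k]
      cross <- (mem[edges$from] == a & mem[edges$to] == b) |
               (mem[edges$from] == b & mem[edges$to] == a)
      neg <- edges$correlation[cross & edges$correlation < 0]
      if (length(neg) >= min_rival_edges && mean(neg) <= rival_threshold)
        out[[length(out) + 1L]] <- data.frame(
          club_a = a, club_b = b, mean_correlation = mean(neg),
          n_edges = length(neg), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(club_a = integer(), club_b = integer(),
                      mean_correlation = numeric(), n_edges = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Taxon ordering that blocks the correlation heatmap by cluster
#'
#' Returns a permutation of the taxa placing same-cluster taxa contiguously:
#' clusters ordered by decreasing size (ties by smallest member name), and
#' taxa within a cluster by decreasing mean intra-cluster correlation (ties
#' by name). Applying the permutation to the rows and columns of the
#' correlation matrix produces the block-diagonal "bright squares along the
#' diagonal" heatmap layout.
#'
#' @param est a [CorrelationEstimate-class].
#' @param clustering a [ClubClustering-class] over the estimate's taxa.
#' @return character vector: the taxa in heatmap order.
#' @export
heatmapOrder <- function(est, clustering) {
  stopifnot(is(est, "CorrelationEstimate"), is(clustering, "ClubClustering"))
  rho <- correlations(est)
  mem <- membership(clustering)
  stopifnot(all(taxonNames(est) %in% names(mem)))
  mem <- mem[taxonNames(est)]
  sz <- table(mem)
  first_member <- vapply(names(sz), function(cl)
    min(names(mem)[mem == as.integer(cl)]), "")
  cl_order <- names(sz)[order(-as.integer(sz), first_member)]
  unlist(lapply(cl_order, function(cl) {
    members <- names(mem)[mem == as.integer(cl)]
    if (length(members) == 1L) return(members)
    mean_intra <- vapply(members, function(tx)
      mean(rho[tx, setdiff(members, tx)]), 1)
    members[order(-mean_intra, members)]
  }), use.names = FALSE)
}
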