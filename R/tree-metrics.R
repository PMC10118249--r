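# Phylogeny-aware metrics: Faith's PD and pairwise UniFrac, built on a shared
# branch x leaf incidence decomposition of a rooted ape::phylo tree.

# leaves (tip labels) descending through each edge; rows follow tree$edge.
branchIncidence <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  M <- matrix(FALSE, nn, nt, dimnames = list(NULL, tree$tip.label))
  M[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    M[p, ] <- M[p, ] | M[ch, ]
  }
  inc <- M[tree$edge[, 2L], , drop = FALSE]
  list(incidence = inc,
       lengths = if (is.null(tree$edge.length))
         rep(0, nrow(tree$edge)) else tree$edge.length)
}

checkLeaves <- function(taxa, tree) {
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop("taxa absent from the tree: ", paste(unknown, collapse = ", "))
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree connecting the root and all
#' present leaves, i.e. the summed lengths of every branch with at least one
#' present descendant.
#'
#' @param present_taxa character vector of present leaf names (>= 1).
#' @param tree rooted [ape::phylo] with branch lengths.
#' @return PD >= 0; equals the total tree length when all leaves are present.
#' @export
faithPD <- function(present_taxa, tree) {
  if (!length(present_taxa)) stop("faithPD needs at least one present taxon")
  checkLeaves(present_taxa, tree)
  bi <- branchIncidence(tree)
  on_path <- rowSums(bi$incidence[, present_taxa, drop = FALSE]) > 0
  sum(bi$lengths[on_path])
}

#' Unweighted UniFrac distance between two communities
#'
#' Fraction of branch length unique to one community's subtree among the
#' branch length in either subtree; 0 for identical presence sets, 1 for
#' communities sharing no branches.
#'
#' @param a,b character vectors of present leaf names (non-empty).
#' @param tree rooted [ape::phylo] with branch lengths.
#' @return distance in \[0, 1\].
#' @export
unweightedUnifrac <- function(a, b, tree) {
  if (!length(a) || !length(b)) stop("both communities must be non-empty")
  checkLeaves(c(a, b), tree)
  bi <- branchIncidence(tree)
  inA <- rowSums(bi$incidence[, a, drop = FALSE]) > 0
  inB <- rowSums(bi$incidence[, b, drop = FALSE]) > 0
  union_len <- sum(bi$lengths[inA | inB])
  if (union_len == 0) return(0)
  sum(bi$lengths[xor(inA, inB)]) / union_len
}

#' Weighted UniFrac distance between two communities
#'
#' Raw form: `sum_i b_i * |A_i - B_i|` over branches, where `A_i` is the
#' proportion of community a descending through branch i. The normalized form
#' divides by `sum_i b_i * (A_i + B_i)` and lies in \[0, 1\].
#'
#' @param a,b numeric proportion vectors named by leaf, each summing to 1
#'   (tolerance 1e-6); leaves absent from a vector carry 0.
#' @param tree rooted [ape::phylo] with branch lengths.
#' @param normalized logical (default TRUE).
#' @return the distance.
#' @export
weightedUnifrac <- function(a, b, tree, normalized = TRUE) {
  toVec <- function(p) {
    if (is.null(names(p))) stop("proportion vectors must be named by leaf")
    checkLeaves(names(p), tree)
    if (abs(sum(p) - 1) > 1e-6) stop("proportions must sum to 1")
    v <- stats::setNames(numeric(length(tree$tip.label)), tree$tip.label)
    v[names(p)] <- p
    v
  }
  va <- toVec(a); vb <- toVec(b)
  bi <- branchIncidence(tree)
  A <- as.numeric(bi$incidence %*% va)
  B <- as.numeric(bi$incidence %*% vb)
  raw <- sum(bi$lengths * abs(A - B))
  if (!normalized) return(raw)
  denom <- sum(bi$lengths * (A + B))
  if (denom == 0) return(0)
  raw / denom
}

#' Pairwise UniFrac distance matrix over the samples of a table
#'
#' @param table an [OtuTable-class]; taxa must be tree leaves. For
#'   `"weighted"`, rows are renormalized to sum to 1 when `renormalize` is
#'   TRUE (required after prevalence filtering, which leaves row sums < 1).
#' @param tree rooted [ape::phylo].
#' @param method `"unweighted"` or `"weighted"`.
#' @param normalized for weighted UniFrac.
#' @param renormalize divide each row by its sum first (weighted only).
#' @return symmetric distance matrix with sample dimnames.
#' @export
unifracMatrix <- function(table, tree,
                          method = c("unweighted", "weighted"),
                          normalized = TRUE, renormalize = FALSE) {
  stopifnot(is(table, "OtuTable"))
  method <- match.arg(method)
  v <- abundances(table)
  checkLeaves(colnames(v), tree)
  bi <- branchIncidence(tree)
  inc <- bi$incidence[, colnames(v), drop = FALSE]
  len <- bi$lengths
  n <- nrow(v)
  D <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  if (method == "unweighted") {
    Bm <- tcrossprod(inc * 1, (v > 0) * 1) > 0  # branches x samples
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      u <- Bm[, i] | Bm[, j]
      ul <- sum(len[u])
      d <- if (ul == 0) 0 else sum(len[xor(Bm[, i], Bm[, j])]) / ul
      D[i, j] <- D[j, i] <- d
    }
  } else {
    rs <- rowSums(v)
    if (renormalize) v <- v / rs
    else if (any(abs(rs - 1) > 1e-6))
      stop("weighted UniFrac needs rows summing to 1 (or renormalize = TRUE)")
    Mb <- tcrossprod(inc * 1, v)  # branches x samples proportions
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      raw <- sum(len * abs(Mb[, i] - Mb[, j]))
      d <- if (normalized) {
        denom <- sum(len * (Mb[, i] + Mb[, j]))
        if (denom == 0) 0 else raw / denom
      } else raw
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}
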