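#' @import methods
NULL

#' OtuTable: a samples x taxa abundance table with group labels
#'
#' Container for an OTU abundance matrix, either raw read counts
#' (`kind = "counts"`) or total-sum-scaled proportions (`kind = "relative"`),
#' together with an optional per-sample group label (e.g. never / former /
#' active smokers). Rows are samples, columns are taxa; both margins carry
#' unique names.
#'
#' A `"relative"` table produced by [totalSumScale()] has rows summing to 1.
#' Prevalence filtering drops taxa without renormalizing, so filtered relative
#' tables keep their original denominators and row sums may be below 1; the
#' validity check therefore only requires row sums in (0, 1 + 1e-9] for
#' relative tables.
#'
#' @slot values numeric matrix, samples x taxa, all entries >= 0.
#' @slot kind `"counts"` or `"relative"`.
#' @slot groups character vector of group labels named by sample id
#'   (zero-length when no metadata has been attached).
#'
#' @seealso [otuTable()], [abundances()], [sampleGroups()]
#' @rawNamespace exportMethods("[")
#' @export
setClass("OtuTable",
  representation(values = "matrix", kind = "character", groups = "character"))

setValidity("OtuTable", function(object) {
  v <- object@values
  msgs <- character()
  if (!is.numeric(v)) msgs <- c(msgs, "values must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msgs <- c(msgs, "values must have sample (row) and taxon (column) names")
  else {
    if (anyDuplicated(rownames(v))) msgs <- c(msgs, "duplicate sample ids")
    if (anyDuplicated(colnames(v))) msgs <- c(msgs, "duplicate taxon ids")
  }
  if (is.numeric(v) && length(v) && min(v) < 0)
    msgs <- c(msgs, "negative abundance values")
  if (length(object@kind) != 1L || !object@kind %in% c("counts", "relative"))
    msgs <- c(msgs, "kind must be 'counts' or 'relative'")
  if (identical(object@kind, "relative") && is.numeric(v) && nrow(v) > 0) {
    rs <- rowSums(v)
    if (any(rs > 1 + 1e-9) || any(rs <= 0))
      msgs <- c(msgs, "relative table rows must have sums in (0, 1]")
  }
  if (length(object@groups)) {
    if (is.null(names(object@groups)) ||
        !all(rownames(v) %in% names(object@groups)))
      msgs <- c(msgs, "groups must be named by sample id and cover all samples")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an OtuTable
#'
#' @param values numeric matrix, samples in rows, taxa in columns, with
#'   dimnames.
#' @param kind `"counts"` (default) or `"relative"`.
#' @param groups optional character vector of group labels named by sample id,
#'   or an unnamed vector of length `nrow(values)` taken in row order.
#' @return An [OtuTable-class] object.
#' @examples
#' m <- matrix(c(2, 3, 5, 0, 1, 9), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
#' otuTable(m, groups = c(s1 = "NS", s2 = "AS"))
#' @export
otuTable <- function(values, kind = c("counts", "relative"), groups = character()) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (length(groups) && is.null(names(groups))) {
    if (length(groups) != nrow(values))
      stop("unnamed 'groups' must have one entry per sample")
    names(groups) <- rownames(values)
  }
  if (length(groups)) groups <- groups[rownames(values)]
  new("OtuTable", values = values, kind = kind,
      groups = stats::setNames(as.character(groups), names(groups)))
}

#' CorrelationEstimate: basis correlations with pseudo p-values
#'
#' Symmetric taxon x taxon matrix of inferred basis (latent-abundance)
#' correlations, with an optional companion matrix of permutation pseudo
#' p-values, plus the resampling settings that produced them.
#'
#' @slot rho symmetric numeric matrix in [-1, 1] with unit diagonal.
#' @slot pvals symmetric numeric matrix in (0, 1] (0 x 0 when not computed).
#' @slot n_inner number of Dirichlet resampling iterations medianed over.
#' @slot n_boot number of permutation replicates behind `pvals` (0 if none).
#' @slot seed integer seed used (NA if none supplied).
#' @export
setClass("CorrelationEstimate",
  representation(rho = "matrix", pvals = "matrix",
                 n_inner = "integer", n_boot = "integer", seed = "integer"))

setValidity("CorrelationEstimate", function(object) {
  r <- object@rho
  msgs <- character()
  if (nrow(r) != ncol(r)) msgs <- c(msgs, "rho must be square")
  if (is.null(colnames(r))) msgs <- c(msgs, "rho must carry taxon names")
  if (length(r)) {
    if (max(abs(r)) > 1 + 1e-8) msgs <- c(msgs, "|rho| must be <= 1")
    if (max(abs(r - t(r))) > 1e-8) msgs <- c(msgs, "rho must be symmetric")
    if (max(abs(diag(r) - 1)) > 1e-8) msgs <- c(msgs, "rho diagonal must be 1")
  }
  p <- object@pvals
  if (length(p)) {
    if (!identical(dim(p), dim(r))) msgs <- c(msgs, "pvals dim mismatch")
    if (min(p) <= 0 || max(p) > 1) msgs <- c(msgs, "pvals must lie in (0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' CoNetwork: signed, weighted co-occurrence network over taxa
#'
#' Nodes are taxa annotated with their mean relative abundance (used for node
#' sizing in viewers); edges are unordered taxon pairs that passed the
#' significance / effect-size filter, weighted by the signed correlation.
#'
#' @slot nodes data.frame with columns `taxon`, `abundance`.
#' @slot edges data.frame with columns `from`, `to`, `correlation`, `p_value`.
#' @export
setClass("CoNetwork",
  representation(nodes = "data.frame", edges = "data.frame"))

setValidity("CoNetwork", function(object) {
  msgs <- character()
  nd <- object@nodes; ed <- object@edges
  if (!all(c("taxon", "abundance") %in% names(nd)))
    msgs <- c(msgs, "nodes need columns taxon, abundance")
  if (!all(c("from", "to", "correlation", "p_value") %in% names(ed)))
    msgs <- c(msgs, "edges need columns from, to, correlation, p_value")
  else if (nrow(ed)) {
    if (any(ed$from == ed$to)) msgs <- c(msgs, "self-edges are not allowed")
    if (max(abs(ed$correlation)) > 1 + 1e-8)
      msgs <- c(msgs, "edge |correlation| must be <= 1")
    if (!all(c(ed$from, ed$to) %in% nd$taxon))
      msgs <- c(msgs, "edge endpoints missing from node table")
  }
  if (anyDuplicated(nd$taxon)) msgs <- c(msgs, "duplicate node taxa")
  if (length(msgs)) msgs else TRUE
})

#' ClubClustering: a disjoint node partition from Markov clustering
#'
#' @slot membership integer vector of cluster ids, dense from 0, named by node.
#' @slot converged logical; FALSE when MCL hit its iteration cap.
#' @slot n_iter number of MCL iterations performed.
#' @export
setClass("ClubClustering",
  representation(membership = "integer", converged = "logical",
                 n_iter = "integer"))

setValidity("ClubClustering", function(object) {
  m <- object@membership
  msgs <- character()
  if (length(m)) {
    if (is.null(names(m))) msgs <- c(msgs, "membership must be named by node")
    ids <- sort(unique(m))
    if (!identical(ids, seq_along(ids) - 1L))
      msgs <- c(msgs, "cluster ids must be dense integers from 0")
  }
  if (length(msgs)) msgs else TRUE
})
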