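#' Accessors for MicrobeClubs classes
#'
#' `abundances()` returns the samples x taxa matrix; `tableKind()` the
#' `"counts"`/`"relative"` flag; `sampleNames()`/`taxonNames()` the margins;
#' `sampleGroups()` the named group labels; `nSamples()`/`nTaxa()` the sizes.
#'
#' @param x an [OtuTable-class] (or, where noted, another MicrobeClubs object).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname accessors
#' @export
setGeneric("tableKind", function(x) standardGeneric("tableKind"))
#' @rdname accessors
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))
#' @rdname accessors
#' @export
setGeneric("taxonNames", function(x) standardGeneric("taxonNames"))
#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("nTaxa", function(x) standardGeneric("nTaxa"))

#' @rdname accessors
#' @export
setMethod("abundances", "OtuTable", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("tableKind", "OtuTable", function(x) x@kind)
#' @rdname accessors
#' @export
setMethod("sampleNames", "OtuTable", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("taxonNames", "OtuTable", function(x) colnames(x@values))
#' @rdname accessors
#' @export
setMethod("sampleGroups", "OtuTable", function(x) {
  if (!length(x@groups)) return(NULL)
  x@groups[rownames(x@values)]
})
#' @rdname accessors
#' @export
setMethod("nSamples", "OtuTable", function(x) nrow(x@values))
#' @rdname accessors
#' @export
setMethod("nTaxa", "OtuTable", function(x) ncol(x@values))

# Subset an OtuTable by samples (i) and/or taxa (j); never drops dimensions.
# (Registered inside local(): roxygen2's object parser cannot introspect
# primitive-generic methods.)
local(setMethod("[", "OtuTable", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (missing(i)) i <- seq_len(nrow(v))
  if (missing(j)) j <- seq_len(ncol(v))
  v <- v[i, j, drop = FALSE]
  g <- if (length(x@groups)) x@groups[rownames(v)] else character()
  new("OtuTable", values = v, kind = x@kind, groups = g)
}))

setMethod("show", "OtuTable", function(object) {
  cat(sprintf("OtuTable (%s): %d samples x %d taxa\n",
              object@kind, nrow(object@values), ncol(object@values)))
  g <- sampleGroups(object)
  if (!is.null(g)) {
    tb <- table(g)
    cat("groups:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
})

#' @rdname accessors
#' @export
setMethod("taxonNames", "CorrelationEstimate", function(x) colnames(x@rho))

#' Correlation and p-value matrices of a CorrelationEstimate
#'
#' @param x a [CorrelationEstimate-class].
#' @return `correlations()`: the symmetric basis-correlation matrix;
#'   `pValues()`: the pseudo p-value matrix, or NULL when not computed.
#' @export
setGeneric("correlations", function(x) standardGeneric("correlations"))
#' @rdname correlations
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))
#' @rdname correlations
#' @export
setMethod("correlations", "CorrelationEstimate", function(x) x@rho)
#' @rdname correlations
#' @export
setMethod("pValues", "CorrelationEstimate", function(x)
  if (length(x@pvals)) x@pvals else NULL)

setMethod("show", "CorrelationEstimate", function(object) {
  cat(sprintf("CorrelationEstimate: %d taxa, n_inner=%d%s\n",
              ncol(object@rho), object@n_inner,
              if (length(object@pvals))
                sprintf(", pseudo p-values from %d permutations", object@n_boot)
              else ""))
})

#' Nodes and edges of a co-occurrence network
#'
#' @param x a [CoNetwork-class].
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname networkNodes
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname networkNodes
#' @export
setMethod("networkNodes", "CoNetwork", function(x) x@nodes)
#' @rdname networkNodes
#' @export
setMethod("networkEdges", "CoNetwork", function(x) x@edges)

setMethod("show", "CoNetwork", function(object) {
  e <- object@edges
  cat(sprintf("CoNetwork: %d nodes, %d edges (%d positive, %d negative)\n",
              nrow(object@nodes), nrow(e),
              sum(e$correlation > 0), sum(e$correlation < 0)))
})

#' Cluster membership of a ClubClustering
#'
#' @param x a [ClubClustering-class].
#' @return integer cluster ids (dense from 0), named by node.
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))
#' @rdname membership
#' @export
setMethod("membership", "ClubClustering", function(x) x@membership)

setMethod("show", "ClubClustering", function(object) {
  sz <- table(object@membership)
  cat(sprintf("ClubClustering: %d nodes in %d clusters (sizes: %s)%s\n",
              length(object@membership), length(sz),
              paste(sort(as.integer(sz), decreasing = TRUE), collapse = ", "),
              if (!object@converged) " [not converged]" else ""))
})
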