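# Readers and writers for the plain-text formats the pipeline touches:
# TSV abundance tables (either orientation), sample metadata, newick trees,
# and GraphML / edge-list network exports loadable by Cytoscape-class viewers.
# TSV is the canonical dialect; a comma-separated file is accepted by sniffing
# the header line.

sniffSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (!length(header)) stop("empty file: ", path)
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else "\t"
}

#' Read an OTU count table from TSV
#'
#' Expects one header row and one leading label column; the numeric body is
#' oriented by `orientation` and always returned as samples x taxa. A file
#' whose fields are comma-separated is accepted (the separator is sniffed from
#' the header line).
#'
#' @param path TSV (or CSV) file path.
#' @param orientation `"samples_in_rows"` (default) or `"taxa_in_rows"`.
#' @return A counts-kind [OtuTable-class] (no group labels attached).
#' @seealso [readMetadata()] to attach group labels, [writeCountsTable()]
#' @export
readCountsTable <- function(path,
                            orientation = c("samples_in_rows", "taxa_in_rows")) {
  orientation <- match.arg(orientation)
  sep <- sniffSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("table needs a label column and at least one data column: ", path)
  labels <- df[[1L]]
  if (anyDuplicated(labels))
    stop("duplicate row labels in ", path, ": ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (anyDuplicated(colnames(df)[-1L]))
    stop("duplicate column labels in ", path)
  body <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s' in %s",
                 body[bad[1L], bad[2L]], labels[bad[1L]],
                 colnames(df)[-1L][bad[2L]], path))
  }
  dimnames(num) <- list(labels, colnames(df)[-1L])
  if (min(num) < 0) {
    bad <- which(num < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative entry at row '%s', column '%s' in %s",
                 rownames(num)[bad[1L]], colnames(num)[bad[2L]], path))
  }
  if (orientation == "taxa_in_rows") num <- t(num)
  otuTable(num, kind = "counts")
}

#' Write an OtuTable to TSV
#'
#' Writes samples in rows with a leading `sample` label column; the companion
#' of [readCountsTable()] (round-trips values exactly via full-precision
#' formatting).
#'
#' @param table an [OtuTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCountsTable <- function(table, path) {
  stopifnot(is(table, "OtuTable"))
  v <- abundances(table)
  df <- data.frame(sample = rownames(v),
                   format(v, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (sample -> group) from TSV
#'
#' @param path TSV with columns `sample` and `group` (a header is required;
#'   comma separation is accepted).
#' @return named character vector mapping sample id to group label.
#' @export
readMetadata <- function(path) {
  sep <- sniffSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(df)))
    stop("metadata must have columns 'sample' and 'group': ", path)
  if (nrow(df) == 0L) stop("metadata file has no samples: ", path)
  if (anyDuplicated(df$sample))
    stop("duplicated sample id in metadata: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  stats::setNames(df$group, df$sample)
}

#' Write sample metadata to TSV
#'
#' @param groups named character vector (sample -> group).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMetadata <- function(groups, path) {
  utils::write.table(
    data.frame(sample = names(groups), group = as.character(groups)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny from a newick file
#'
#' Thin wrapper over [ape::read.tree()] that enforces the contract the
#' diversity and UniFrac stages rely on: named leaves, and branch lengths
#' (missing lengths are set to 0, negative lengths rejected). A trifurcating
#' root is accepted as given.
#'
#' @param path newick file.
#' @return an [ape::phylo] tree.
#' @export
readTree <- function(path) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) stop("unparseable newick in ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("unparseable newick in ", path)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  tree$edge.length[is.na(tree$edge.length)] <- 0
  if (any(tree$edge.length < 0)) stop("negative branch length in ", path)
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf names in ", path)
  tree
}

#' Export a co-occurrence network to GraphML or a TSV edge list
#'
#' GraphML carries node attributes `relative_abundance` and (when a clustering
#' is given) `cluster_id`, and edge attributes `correlation`, `p_value` and
#' `sign`; the edge list is `taxonA<TAB>taxonB<TAB>correlation`. Both load in
#' Cytoscape-class viewers, where node size conventionally encodes relative
#' abundance and edge thickness the correlation magnitude.
#'
#' @param network a [CoNetwork-class].
#' @param path output file.
#' @param format `"graphml"` or `"edgelist"`.
#' @param clustering optional [ClubClustering-class]; must cover every network
#'   node.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(network, path, format = c("graphml", "edgelist"),
                         clustering = NULL) {
  stopifnot(is(network, "CoNetwork"))
  format <- match.arg(format)
  nodes <- networkNodes(network)
  edges <- networkEdges(network)
  if (!is.null(clustering)) {
    stopifnot(is(clustering, "ClubClustering"))
    mem <- membership(clustering)
    missing <- setdiff(names(mem), nodes$taxon)
    if (length(missing))
      stop("clustering covers nodes absent from the network: ",
           paste(missing, collapse = ", "))
  }
  if (format == "edgelist") {
    df <- data.frame(from = edges$from, to = edges$to,
                     correlation = format(edges$correlation, digits = 17,
                                          trim = TRUE, scientific = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "correlation", "p_value")],
    directed = FALSE, vertices = nodes$taxon)
  igraph::V(g)$relative_abundance <- nodes$abundance[
    match(igraph::V(g)$name, nodes$taxon)]
  if (!is.null(clustering)) {
    mem <- membership(clustering)
    igraph::V(g)$cluster_id <- as.integer(mem[igraph::V(g)$name])
  }
  if (nrow(edges)) {
    igraph::E(g)$sign <- ifelse(igraph::E(g)$correlation >= 0,
                                "positive", "negative")
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a TSV edge list written by [writeNetwork()]
#'
#' @param path edge-list file (`from<TAB>to<TAB>correlation`, no header).
#' @return data.frame with columns `from`, `to`, `correlation`.
#' @export
readEdgeList <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("from", "to", "correlation"),
                          colClasses = c("character", "character", "numeric"),
                          stringsAsFactors = FALSE)
  df
}

#' Write a labeled square matrix (distances, correlations) to TSV
#'
#' @param m square numeric matrix with dimnames.
#' @param path output file.
#' @param label name of the leading label column.
#' @return `path`, invisibly.
#' @export
writeSquareMatrix <- function(m, path, label = "id") {
  df <- data.frame(rownames(m), format(m, digits = 17, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
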