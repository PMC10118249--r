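# Contaminant removal, total-sum scaling, and the group-wise prevalence
# filters. The screening is done once per analysis: counts -> remove
# contaminant taxa by name -> scale each sample to proportions -> drop taxa
# below the prevalence bar. Rows are deliberately NOT renormalized after taxon
# drops: proportions keep their original per-sample denominators, and the
# correlation stage works on counts anyway.

#' Remove contaminant taxa by name
#'
#' Drops every taxon whose label contains any of the given substrings
#' (case-insensitive, fixed strings). The default pattern targets
#' *Halomonas*, a saline-buffer contaminant of bronchoscope washes.
#'
#' @param table an [OtuTable-class] (counts or relative).
#' @param patterns character vector of substrings; empty vector leaves the
#'   table unchanged.
#' @return the filtered [OtuTable-class]; sample set unchanged.
#' @export
removeContaminants <- function(table, patterns = "Halomonas") {
  stopifnot(is(table, "OtuTable"))
  if (!length(patterns)) return(table)
  taxa <- taxonNames(table)
  hit <- rep(FALSE, length(taxa))
  for (p in patterns)
    hit <- hit | grepl(tolower(p), tolower(taxa), fixed = TRUE)
  if (all(hit)) stop("contaminant patterns would remove every taxon")
  table[, !hit]
}

#' Total-sum scaling to relative abundances
#'
#' Divides each entry by the sum of all entries for that sample, scaling each
#' sample's profile to proportions on \[0, 1\].
#'
#' @param table a counts-kind [OtuTable-class]; every sample must have a
#'   positive total.
#' @return a relative-kind [OtuTable-class] with rows summing to 1 (within
#'   1e-12).
#' @export
totalSumScale <- function(table) {
  stopifnot(is(table, "OtuTable"))
  if (tableKind(table) != "counts")
    stop("totalSumScale expects a counts-kind table")
  v <- abundances(table)
  totals <- rowSums(v)
  if (any(totals <= 0))
    stop("zero-total sample(s): ",
         paste(rownames(v)[totals <= 0], collapse = ", "))
  otuTable(v / totals, kind = "relative", groups = table@groups)
}

prevalenceOf <- function(v) colMeans(v > 0)

#' Group-wise prevalence filter
#'
#' Within each group, a taxon's prevalence is the fraction of that group's
#' samples in which it is non-zero. With `uniform_set = FALSE` each group
#' keeps its own taxa with prevalence >= `min_prevalence` in that group
#' (one table per group; retained taxon sets may differ — the "less than
#' 50% are eliminated" rule read strictly, so prevalence exactly at the
#' threshold is retained). With `uniform_set = TRUE` a single table is
#' returned keeping, for all groups, any taxon whose prevalence strictly
#' exceeds `min_prevalence` in at least one group (the "more than 50% of one
#' of the groups" rule, also strict).
#'
#' @param table a relative-kind [OtuTable-class] with group labels.
#' @param min_prevalence prevalence threshold in (0, 1]; default 0.5.
#' @param uniform_set logical; see above.
#' @return `uniform_set = FALSE`: named list of per-group [OtuTable-class]
#'   objects; `uniform_set = TRUE`: a single [OtuTable-class] over all
#'   samples.
#' @export
prevalenceFilter <- function(table, min_prevalence = 0.5, uniform_set = FALSE) {
  stopifnot(is(table, "OtuTable"))
  if (tableKind(table) != "relative")
    stop("prevalenceFilter expects a relative-kind (normalized) table")
  if (min_prevalence <= 0 || min_prevalence > 1)
    stop("min_prevalence must lie in (0, 1]")
  g <- sampleGroups(table)
  if (is.null(g)) stop("prevalenceFilter needs group labels")
  v <- abundances(table)
  groups <- unique(g)
  prev <- vapply(groups, function(gr) prevalenceOf(v[g == gr, , drop = FALSE]),
                 numeric(ncol(v)))
  if (is.null(dim(prev))) prev <- matrix(prev, nrow = ncol(v))
  if (uniform_set) {
    keep <- apply(prev > min_prevalence, 1L, any)
    return(table[, keep])
  }
  out <- lapply(groups, function(gr) {
    keep <- prev[, match(gr, groups)] >= min_prevalence
    table[g == gr, keep]
  })
  names(out) <- groups
  out
}
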